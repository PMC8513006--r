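# synthetic feature matrix with controllable class signal
fake_features <- function(n_participants = 10, windows_per_class = 20,
                          informative = c("mangle", "sdangle"), seed = 4) {
  set.seed(seed)
  fn <- feature_names()
  rows <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    for (cat in c("FT", "NFT")) {
      n <- windows_per_class
      m <- matrix(rnorm(n * 49), n, 49, dimnames = list(NULL, fn))
      if (cat == "FT") {
        m[, informative[1]] <- rnorm(n, 20, 3)
        m[, informative[2]] <- rnorm(n, 15, 3)
      } else {
        m[, informative[1]] <- rnorm(n, 60, 3)
        m[, informative[2]] <- rnorm(n, 2, 1)
      }
      act <- if (cat == "FT") "Repeated face touching" else "Leisure walk"
      rows[[length(rows) + 1]] <- cbind(
        data.frame(participant_id = pid, activity = act, category = cat,
                   window_start_s = seq_len(n), stringsAsFactors = FALSE),
        as.data.frame(m))
    }
  }
  do.call(rbind, rows)
}

test_that("nested plan is a leakage-free partition with 10 outer folds", {
  ids <- sprintf("P%02d", 1:10)
  plan <- make_nested_plan(ids, seed = 3)
  expect_length(plan$folds, 10)
  expect_setequal(vapply(plan$folds, `[[`, "", "test_participant"), ids)
  for (fold in plan$folds) {
    groups <- fold$inner_groups
    expect_length(groups, 3)
    expect_equal(lengths(groups), c(`1` = 3, `2` = 3, `3` = 3))
    train <- unlist(groups)
    expect_equal(anyDuplicated(train), 0)                 # pairwise disjoint
    expect_setequal(train, setdiff(ids, fold$test_participant))
    expect_false(fold$test_participant %in% train)        # no leakage
  }
  expect_identical(plan, make_nested_plan(ids, seed = 3)) # deterministic
  expect_false(identical(plan, make_nested_plan(ids, seed = 4)))
  expect_error(make_nested_plan(c("a", "b", "c"), 1), "design error")
})

test_that("plan construction does not disturb the global RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(make_nested_plan(sprintf("P%02d", 1:10), seed = 5))
  expect_identical(rnorm(1), a)
})

test_that("grid search returns the single point of a 1-point grid untried alternatives", {
  feats <- fake_features(n_participants = 9)
  fold <- list(test_participant = "none",
               inner_groups = split(sprintf("P%02d", 1:9),
                                    rep(1:3, each = 3)))
  g1 <- data.frame(maxdepth = 4, minbucket = 5)
  res <- grid_search_inner(feats, fold, "decision_tree", "binary", grid = g1)
  expect_equal(res$params$maxdepth, 4)
  expect_length(res$grid_scores, 1)
})

test_that("grid search picks the separating point and breaks ties by grid order", {
  feats <- fake_features(n_participants = 9)
  fold <- list(test_participant = "none",
               inner_groups = split(sprintf("P%02d", 1:9),
                                    rep(1:3, each = 3)))
  # minbucket larger than any inner training split forces a degenerate tree
  grid <- data.frame(maxdepth = c(30, 30), minbucket = c(10000, 1))
  res <- grid_search_inner(feats, fold, "decision_tree", "binary",
                           grid = grid)
  expect_equal(res$params$minbucket, 1)
  expect_gt(res$score, 0.95)        # two clean informative features separate

  tie <- data.frame(maxdepth = c(10, 10), minbucket = c(1, 1))
  res_tie <- grid_search_inner(feats, fold, "decision_tree", "binary",
                               grid = tie)
  expect_equal(res_tie$grid_scores[1], res_tie$grid_scores[2])
  expect_identical(res_tie$params, as.list(tie[1, , drop = FALSE]))
})

test_that("grid search reports a stratification error for a one-class inner split", {
  feats <- fake_features(n_participants = 9)
  feats$category[feats$participant_id %in% sprintf("P%02d", 1:6)] <- "NFT"
  fold <- list(test_participant = "none",
               inner_groups = split(sprintf("P%02d", 1:9),
                                    rep(1:3, each = 3)))
  expect_error(
    grid_search_inner(feats, fold, "decision_tree", "binary",
                      grid = data.frame(maxdepth = 3, minbucket = 1)),
    "stratification error")
})

test_that("binary metrics match direct arithmetic", {
  truth <- c(rep("FT", 9), rep("NFT", 11))
  pred <- c(rep("FT", 8), "NFT", rep("FT", 2), rep("NFT", 9))
  m <- binary_metrics(truth, pred)        # TP=8 FP=2 FN=1 TN=9
  expect_equal(m$precision, 0.800)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-6)
  expect_equal(m$recall, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-6)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.85)

  perfect <- binary_metrics(truth, truth,
                            scores = ifelse(truth == "FT", 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)            # perfectly separating scores

  w <- capture_warnings(m0 <- binary_metrics(rep("NFT", 5), rep("NFT", 5)))
  expect_match(w, "recall undefined", all = FALSE)
  expect_match(w, "precision undefined", all = FALSE)
  expect_true(is.na(m0$recall) && is.na(m0$precision))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:5) {
    truth <- sample(c("FT", "NFT"), 80, replace = TRUE)
    scores <- rnorm(80) + (truth == "FT") * runif(1, 0, 2)
    scores[sample(80, 10)] <- round(scores[sample(80, 10)], 1)  # some ties
    got <- binary_metrics(truth, truth, scores = scores)$auc
    want <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("NFT", "FT"),
      direction = "<", quiet = TRUE)))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("macro metrics match direct arithmetic and a binomial null", {
  truth <- c(rep("A", 4), rep("B", 4))
  pred <- c("A", "A", "A", "B", "B", "B", "B", "B")
  m <- multiclass_metrics(truth, pred)
  expect_equal(m$macro_recall, (0.75 + 1.0) / 2)

  all_right <- multiclass_metrics(truth, truth)
  expect_equal(unlist(all_right), c(accuracy = 1, macro_recall = 1,
                                    macro_precision = 1, macro_f1 = 1))

  set.seed(10)
  classes <- letters[1:10]
  truth10 <- rep(classes, each = 300)
  pred10 <- sample(classes, 3000, replace = TRUE)
  m10 <- multiclass_metrics(truth10, pred10)
  expect_equal(m10$accuracy, 0.1, tolerance = 0.25)  # ~3 binomial SDs

  expect_message(
    multiclass_metrics(c("a", "b"), c("a", "b"), classes = c("a", "b", "c")),
    "absent")
})

test_that("pooled confusion rows are percentages summing to 100", {
  truth <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  perfect <- pooled_confusion(truth, truth)
  expect_equal(diag(perfect), c(A = 100, B = 100, C = 100))
  set.seed(2)
  pred <- sample(c("A", "B", "C"), 10, replace = TRUE)
  cm <- pooled_confusion(truth, pred)
  expect_equal(unname(rowSums(cm)), rep(100, 3), tolerance = 1e-6)
  expect_error(pooled_confusion(character(0), character(0)), "empty")
})

test_that("training-fold standardization yields zero-mean unit-SD training columns", {
  set.seed(5)
  X <- matrix(rnorm(600, 3, 2), 100, 6)
  sc <- wristft:::.scaler_fit(X)
  Z <- wristft:::.scaler_apply(sc, X)
  expect_true(all(abs(colMeans(Z)) < 1e-8))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-8))
})

test_that("forest importances are scaled to max 1 and find the informative features", {
  feats <- fake_features(n_participants = 10)
  plan <- make_nested_plan(unique(feats$participant_id), seed = 1)
  rep_rf <- run_nested_cv(feats, "binary", "random_forest", plan,
                          grid = data.frame(num_trees = 100, max_depth = 0))
  imp <- forest_importances(rep_rf)
  expect_equal(max(imp$importance), 1)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_true(all(c("mangle", "sdangle") %in% imp$feature[1:5]))
  expect_equal(nrow(attr(imp, "top")), 15)
  expect_gt(rep_rf$summary$mean[rep_rf$summary$metric == "f1"], 0.9)

  rep_lr <- run_nested_cv(feats, "binary", "logistic_regression", plan,
                          grid = data.frame(C = 1))
  expect_error(forest_importances(rep_lr), "unsupported-family")
})

test_that("nested CV report aggregates fold metrics exactly and collapses consistently", {
  sim <- simulate_dataset(small_sim(n_participants = 6, duration = 60,
                                    seed = 31))
  feats <- extract_features(segments_of(sim), 5)
  plan <- make_nested_plan(unique(feats$participant_id), seed = 31)
  rep_mc <- suppressMessages(
    run_nested_cv(feats, "multiclass", "decision_tree", plan,
                  grid = data.frame(maxdepth = 10, minbucket = 5)))
  expect_length(rep_mc$folds, 6)

  # mean/SD equal brute-force recomputation from the per-fold values
  for (metric in rep_mc$summary$metric) {
    v <- vapply(rep_mc$folds, function(f) f$metrics[[metric]], 0)
    row <- rep_mc$summary[rep_mc$summary$metric == metric, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
  }

  # collapsing 10-class predictions to FT/NFT can only help accuracy
  for (f in unique(rep_mc$predictions$fold)) {
    sub <- rep_mc$predictions[rep_mc$predictions$fold == f, ]
    bin_acc <- mean(activity_category(sub$truth) ==
                      activity_category(sub$pred))
    mc_acc <- mean(sub$truth == sub$pred)
    expect_gte(bin_acc, mc_acc)
  }

  cm <- rep_mc$pooled_confusion
  covered <- rowSums(cm) > 0
  expect_equal(unname(rowSums(cm)[covered]),
               rep(100, sum(covered)), tolerance = 1e-6)
})

test_that("window sweep cells equal independent single-length runs", {
  sim <- simulate_dataset(small_sim(n_participants = 4, duration = 60,
                                    seed = 8))
  segs <- segments_of(sim)
  grids <- list(decision_tree = data.frame(maxdepth = 5, minbucket = 5))
  tab <- window_sweep(segs, lengths = c(2, 5), task = "binary",
                      families = "decision_tree", seed = 8, grids = grids)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$decision_tree >= 0 & tab$decision_tree <= 1))
  expect_true(attr(tab, "best_length") %in% c(2, 5))

  feats5 <- extract_features(segs, 5)
  plan <- make_nested_plan(unique(feats5$participant_id), seed = 8)
  solo <- run_nested_cv(feats5, "binary", "decision_tree", plan,
                        grid = grids$decision_tree)
  expect_equal(tab$decision_tree[tab$window_length == 5],
               solo$summary$mean[solo$summary$metric == "accuracy"])

  tab2 <- window_sweep(segs, lengths = c(2, 5), task = "binary",
                       families = "decision_tree", seed = 8, grids = grids)
  expect_identical(tab, tab2)
})
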