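#' Build a participant-grouped nested cross-validation plan
#'
#' Leave-one-subject-out outer folds: each participant is the test subject
#' in exactly one outer fold. Within each outer fold the remaining
#' participants are shuffled (deterministically from `seed`) and split into
#' three inner groups — of exactly three participants each when
#' `length(participant_ids) == 10` — so every inner iteration trains on two
#' groups and validates on the third.
#'
#' @param participant_ids Character vector of participant identifiers
#'   (at least 4).
#' @param seed Integer seed controlling the inner-group shuffle.
#' @return A `nested_cv_plan`: list with `folds` (each with
#'   `test_participant` and `inner_groups`, a list of 3 id vectors) and
#'   `seed`.
#' @export
make_nested_plan <- function(participant_ids, seed = 1) {
  ids <- sort(unique(as.character(participant_ids)))
  n <- length(ids)
  if (n < 4) {
    stop("design error: nested cross-validation needs at least 4 participants",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- lapply(ids, function(test_id) {
    rest <- sample(setdiff(ids, test_id))
    grp <- sort(rep_len(1:3, length(rest)))
    list(test_participant = test_id,
         inner_groups = split(rest, grp))
  })
  plan <- list(folds = folds, seed = as.integer(seed),
               participant_ids = ids)
  class(plan) <- "nested_cv_plan"
  plan
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default hyperparameter grids for the four classifier families
#'
#' Logistic regression is ridge-penalized with inverse regularization
#' strength `C`; the SVM uses a radial kernel with cost and a kernel-scale
#' multiplier on the `1/n_features` default; the decision tree is
#' pre-pruned by maximum depth and minimum leaf size; the random forest by
#' tree count and maximum depth (`0` = unlimited).
#'
#' @return Named list of data frames, one grid per family, rows in search
#'   order (ties in validation score resolve to the earlier row).
#' @export
default_grids <- function() {
  list(
    logistic_regression = data.frame(C = c(0.01, 0.1, 1, 10, 100)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma_mult = c(0.5, 1, 2)),
    decision_tree = expand.grid(maxdepth = c(3, 5, 10, 30),
                                minbucket = c(1, 5, 10)),
    random_forest = expand.grid(num_trees = c(100, 500),
                                max_depth = c(5, 10, 0))
  )
}

.families <- function() {
  c("logistic_regression", "svm", "decision_tree", "random_forest")
}

# z-score standardization fitted on training windows only
.scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

.scaler_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

# Fit one classifier. X is an already-standardized numeric matrix, y a
# factor (binary: levels NFT, FT). Returns an object usable by
# .predict_model().
.fit_model <- function(family, params, X, y, task, seed = 1L) {
  y <- droplevels(y)
  fit <- switch(
    family,
    logistic_regression = {
      lam <- 1 / (nrow(X) * params$C)    # inverse-regularization convention
      fam <- if (task == "binary") "binomial" else "multinomial"
      # descending path ending at the target lambda: glmnet's coordinate
      # descent needs the warm starts to converge at small penalties
      path <- exp(seq(log(max(lam * 1e4, 1)), log(lam), length.out = 15))
      suppressWarnings(
        glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = path,
                       thresh = 1e-5, maxit = 2e4, standardize = FALSE)
      )
    },
    svm = {
      e1071::svm(x = X, y = y, kernel = "radial", cost = params$cost,
                 gamma = params$gamma_mult / ncol(X), scale = FALSE)
    },
    decision_tree = {
      df <- data.frame(X)
      df$.label <- y
      rpart::rpart(.label ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth,
                     minbucket = params$minbucket,
                     minsplit = max(2L, 2L * params$minbucket),
                     cp = 0, xval = 0))
    },
    random_forest = {
      md <- if (params$max_depth == 0) NULL else params$max_depth
      # probability forest only where scores are needed (binary AUC/ROC)
      ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                     max.depth = md, probability = task == "binary",
                     importance = "impurity",
                     seed = seed, num.threads = 1)
    },
    stop("unsupported-family error: ", family, call. = FALSE)
  )
  structure(list(family = family, fit = fit, levels = levels(y),
                 task = task,
                 lambda = if (family == "logistic_regression")
                   1 / (nrow(X) * params$C) else NULL),
            class = "wristft_model")
}

# Predict classes and, for the binary task, a score for the positive
# class FT (probability for LR/tree/forest, decision value for SVM).
.predict_model <- function(model, X) {
  lev <- model$levels
  binary <- model$task == "binary"
  score <- NULL
  cls <- switch(
    model$family,
    logistic_regression = {
      if (binary) {
        pr <- as.numeric(stats::predict(model$fit, X, type = "response",
                                        s = model$lambda))
        score <- if (lev[length(lev)] == "FT") pr else 1 - pr
        factor(ifelse(pr > 0.5, lev[2], lev[1]), levels = lev)
      } else {
        factor(as.character(stats::predict(model$fit, X, type = "class",
                                           s = model$lambda)),
               levels = lev)
      }
    },
    svm = {
      pr <- stats::predict(model$fit, X, decision.values = binary)
      if (binary) {
        dv <- attr(pr, "decision.values")
        pos_first <- startsWith(colnames(dv)[1], "FT/")
        score <- if (pos_first) as.numeric(dv) else -as.numeric(dv)
      }
      factor(as.character(pr), levels = lev)
    },
    decision_tree = {
      pr <- stats::predict(model$fit, data.frame(X), type = "prob")
      if (binary) score <- pr[, "FT"]
      factor(colnames(pr)[max.col(pr, ties.method = "first")], levels = lev)
    },
    random_forest = {
      pr <- stats::predict(model$fit, data = X,
                           num.threads = 1)$predictions
      if (binary) {
        score <- pr[, "FT"]
        factor(colnames(pr)[max.col(pr, ties.method = "first")],
               levels = lev)
      } else {
        factor(as.character(pr), levels = lev)
      }
    }
  )
  list(class = cls, score = score)
}

#' Binary classification metrics
#'
#' Face touching (`"FT"`) is the positive class. `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)`, `F1 = 2PR/(P+R)`; AUC is the area under the
#' trapezoidal ROC curve over score thresholds. Metrics whose denominator
#' is empty (e.g. recall with no positive examples) are returned as `NA`
#' with a warning rather than silently 0.
#'
#' @param truth,pred Factors or character vectors of `"FT"`/`"NFT"` labels.
#' @param scores Optional numeric scores, higher = more FT-like, for AUC.
#' @param positive Positive class label (default `"FT"`).
#' @return Named list: `accuracy`, `recall`, `precision`, `f1`, `auc`.
#' @export
binary_metrics <- function(truth, pred, scores = NULL, positive = "FT") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  acc <- mean(truth == pred)
  if (tp + fn == 0) {
    warning("recall undefined: no positive examples in truth")
    rec <- NA_real_
  } else rec <- tp / (tp + fn)
  if (tp + fp == 0) {
    warning("precision undefined: no positive predictions")
    prec <- NA_real_
  } else prec <- tp / (tp + fp)
  f1 <- if (is.na(rec) || is.na(prec)) NA_real_
        else if (rec + prec == 0) 0 else 2 * prec * rec / (prec + rec)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2) {
      warning("AUC undefined: single-class test set")
    } else {
      auc <- .roc(scores, truth, positive)$auc
    }
  }
  list(accuracy = acc, recall = rec, precision = prec, f1 = f1, auc = auc)
}

# ROC curve over score thresholds (ties grouped) and trapezoidal AUC
.roc <- function(scores, truth, positive = "FT") {
  o <- order(scores, decreasing = TRUE)
  y <- as.character(truth)[o] == positive
  s <- scores[o]
  np <- sum(y); nn <- sum(!y)
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tpr <- c(0, cumsum(y)[keep] / np)
  fpr <- c(0, cumsum(!y)[keep] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC points for a set of scored predictions
#'
#' @inheritParams binary_metrics
#' @return Data frame with columns `fpr`, `tpr` (starting at (0,0)).
#' @export
roc_points <- function(scores, truth, positive = "FT") {
  .roc(scores, truth, positive)$points
}

#' Multiclass (macro-averaged) classification metrics
#'
#' One-vs-rest precision, recall and F1 per class, averaged unweighted over
#' the classes present in `truth`; classes absent from the test fold are
#' excluded from the average with a logged note. A class never predicted
#' contributes precision 0.
#'
#' @param truth,pred Factors or character vectors of activity labels.
#' @param classes Full class set (default: classes observed in `truth`).
#' @return Named list: `accuracy`, `macro_recall`, `macro_precision`,
#'   `macro_f1`.
#' @export
multiclass_metrics <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  if (is.null(classes)) classes <- sort(unique(truth))
  present <- classes[classes %in% truth]
  absent <- setdiff(classes, present)
  if (length(absent) > 0) {
    message("multiclass_metrics: class(es) absent from test fold excluded ",
            "from macro average: ", paste(absent, collapse = ", "))
  }
  per <- vapply(present, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    rec <- tp / sum(truth == cl)
    prec <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(rec, prec, f1)
  }, numeric(3))
  list(accuracy = mean(truth == pred),
       macro_recall = mean(per[1, ]),
       macro_precision = mean(per[2, ]),
       macro_f1 = mean(per[3, ]))
}

# label column and factor for a task
.task_labels <- function(features, task) {
  if (task == "binary") {
    factor(features$category, levels = c("NFT", "FT"))
  } else {
    factor(features$activity, levels = .activity_names())
  }
}

#' Inner-loop grid search over one outer fold's training participants
#'
#' For every grid row, trains on each union of two inner groups and scores
#' on the held-out group; selects the row maximizing the mean validation F1
#' (binary task: F1 of the FT class; multiclass: macro-F1). Ties resolve to
#' the first row in grid order. Features are standardized by each inner
#' training split's own statistics.
#'
#' @param features Feature matrix data frame (see [extract_features()])
#'   restricted or not — only the fold's training participants are used.
#' @param fold One element of a [make_nested_plan()] `folds` list.
#' @param family Classifier family name (see [default_grids()]).
#' @param task `"binary"` or `"multiclass"`.
#' @param grid Hyperparameter grid data frame; default from
#'   [default_grids()].
#' @param seed Integer seed for stochastic learners.
#' @return List with `params` (best row as a list), `score` (its mean
#'   validation F1) and `grid_scores` (all rows').
#' @export
grid_search_inner <- function(features, fold, family, task,
                              grid = default_grids()[[family]], seed = 1L) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  fn <- feature_names()
  y_all <- .task_labels(features, task)
  groups <- fold$inner_groups
  splits <- lapply(seq_along(groups), function(k) {
    val_ids <- groups[[k]]
    tr_ids <- unlist(groups[-k], use.names = FALSE)
    tr <- features$participant_id %in% tr_ids
    va <- features$participant_id %in% val_ids
    ytr <- y_all[tr]
    if (length(unique(as.character(ytr))) < 2) {
      stop("stratification error: inner split ", k, " (validation group ",
           paste(val_ids, collapse = ","),
           ") leaves fewer than 2 classes in training", call. = FALSE)
    }
    scaler <- .scaler_fit(as.matrix(features[tr, fn]))
    list(Xtr = .scaler_apply(scaler, as.matrix(features[tr, fn])),
         ytr = ytr,
         Xva = .scaler_apply(scaler, as.matrix(features[va, fn])),
         yva = y_all[va])
  })
  grid_scores <- vapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    mean(vapply(splits, function(sp) {
      model <- .fit_model(family, params, sp$Xtr, sp$ytr, task,
                          seed = seed + i)
      pred <- .predict_model(model, sp$Xva)$class
      if (task == "binary") {
        m <- suppressWarnings(binary_metrics(sp$yva, pred))
        if (is.na(m$f1)) 0 else m$f1
      } else {
        suppressMessages(multiclass_metrics(
          sp$yva, pred, classes = levels(y_all)))$macro_f1
      }
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(grid_scores)   # first max = first in grid order on ties
  list(params = as.list(grid[best, , drop = FALSE]),
       score = grid_scores[best],
       grid_scores = grid_scores)
}

#' Run the nested cross-validation protocol
#'
#' For each outer fold: hyperparameters are chosen by [grid_search_inner()]
#' on the 9 training participants, features are standardized by the
#' training fold's statistics, the model is refit on all training
#' participants and evaluated on the held-out test participant. Final
#' metrics are the mean and SD over the outer folds. The absence of
#' participant leakage (empty intersection of test and training ids) is
#' asserted programmatically in every fold.
#'
#' @param features Feature matrix data frame from [extract_features()]
#'   covering all plan participants.
#' @param task `"binary"` (FT vs NFT) or `"multiclass"` (10-activity
#'   recognition).
#' @param family Classifier family (see [default_grids()]).
#' @param plan A [make_nested_plan()].
#' @param grid Hyperparameter grid; default [default_grids()].
#' @return A `nested_cv_report`: list with `task`, `family`, `folds`
#'   (per-fold metrics, chosen hyperparameters, test predictions),
#'   `summary` (mean/SD per metric), `pooled_confusion` (row-normalized
#'   percent), `roc` (per-fold ROC point sets, binary only),
#'   `importances` (fold x feature impurity matrix, forest only) and
#'   `predictions` (pooled test predictions).
#' @export
run_nested_cv <- function(features, task = c("binary", "multiclass"),
                          family = .families(), plan,
                          grid = NULL) {
  task <- match.arg(task)
  family <- match.arg(family, .families())
  if (is.null(grid)) grid <- default_grids()[[family]]
  fn <- feature_names()
  stopifnot(all(fn %in% colnames(features)))
  if (!all(plan$participant_ids %in% features$participant_id)) {
    stop("feature matrix does not cover all plan participants",
         call. = FALSE)
  }
  y_all <- .task_labels(features, task)

  fold_results <- vector("list", length(plan$folds))
  preds <- vector("list", length(plan$folds))
  rocs <- list()
  importances <- list()
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    test_id <- fold$test_participant
    train_ids <- unlist(fold$inner_groups, use.names = FALSE)
    stopifnot(length(intersect(test_id, train_ids)) == 0)  # no leakage
    tr <- features$participant_id %in% train_ids
    te <- features$participant_id == test_id

    search <- grid_search_inner(features[tr, , drop = FALSE], fold,
                                family, task, grid,
                                seed = plan$seed + i * 101L)
    scaler <- .scaler_fit(as.matrix(features[tr, fn]))
    Xtr <- .scaler_apply(scaler, as.matrix(features[tr, fn]))
    Xte <- .scaler_apply(scaler, as.matrix(features[te, fn]))
    model <- .fit_model(family, search$params, Xtr, y_all[tr], task,
                        seed = plan$seed + i * 101L + 50L)
    out <- .predict_model(model, Xte)
    truth <- y_all[te]

    if (task == "binary") {
      metrics <- binary_metrics(truth, out$class, out$score)
      if (length(unique(as.character(truth))) >= 2) {
        rocs[[test_id]] <- roc_points(out$score, truth)
      } else {
        warning("fold ", i, " (", test_id,
                "): single-class test set, excluded from AUC averaging")
      }
    } else {
      metrics <- multiclass_metrics(truth, out$class,
                                    classes = levels(y_all))
    }
    if (family == "random_forest") {
      importances[[test_id]] <- model$fit$variable.importance
    }
    fold_results[[i]] <- list(
      fold = i, test_participant = test_id,
      params = search$params, inner_score = search$score,
      metrics = metrics, n_test = sum(te)
    )
    preds[[i]] <- data.frame(
      participant_id = test_id, fold = i,
      truth = as.character(truth), pred = as.character(out$class),
      score = if (is.null(out$score)) NA_real_ else out$score,
      stringsAsFactors = FALSE
    )
  }

  predictions <- do.call(rbind, preds)
  metric_names <- names(fold_results[[1]]$metrics)
  summ <- do.call(rbind, lapply(metric_names, function(m) {
    v <- vapply(fold_results, function(f) f$metrics[[m]], numeric(1))
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               n_folds = sum(!is.na(v)), stringsAsFactors = FALSE)
  }))
  classes <- levels(y_all)
  report <- list(
    task = task, family = family,
    folds = fold_results,
    summary = summ,
    pooled_confusion = pooled_confusion(predictions$truth,
                                        predictions$pred, classes),
    roc = if (task == "binary") rocs else NULL,
    importances = if (family == "random_forest")
      do.call(rbind, importances) else NULL,
    predictions = predictions,
    plan_seed = plan$seed
  )
  class(report) <- "nested_cv_report"
  report
}

#' Pooled, row-normalized confusion matrix (percent)
#'
#' Counts true-class by predicted-class over all pooled test predictions
#' and normalizes each row to 100%. Rows for classes with no test windows
#' are left at zero.
#'
#' @param truth,pred Label vectors of equal, positive length.
#' @param classes Class set fixing the row/column order.
#' @return Square matrix of row percentages.
#' @export
pooled_confusion <- function(truth, pred,
                             classes = sort(unique(c(truth, pred)))) {
  if (length(truth) == 0) stop("empty predictions", call. = FALSE)
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  counts <- table(truth, pred)
  rs <- rowSums(counts)
  pct <- sweep(unclass(counts), 1, ifelse(rs == 0, 1, rs), "/") * 100
  pct
}

#' Scaled impurity-based feature importances from the forest folds
#'
#' Mean impurity importance of each feature across the outer-fold random
#' forests, divided by its maximum so the most important feature scores
#' exactly 1.
#'
#' @param report A `nested_cv_report` from a `random_forest` run.
#' @param top Number of top features to flag (default 15).
#' @return Data frame `feature, importance`, sorted decreasing, with the
#'   top-`top` subset in attribute `"top"`.
#' @export
forest_importances <- function(report, top = 15) {
  if (is.null(report$importances)) {
    stop("unsupported-family error: importances require a random_forest report",
         call. = FALSE)
  }
  imp <- colMeans(report$importances)
  imp <- pmax(imp, 0)
  imp <- imp / max(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top") <- utils::head(out, top)
  out
}

#' Accuracy-versus-window-length sweep
#'
#' Re-runs feature extraction and nested cross-validation for each window
#' length and tabulates the mean outer-fold accuracy per classifier
#' family, together with the best length per family.
#'
#' @param segments List of `labeled_segment`s covering all participants.
#' @param lengths Integer window lengths in seconds (subset of 2..16).
#' @param task `"binary"` or `"multiclass"`.
#' @param families Classifier families to include.
#' @param seed Seed for the nested plan.
#' @param grids Named list of grids (default [default_grids()]).
#' @return Data frame with column `window_length` and one accuracy column
#'   per family; attribute `"best_length"` holds the argmax length per
#'   family.
#' @export
window_sweep <- function(segments, lengths = 2:16,
                         task = c("binary", "multiclass"),
                         families = .families(), seed = 1,
                         grids = default_grids()) {
  task <- match.arg(task)
  families <- match.arg(families, .families(), several.ok = TRUE)
  rows <- lapply(lengths, function(w) {
    feats <- extract_features(segments, w)
    plan <- make_nested_plan(unique(feats$participant_id), seed)
    acc <- vapply(families, function(fam) {
      rep <- run_nested_cv(feats, task, fam, plan, grid = grids[[fam]])
      rep$summary$mean[rep$summary$metric == "accuracy"]
    }, numeric(1))
    c(window_length = w, acc)
  })
  out <- as.data.frame(do.call(rbind, rows))
  best <- vapply(families, function(fam) {
    out$window_length[which.max(out[[fam]])]
  }, numeric(1))
  attr(out, "best_length") <- best
  out
}

#' @export
print.nested_cv_report <- function(x, ...) {
  cat("Nested cross-validation report\n")
  cat("  task:   ", x$task, "\n")
  cat("  family: ", x$family, "\n")
  cat("  folds:  ", length(x$folds), "\n")
  cat("  metrics (mean (SD) over outer folds):\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("    %-16s %s\n", x$summary$metric[i],
                format_mean_sd(x$summary$mean[i], x$summary$sd[i])))
  }
  invisible(x)
}

#' Format a metric as "mean (SD)" to two decimals
#'
#' @param mean,sd Numeric scalars.
#' @return Character scalar like `"0.93 (0.08)"`.
#' @export
format_mean_sd <- function(mean, sd) {
  sprintf("%.2f (%.2f)", mean, sd)
}
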