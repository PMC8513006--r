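#' The scripted ten-activity protocol
#'
#' The laboratory protocol comprises ten scripted activities, four of which
#' involve hand-to-face movements (category `"FT"`, face touching) and six of
#' which do not (`"NFT"`). `"FT"` is the positive class in binary recognition.
#'
#' @return A data frame with columns `name` (activity label) and `category`
#'   (`"FT"` or `"NFT"`), one row per activity, in protocol order.
#' @examples
#' activity_catalog()
#' @export
activity_catalog <- function() {
  data.frame(
    name = c(
      "Using mobile phone",
      "Lying flat on the back",
      "Computer tasks",
      "Writing",
      "Leisure walk",
      "Moving items from one location to another",
      "Repeated face touching",
      "Eating and drinking",
      "Simulated smoking",
      "Adjusting eyeglass"
    ),
    category = c(rep("NFT", 6), rep("FT", 4)),
    stringsAsFactors = FALSE
  )
}

#' Category (FT/NFT) of an activity label
#'
#' @param activity Character vector of activity names from
#'   [activity_catalog()].
#' @return Character vector of `"FT"`/`"NFT"`.
#' @export
activity_category <- function(activity) {
  cat <- activity_catalog()
  idx <- match(activity, cat$name)
  if (anyNA(idx)) {
    stop("unknown activity label(s): ",
         paste(unique(activity[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  cat$category[idx]
}

.activity_names <- function() activity_catalog()$name
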