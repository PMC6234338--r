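#' Load the reduced morningness-eveningness scoring key
#'
#' The 5-item reduced scale is scored by summing per-item scores; the
#' standard key uses item ranges 1-5, 1-4, 1-5, 1-5 and 0-6, giving a
#' total between 4 (extreme evening) and 25 (extreme morning). The key
#' and the class cutoffs are shipped as a JSON config so an alternative
#' wording or key can be swapped in without code change.
#'
#' @param path optional path to an alternative key config.
#' @return list with `items` (data frame: item, min, max) and `classes`
#'   (data frame: label, lo, hi).
#' @export
meq_key <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rmeq_key.json", package = "cogbattery")
  key <- jsonlite::fromJSON(path)
  stopifnot(nrow(key$items) == 5L, nrow(key$classes) == 5L)
  key
}

#' Score a reduced morningness-eveningness response
#'
#' @param item_scores integer vector of 5 item scores, each within its
#'   item's admissible range per the scoring key.
#' @param key scoring key from [meq_key()].
#' @return integer total in `[4, 25]` (higher = more morning-oriented).
#' @export
score_meq <- function(item_scores, key = meq_key()) {
  if (length(item_scores) != 5L)
    stop("expected 5 item scores, got ", length(item_scores))
  if (anyNA(item_scores))
    stop("missing item score at item ", which(is.na(item_scores))[1L])
  bad <- which(item_scores < key$items$min | item_scores > key$items$max |
                 item_scores != round(item_scores))
  if (length(bad))
    stop("item ", bad[1L], " score ", item_scores[bad[1L]],
         " outside admissible range [", key$items$min[bad[1L]], ", ",
         key$items$max[bad[1L]], "]")
  as.integer(sum(item_scores))
}

#' Classify a chronotype from the questionnaire total
#'
#' Cutoffs: definitely evening 4-7, moderately evening 8-11, neither
#' 12-17, moderately morning 18-21, definitely morning 22-25. Every
#' integer total maps to exactly one class.
#'
#' @param total integer total(s) in `[4, 25]`.
#' @param key scoring key from [meq_key()].
#' @return factor with the five chronotype labels (evening to morning).
#' @export
classify_meq <- function(total, key = meq_key()) {
  cls <- key$classes
  if (anyNA(total) || any(total < min(cls$lo)) || any(total > max(cls$hi)) ||
      any(total != round(total)))
    stop("total must be an integer in [", min(cls$lo), ", ", max(cls$hi), "]")
  idx <- vapply(total, function(x) which(x >= cls$lo & x <= cls$hi), 0L)
  factor(cls$label[idx], levels = cls$label)
}

#' Convert a slider position to a mood rating
#'
#' The mood item is a visual-analog slider; its position in `[0, 1]` is
#' mapped affinely onto the 1--10 rating scale (10 = happiest). A skipped
#' item (`NULL` or `NA`) is recorded as absent.
#'
#' @param slider slider position in `[0, 1]`, or `NULL`/`NA` if skipped.
#' @return mood rating in `[1, 10]`, or `NULL` if skipped.
#' @export
record_mood <- function(slider) {
  if (is.null(slider) || (length(slider) == 1L && is.na(slider))) return(NULL)
  stopifnot(slider >= 0, slider <= 1)
  1 + 9 * slider
}
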