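#' Published elevation thresholds for the four distress scales
#'
#' State anxiety (SSAI) > 40, trait anxiety (STAI) > 40, perceived stress
#' (PSS) > 15, depressive symptoms (EPDS) > 10; all strict cutoffs.
#'
#' @return Named numeric vector of thresholds.
#' @export
distress_thresholds <- function() c(ssai = 40, stai = 40, pss = 15, epds = 10)

#' Validate distress scores against the scale ranges
#'
#' SSAI/STAI totals live on 20-80, PSS on 0-40, EPDS on 0-30. In-range and
#' missing values pass through; an out-of-range value raises an error naming
#' the scale.
#'
#' @param scores A data frame with any of the columns `ssai`, `stai`, `pss`,
#'   `epds` (per scan), or a named vector/list of single scores.
#' @return The input, invisibly coerced to a tibble, unchanged.
#' @export
validate_scores <- function(scores) {
  if (!is.data.frame(scores)) scores <- tibble::as_tibble(as.list(scores))
  bounds <- distress_bounds()
  for (nm in intersect(names(scores), names(bounds))) {
    b <- bounds[[nm]]
    v <- scores[[nm]]
    bad <- !is.na(v) & (v < b[1] | v > b[2])
    if (any(bad)) {
      stop(sprintf("%s score out of range [%g, %g]: %s", toupper(nm),
                   b[1], b[2], paste(v[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  tibble::as_tibble(scores)
}

#' Classify a distress score as low or high
#'
#' High means strictly greater than the scale's threshold; a score exactly at
#' the threshold is low.
#'
#' @param measure Scale name: one of `ssai`, `stai`, `pss`, `epds`.
#' @param value Score value(s); `NA` classifies as `NA`.
#' @param thresholds Threshold overrides, defaults [distress_thresholds()].
#' @return Character vector `"low"`/`"high"` (NA preserved).
#' @export
classify_distress <- function(measure, value,
                              thresholds = distress_thresholds()) {
  measure <- tolower(measure)
  if (!measure %in% names(thresholds)) {
    stop("unknown distress measure: ", measure, call. = FALSE)
  }
  b <- distress_bounds()[[measure]]
  if (!is.null(b) && any(!is.na(value) & (value < b[1] | value > b[2]))) {
    stop(toupper(measure), " score outside scale range", call. = FALSE)
  }
  ifelse(is.na(value), NA_character_,
         ifelse(value > thresholds[[measure]], "high", "low"))
}

#' Is any distress measure elevated?
#'
#' TRUE when at least one of the four measures strictly exceeds its
#' threshold. Missing measures are treated as non-elevated (complete absence
#' of all four still returns FALSE, with a message).
#'
#' @param scores Data frame (or named vector) with columns `ssai`, `stai`,
#'   `pss`, `epds`.
#' @param thresholds Threshold overrides.
#' @return Logical vector, one per row.
#' @export
any_elevated <- function(scores, thresholds = distress_thresholds()) {
  scores <- validate_scores(scores)
  present <- intersect(names(thresholds), names(scores))
  if (length(present) == 0) {
    stop("no distress score columns found", call. = FALSE)
  }
  high <- matrix(
    vapply(present, function(nm) {
      !is.na(scores[[nm]]) & scores[[nm]] > thresholds[[nm]]
    }, logical(nrow(scores))),
    nrow = nrow(scores)
  )
  n_missing <- rowSums(matrix(
    vapply(present, function(nm) is.na(scores[[nm]]), logical(nrow(scores))),
    nrow = nrow(scores)
  ))
  if (any(n_missing > 0)) {
    message(sum(n_missing > 0), " row(s) have missing distress scores; ",
            "missing measures count as non-elevated")
  }
  rowSums(high) > 0
}
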