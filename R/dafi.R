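#' Score the Deficit Accumulation Frailty Index
#'
#' The DAFI is the sum of ordinal deficit-indicator codes (0 = absent,
#' 1 = intermediate, 2 = most adverse) divided by the maximum possible
#' sum, i.e. twice the number of indicators actually assessed. A missing
#' indicator is excluded from both numerator and denominator. The score is
#' only considered valid when at least `min_assessed` indicators (default
#' 35 of the 44) were assessed.
#'
#' @param values Integer-ish vector of indicator codes in `{0, 1, 2}` with
#'   `NA` for unassessed items.
#' @param min_assessed Validity threshold on the number of assessed
#'   indicators (default 35).
#' @param excluded Optional logical vector (or integer index) of
#'   indicators excluded by design (e.g. self-reported cognition, the
#'   index disease itself); these never enter numerator or denominator.
#' @return A one-row tibble: `dafi` (in `[0, 1]`, `NA` when invalid),
#'   `n_assessed`, `category` (`robust`/`pre_frail`/`frail`/`invalid`).
#' @examples
#' score_dafi(c(rep(0, 40), 1, 1, 2, NA))
#' @export
score_dafi <- function(values, min_assessed = 35, excluded = NULL) {
  if (!is.null(excluded)) {
    if (is.logical(excluded)) {
      stopifnot(length(excluded) == length(values))
      values <- values[!excluded]
    } else values <- values[-excluded]
  }
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad))
    cf_abort(sprintf("indicator values outside {0, 1, 2, NA}: %s",
                     paste(unique(values[bad]), collapse = ", ")),
             "cogfrail_data_error")
  n_assessed <- sum(!is.na(values))
  if (n_assessed < min_assessed) {
    return(tibble::tibble(dafi = NA_real_, n_assessed = n_assessed,
                          category = "invalid"))
  }
  score <- sum(values, na.rm = TRUE) / (2 * n_assessed)
  tibble::tibble(dafi = score, n_assessed = n_assessed,
                 category = categorize_dafi(score))
}

#' Classify a DAFI score into frailty categories
#'
#' Cut-offs: robust below 0.2, pre-frail in `[0.2, 0.35)`, frail at 0.35
#' and above.
#'
#' @param score Numeric DAFI score(s) in `[0, 1]`; `NA` allowed.
#' @return Character vector of `"robust"`, `"pre_frail"`, `"frail"` (`NA`
#'   stays `NA`).
#' @examples
#' categorize_dafi(c(0.19, 0.20, 0.35))
#' @export
categorize_dafi <- function(score) {
  ok <- !is.na(score)
  if (any(score[ok] < 0 | score[ok] > 1))
    cf_abort("DAFI score outside [0, 1]", "cogfrail_data_error")
  out <- rep(NA_character_, length(score))
  out[ok] <- ifelse(score[ok] < 0.2, "robust",
                    ifelse(score[ok] < 0.35, "pre_frail", "frail"))
  out
}

#' Score DAFI for every visit in an indicator table
#'
#' Applies [score_dafi()] row-wise to a visit-level indicator table
#' (one 0/1/2/`NA` column per indicator), carrying the identifier columns
#' through.
#'
#' @param indicators Tibble with `participant_id`, `month` and indicator
#'   columns.
#' @param indicator_cols Character vector naming the indicator columns;
#'   defaults to every column except known identifiers.
#' @param schema Optional indicator schema with an `excluded` flag column
#'   (see [default_indicator_schema()]); excluded indicators are dropped
#'   before scoring.
#' @inheritParams score_dafi
#' @return Tibble: `participant_id`, `month`, `dafi`, `n_assessed`,
#'   `category`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_survivors = 10, n_controls = 5))
#' dafi_scores(sim$indicators)
#' @export
dafi_scores <- function(indicators, indicator_cols = NULL, schema = NULL,
                        min_assessed = 35) {
  check_columns(indicators, c("participant_id", "month"),
                "indicator table")
  if (is.null(indicator_cols))
    indicator_cols <- setdiff(names(indicators),
                              c("participant_id", "group", "age_enroll",
                                "month"))
  check_columns(indicators, indicator_cols, "indicator table")
  if (!is.null(schema)) {
    check_columns(schema, c("indicator", "excluded"), "indicator schema")
    keep <- schema$indicator[!schema$excluded]
    indicator_cols <- intersect(indicator_cols, keep)
  }
  m <- as.matrix(indicators[, indicator_cols])
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i)
    score_dafi(m[i, ], min_assessed = min_assessed))
  dplyr::bind_cols(indicators[, intersect(c("participant_id", "group",
                                            "age_enroll", "month"),
                                          names(indicators))],
                   res)
}
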