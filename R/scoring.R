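#' Flag non-normal raw test-score distributions
#'
#' Distributional screen applied per test before standardization: a sample
#' is called non-normal when its absolute sample skewness exceeds
#' `threshold`. A fixed skewness rule (rather than a significance test) is
#' deliberately sample-size independent: with hundreds of observations a
#' formal test rejects trivial departures, while the transformation only
#' matters for visibly asymmetric scores.
#'
#' @param values Numeric sample; `NA`s dropped.
#' @param threshold Absolute skewness above which the sample is flagged
#'   (default 1).
#' @param min_n Minimum sample size (default 20).
#' @return `"normal"` or `"non_normal"`.
#' @examples
#' assess_normality(rnorm(100))
#' @export
assess_normality <- function(values, threshold = 1, min_n = 20) {
  values <- values[!is.na(values)]
  if (length(values) < min_n)
    cf_abort(sprintf("need at least %d non-missing values, got %d",
                     min_n, length(values)), "cogfrail_data_error")
  g1 <- skewness(values)
  if (is.nan(g1))
    cf_abort("sample has zero variance; skewness undefined",
             "cogfrail_data_error")
  if (abs(g1) > threshold) "non_normal" else "normal"
}

#' Fit a Box-Cox power transformation
#'
#' Profile-likelihood fit of the Box-Cox parameter over a lambda grid. If
#' any value is non-positive a shift of `1 - min(values)` is applied first
#' so the minimum becomes 1. If the maximum-likelihood lambda fails to
#' reduce absolute skewness (possible in small or oddly shaped samples),
#' the grid value minimizing absolute post-transform skewness is used
#' instead.
#'
#' @param values Numeric sample, `NA`s dropped.
#' @param grid Candidate lambdas (default `seq(-3, 3, by = 0.01)`).
#' @return A list with `lambda`, `shift`, and the profile log-likelihood
#'   at the optimum.
#' @examples
#' fit_boxcox(rlnorm(500))$lambda  # near 0
#' @export
fit_boxcox <- function(values, grid = seq(-3, 3, by = 0.01)) {
  x <- values[!is.na(values)]
  if (length(x) < 3L || sd(x) == 0)
    cf_abort("Box-Cox requires a non-degenerate sample",
             "cogfrail_data_error")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  n <- length(xs)
  slx <- sum(log(xs))
  ll <- vapply(grid, function(l) {
    y <- box_cox(xs, l)
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  sk0 <- abs(skewness(xs))
  if (abs(skewness(box_cox(xs, lambda))) > sk0) {
    sk <- vapply(grid, function(l) abs(skewness(box_cox(xs, l))), numeric(1))
    lambda <- grid[which.min(sk)]
  }
  list(lambda = lambda, shift = shift, loglik = max(ll))
}

# the Box-Cox transform itself; values must be positive after shifting
box_cox <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

apply_transform <- function(x, lambda, shift) {
  if (lambda == 1 && shift == 0) return(x)  # untransformed tests: identity
  xs <- pmax(x + shift, .Machine$double.eps)
  box_cox(xs, lambda)
}

#' Fit the control-group standardization reference
#'
#' For each test in the schema, fits the transformation and z-scoring
#' reference on the healthy-control baseline sample: the normality screen
#' decides whether a Box-Cox transform is needed; the reference mean and
#' SD are then computed from the (possibly transformed) baseline control
#' values. The reference population defines the scale for all groups and
#' visits, so group effects and practice effects cannot leak into the
#' transform.
#'
#' @param scores Visit-level tibble with `participant_id`, `group`,
#'   `month` and one column per test.
#' @param schema Test schema (see [default_test_schema()]); only `test`,
#'   `domain`, `direction` are used.
#' @param transform `"auto"` (Box-Cox when flagged non-normal), `"never"`
#'   (identity for every test), or `"always"`.
#' @param skew_threshold Passed to [assess_normality()].
#' @param reference_month Baseline month defining the reference visits
#'   (default 0).
#' @return A tibble of class `standardization_reference`: one row per
#'   test with `lambda`, `shift`, `ref_mean`, `ref_sd`, `transformed`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_survivors = 30, n_controls = 30))
#' fit_reference(sim$scores, sim$config$test_schema)
#' @export
fit_reference <- function(scores, schema = default_test_schema(),
                          transform = c("auto", "never", "always"),
                          skew_threshold = 1, reference_month = 0) {
  transform <- match.arg(transform)
  check_columns(scores, c("participant_id", "group", "month"),
                "scores table")
  check_columns(scores, schema$test, "scores table")
  base <- dplyr::filter(scores, .data$group == "control",
                        .data$month == reference_month)
  if (nrow(base) == 0L)
    cf_abort("no baseline control visits to build the reference from",
             "cogfrail_data_error")
  ref <- purrr::map_dfr(schema$test, function(tn) {
    x <- base[[tn]]
    x <- x[!is.na(x)]
    # samples below the screen's minimum are left untransformed: with so
    # few reference values a fitted power transform is not trustworthy
    use_bc <- switch(transform,
      never = FALSE,
      always = TRUE,
      auto = length(x) >= 20 &&
        assess_normality(x, threshold = skew_threshold) == "non_normal")
    if (use_bc) {
      bc <- fit_boxcox(x)
      y <- apply_transform(x, bc$lambda, bc$shift)
      tibble::tibble(test = tn, lambda = bc$lambda, shift = bc$shift,
                     transformed = TRUE,
                     ref_mean = mean(y), ref_sd = sd(y))
    } else {
      tibble::tibble(test = tn, lambda = 1, shift = 0, transformed = FALSE,
                     ref_mean = mean(x), ref_sd = sd(x))
    }
  })
  if (any(ref$ref_sd <= 0))
    cf_abort(sprintf("zero reference SD for test(s): %s",
                     paste(ref$test[ref$ref_sd <= 0], collapse = ", ")),
             "cogfrail_data_error")
  structure(ref, class = c("standardization_reference", class(ref)))
}

#' Standardize raw test scores against the control reference
#'
#' Applies each test's fitted transformation, z-scores against the
#' control-baseline reference mean/SD, and negates the z-score for
#' `higher_worse` (timed) tests so that higher always means better.
#'
#' @param scores Visit-level tibble (as for [fit_reference()]).
#' @param reference A `standardization_reference`.
#' @param schema Test schema supplying `domain` and `direction`.
#' @return A long tibble: `participant_id`, `group`, `age_enroll` (if
#'   present), `month`, `test`, `domain`, `z`.
#' @export
standardize_scores <- function(scores, reference,
                               schema = default_test_schema()) {
  stopifnot(inherits(reference, "standardization_reference"))
  check_columns(scores, c("participant_id", "month"), "scores table")
  tests <- intersect(names(scores), schema$test)
  unknown <- setdiff(tests, reference$test)
  if (length(unknown) > 0L)
    cf_abort(sprintf("test(s) absent from reference: %s",
                     paste(unknown, collapse = ", ")),
             "cogfrail_schema_error")
  id_cols <- intersect(c("participant_id", "group", "age_enroll", "month"),
                       names(scores))
  long <- tidyr::pivot_longer(scores[, c(id_cols, tests)],
                              cols = dplyr::all_of(tests),
                              names_to = "test", values_to = "raw")
  long <- dplyr::left_join(long, reference, by = "test")
  long <- dplyr::left_join(long,
                           schema[, c("test", "domain", "direction")],
                           by = "test")
  long <- long |>
    dplyr::group_by(.data$test) |>
    dplyr::mutate(z = {
      zt <- (apply_transform(.data$raw, .data$lambda[1], .data$shift[1]) -
               .data$ref_mean[1]) / .data$ref_sd[1]
      if (.data$direction[1] == "higher_worse") -zt else zt
    }) |>
    dplyr::ungroup()
  long[, c(id_cols, "test", "domain", "z")]
}

#' Compute domain composite scores
#'
#' Per participant-visit, the domain score is the mean of the available
#' member-test z-scores; it is missing when fewer than `min_tests` (by
#' default, half the domain's tests, rounded up) are present.
#'
#' @param z Long z-score table from [standardize_scores()].
#' @param schema Test schema defining domain membership.
#' @param min_tests Named integer vector of per-domain minimums, or `NULL`
#'   for the half-rule.
#' @return A wide tibble (the domain-score panel): identifier columns,
#'   one score column per domain, and `n_<domain>` counts of tests used.
#' @export
domain_scores <- function(z, schema = default_test_schema(),
                          min_tests = NULL) {
  check_columns(z, c("participant_id", "month", "test", "domain", "z"),
                "z-score table")
  sizes <- table(schema$domain)
  if (is.null(min_tests))
    min_tests <- setNames(ceiling(as.numeric(sizes) / 2), names(sizes))
  id_cols <- intersect(c("participant_id", "group", "age_enroll", "month"),
                       names(z))
  agg <- z |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, "domain")))) |>
    dplyr::summarise(score = mean(.data$z, na.rm = TRUE),
                     n_used = sum(!is.na(.data$z)), .groups = "drop") |>
    dplyr::mutate(score = as.numeric(ifelse(
      .data$n_used >= unname(min_tests[.data$domain]),
      .data$score, NA_real_)))
  wide <- tidyr::pivot_wider(agg, id_cols = dplyr::all_of(id_cols),
                             names_from = "domain",
                             values_from = c("score", "n_used"))
  doms <- unique(schema$domain)
  for (d in doms) {
    names(wide)[names(wide) == paste0("score_", d)] <- d
    names(wide)[names(wide) == paste0("n_used_", d)] <- paste0("n_", d)
  }
  dplyr::arrange(wide, .data$participant_id, .data$month)
}

#' Score a cohort end-to-end
#'
#' Convenience wrapper: fit the control-baseline reference, standardize
#' all visits, and build the domain-score panel.
#'
#' @inheritParams fit_reference
#' @param ... Passed to [fit_reference()].
#' @return A list with `reference`, `z` (long), and `panel` (wide domain
#'   scores).
#' @export
score_cohort <- function(scores, schema = default_test_schema(), ...) {
  reference <- fit_reference(scores, schema, ...)
  z <- standardize_scores(scores, reference, schema)
  list(reference = reference, z = z,
       panel = domain_scores(z, schema))
}
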