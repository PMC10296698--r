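#' Default neuropsychological test schema
#'
#' The test-to-domain mapping for the two cognitive composites:
#' APE (attention, processing speed, executive function; 7 tests) and
#' LM (learning and memory; 9 tests). Timed tests, where a larger raw
#' score means slower performance, carry `direction = "higher_worse"` and
#' have their z-scores negated during standardization so that higher
#' always means better.
#'
#' When used by the synthetic-cohort generator the schema also carries the
#' generating parameters for each raw test: an affine map of the latent
#' domain score (`offset`, `loading`), measurement noise (`noise_sd`) and a
#' sinh-arcsinh skew tilt (`skew`) so that some tests are visibly
#' non-normal and the Box-Cox step has work to do.
#'
#' @return A tibble with columns `test`, `domain`, `direction`, `offset`,
#'   `loading`, `noise_sd`, `skew`.
#' @examples
#' default_test_schema()
#' @export
default_test_schema <- function() {
  tibble::tribble(
    ~test,                 ~domain, ~direction,     ~offset, ~loading, ~noise_sd, ~skew,
    "digit_symbol",        "APE",   "higher_better",   45,      8.0,      6.0,     0,
    "trails_a",            "APE",   "higher_worse",    35,      7.0,      8.0,     0.6,
    "trails_b",            "APE",   "higher_worse",    90,     20.0,     25.0,     0.8,
    "dkefs_color_word",    "APE",   "higher_worse",    55,     10.0,     10.0,     0.5,
    "nab_digits_forward",  "APE",   "higher_better",    8,      1.5,      1.8,     0,
    "nab_digits_backward", "APE",   "higher_better",    6,      1.5,      1.8,     0,
    "nab_driving_scenes",  "APE",   "higher_better",   45,      6.0,      7.0,     0,
    "nab_list_trial1",     "LM",    "higher_better",    5,      1.2,      1.5,     0,
    "nab_list_semantic",   "LM",    "higher_better",   10,      2.5,      3.0,     0.4,
    "nab_list_a_imm",      "LM",    "higher_better",   25,      5.0,      5.5,     0,
    "nab_list_a_del",      "LM",    "higher_better",    7,      2.0,      2.2,     0,
    "nab_list_long_delay", "LM",    "higher_better",    7,      2.0,      2.2,     0,
    "nab_list_b_imm",      "LM",    "higher_better",    6,      1.8,      2.0,     0,
    "nab_recognition",     "LM",    "higher_better",   17,      1.5,      2.0,    -0.7,
    "logical_memory_1",    "LM",    "higher_better",   40,      9.0,     10.0,     0,
    "logical_memory_2",    "LM",    "higher_better",   25,      8.0,      9.0,     0.3
  )
}

#' Default frailty-indicator schema
#'
#' Forty-four ordinal deficit indicators (coded 0 = absent, 1 =
#' intermediate, 2 = most adverse) spanning functional status,
#' comorbidity, depression, anxiety, fatigue and mobility. Item content is
#' abstracted: the schema carries generic labels plus the generating
#' probabilities used by [simulate_cohort()] — an ordered-logit model with
#' a baseline prevalence, a survivor-group shift, a per-year age gradient
#' and a per-month drift so that deficits accumulate over follow-up.
#'
#' @param n_indicators Number of indicators (default 44).
#' @return A tibble with columns `indicator`, `excluded`, `base_logit`
#'   (logit of P(score >= 1) at the age center for controls), `group_beta`
#'   (survivor shift, logits), `age_beta` (per-year), `month_beta`
#'   (per-month), `sev_gap` (logit gap between P(>=1) and P(=2)).
#' @examples
#' default_indicator_schema()
#' @export
default_indicator_schema <- function(n_indicators = 44) {
  prev <- seq(0.04, 0.40, length.out = n_indicators)
  tibble::tibble(
    indicator = sprintf("i%02d", seq_len(n_indicators)),
    excluded = FALSE,
    base_logit = qlogis(prev),
    group_beta = rep(c(0.35, 0.55, 0.45, 0.25), length.out = n_indicators),
    age_beta = rep(c(0.03, 0.05, 0.04, 0.06), length.out = n_indicators),
    month_beta = rep(c(0.004, 0.008, 0.006, 0.002), length.out = n_indicators),
    sev_gap = rep(c(1.6, 1.4, 1.8, 1.5), length.out = n_indicators)
  )
}

# default age-quartile bins: [60-68], [69-72], [73-76], [77-89]
# stored as right-open upper edges for the first three bins
default_quartile_bins <- function() c(69, 73, 77)

# assign quartile 1..4 from enrollment age given upper edges of bins 1..3
age_quartile <- function(age, bins = default_quartile_bins()) {
  stopifnot(length(bins) == 3L, !is.unsorted(bins))
  findInterval(age, bins) + 1L
}

quartile_labels <- function(bins = default_quartile_bins()) {
  c(sprintf("age <%g", bins[1]),
    sprintf("age %g-%g", bins[1], bins[2] - 1),
    sprintf("age %g-%g", bins[2], bins[3] - 1),
    sprintf("age %g+", bins[3]))
}

# canonical fixed-effect names, intercept block then slope block
gamma_names <- function() {
  c("gamma00", "gamma01", "gamma02", "gamma03", "gamma04", "gamma05",
    "gamma10", "gamma11", "gamma12.2", "gamma12.3", "gamma12.4",
    "gamma13.2", "gamma13.3", "gamma13.4")
}
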