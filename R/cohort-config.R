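#' Configuration for the synthetic cohort generator
#'
#' Bundles every generating parameter of the synthetic survivor/control
#' cohort: sample sizes, the enrollment-age distribution, the visit
#' schedule, the level-2 fixed effects per cognitive domain, the
#' person-level random-effect structure, the per-test measurement model,
#' the frailty-indicator model, missingness and dropout. Defaults emulate
#' the motivating study design: 328 breast-cancer survivors and 158
#' non-cancer controls aged 60-89 (mean 72.5, SD 5.8), assessed at 0, 8,
#' 16 and 24 months, with domain trends set to the fitted posterior means
#' of that study so the generator's ground truth is realistic.
#'
#' @param n_survivors,n_controls Cohort sizes.
#' @param age_range Length-2 numeric, enrollment-age truncation bounds
#'   (years).
#' @param age_mean,age_sd Moments of the (truncated) normal enrollment-age
#'   distribution, years.
#' @param visit_months Strictly increasing month offsets starting at 0.
#' @param true_gammas Named list, one numeric vector of the 14 fixed
#'   effects per domain, in the order given by `cogfrail:::gamma_names()`:
#'   intercept block (overall, age, age^2, survivor, age x survivor,
#'   age^2 x survivor; per-year scale, age centered at `age_mean`) then
#'   slope block (months, months x survivor, months x quartiles 2-4,
#'   survivor x months x quartiles 2-4; per-month scale).
#' @param sigma_alpha,sigma_beta,rho,sigma_eps Random-intercept SD,
#'   random-slope SD, their correlation, and residual SD; scalars are
#'   recycled across domains, or supply one value per domain (named or in
#'   `true_gammas` order).
#' @param quartile_bins Upper edges of the first three baseline
#'   age-quartile bins (default 69, 73, 77, i.e. bins 60-68, 69-72,
#'   73-76, 77-89).
#' @param test_schema Tibble as returned by [default_test_schema()].
#' @param indicator_schema Tibble as returned by
#'   [default_indicator_schema()].
#' @param missing_rate Probability that an individual frailty indicator is
#'   unassessed at a visit.
#' @param dropout_hazard Per-follow-up-visit probability of monotone
#'   dropout (once a visit is missed, all later visits are missed).
#' @param seed Integer root seed; all randomness flows from it.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_survivors = 20, n_controls = 10)
#' cfg$age_mean
#' @export
cohort_config <- function(n_survivors = 328,
                          n_controls = 158,
                          age_range = c(60, 89),
                          age_mean = 72.5,
                          age_sd = 5.8,
                          visit_months = c(0, 8, 16, 24),
                          true_gammas = default_true_gammas(),
                          sigma_alpha = c(APE = 0.60, LM = 0.64),
                          sigma_beta = c(APE = 0.004, LM = 0.005),
                          rho = c(APE = 0.16, LM = 0.27),
                          sigma_eps = c(APE = 0.194, LM = 0.361),
                          quartile_bins = default_quartile_bins(),
                          test_schema = default_test_schema(),
                          indicator_schema = default_indicator_schema(),
                          missing_rate = 0.02,
                          dropout_hazard = 0.05,
                          seed = 20230616) {
  cfg <- list(
    n_survivors = n_survivors, n_controls = n_controls,
    age_range = age_range, age_mean = age_mean, age_sd = age_sd,
    visit_months = visit_months, true_gammas = true_gammas,
    sigma_alpha = sigma_alpha, sigma_beta = sigma_beta, rho = rho,
    sigma_eps = sigma_eps, quartile_bins = quartile_bins,
    test_schema = test_schema, indicator_schema = indicator_schema,
    missing_rate = missing_rate, dropout_hazard = dropout_hazard,
    seed = seed
  )
  validate_cohort_config(cfg)
}

#' Default generating fixed effects
#'
#' Per-domain 14-vectors of level-2 fixed effects used as the generator's
#' ground truth. Values are the posterior means reported for the APE and
#' LM domain models in the motivating cohort (the APE quadratic
#' survivor-difference term is taken as -0.001, the value consistent with
#' its reported interval and the age-65 gap).
#'
#' @return Named list with elements `APE` and `LM`.
#' @export
default_true_gammas <- function() {
  list(
    APE = setNames(c(0.013, -0.047, 0.00001, -0.130, 0.016, -0.001,
                     0.004, 0.0002, 0.001, -0.002, -0.008,
                     -0.001, 0.0004, 0.005), gamma_names()),
    LM = setNames(c(0.048, -0.048, -0.0006, -0.205, 0.012, 0.0004,
                    0.019, -0.0029, 0.0006, -0.007, -0.007,
                    0.0005, 0.0073, 0.0053), gamma_names())
  )
}

# recycle a possibly-scalar per-domain parameter to the domain names
recycle_domains <- function(x, domains, field) {
  if (length(x) == 1L) return(setNames(rep(x, length(domains)), domains))
  if (!is.null(names(x))) {
    if (!all(domains %in% names(x)))
      cf_abort(sprintf("config field '%s' lacks values for domain(s): %s",
                       field, paste(setdiff(domains, names(x)), collapse = ", ")),
               "cogfrail_config_error")
    return(x[domains])
  }
  if (length(x) != length(domains))
    cf_abort(sprintf("config field '%s' must be scalar or one value per domain", field),
             "cogfrail_config_error")
  setNames(x, domains)
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, msg)
    cf_abort(sprintf("invalid config field '%s': %s", field, msg),
             "cogfrail_config_error")

  if (length(cfg$n_survivors) != 1L || cfg$n_survivors < 0 ||
      cfg$n_survivors != round(cfg$n_survivors))
    bad("n_survivors", "must be a non-negative integer")
  if (length(cfg$n_controls) != 1L || cfg$n_controls < 0 ||
      cfg$n_controls != round(cfg$n_controls))
    bad("n_controls", "must be a non-negative integer")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    bad("age_range", "must be an increasing pair of years")
  if (cfg$age_sd <= 0) bad("age_sd", "must be positive")
  vm <- cfg$visit_months
  if (length(vm) < 1L || vm[1] != 0 || is.unsorted(vm, strictly = TRUE))
    bad("visit_months", "must be strictly increasing and start at 0")

  if (!is.list(cfg$true_gammas) || is.null(names(cfg$true_gammas)))
    bad("true_gammas", "must be a named list of per-domain coefficient vectors")
  domains <- names(cfg$true_gammas)
  for (d in domains) {
    g <- cfg$true_gammas[[d]]
    if (length(g) != 14L || anyNA(g))
      bad("true_gammas", sprintf("domain '%s' must have 14 finite values", d))
    names(cfg$true_gammas[[d]]) <- gamma_names()
  }
  for (f in c("sigma_alpha", "sigma_beta", "sigma_eps")) {
    cfg[[f]] <- recycle_domains(cfg[[f]], domains, f)
    if (any(cfg[[f]] <= 0)) bad(f, "must be positive")
  }
  cfg$rho <- recycle_domains(cfg$rho, domains, "rho")
  if (any(cfg$rho <= -1 | cfg$rho >= 1)) bad("rho", "must lie in (-1, 1)")

  if (length(cfg$quartile_bins) != 3L || is.unsorted(cfg$quartile_bins))
    bad("quartile_bins", "must be three increasing upper edges")
  check_columns(cfg$test_schema,
                c("test", "domain", "direction", "offset", "loading",
                  "noise_sd", "skew"), "test_schema")
  if (!all(cfg$test_schema$domain %in% domains))
    bad("test_schema", "contains domains absent from true_gammas")
  if (!all(cfg$test_schema$direction %in% c("higher_better", "higher_worse")))
    bad("test_schema", "direction must be higher_better or higher_worse")
  check_columns(cfg$indicator_schema,
                c("indicator", "excluded", "base_logit", "group_beta",
                  "age_beta", "month_beta", "sev_gap"), "indicator_schema")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    bad("missing_rate", "must be a probability in [0, 1]")
  if (cfg$dropout_hazard < 0 || cfg$dropout_hazard > 1)
    bad("dropout_hazard", "must be a probability in [0, 1]")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    bad("seed", "must be a single integer")

  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d survivors, %d controls; ages %g-%g (mean %g, sd %g)\n",
              x$n_survivors, x$n_controls, x$age_range[1], x$age_range[2],
              x$age_mean, x$age_sd))
  cat(sprintf("  visits at months %s; domains: %s\n",
              paste(x$visit_months, collapse = ", "),
              paste(names(x$true_gammas), collapse = ", ")))
  cat(sprintf("  %d tests, %d indicators; missing_rate %g, dropout_hazard %g, seed %d\n",
              nrow(x$test_schema), nrow(x$indicator_schema),
              x$missing_rate, x$dropout_hazard, as.integer(x$seed)))
  invisible(x)
}
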