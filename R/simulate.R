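#' Simulate a synthetic survivor/control cohort
#'
#' Draws a longitudinal cohort with the structure the downstream analysis
#' assumes, from known ground-truth parameters. Per participant:
#' enrollment age from a truncated normal; a latent intercept/slope pair
#' per cognitive domain whose means follow the level-2 model (quadratic
#' centered-age trend per group for intercepts; group and baseline
#' age-quartile effects for slopes) and whose deviations are bivariate
#' normal with SDs `sigma_alpha`, `sigma_beta` and correlation `rho`. Per
#' visit: an observed latent domain value (truth plus `Normal(0,
#' sigma_eps)` residual), raw test scores as per-test affine transforms of
#' that value plus sinh-arcsinh-skewed noise, and ordinal frailty
#' indicators from an ordered-logit model with group, age and follow-up
#' effects. Dropout is monotone with a constant per-visit hazard;
#' indicators are independently missing at `missing_rate`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_sim`: a list of tibbles
#'   \describe{
#'     \item{scores}{one row per retained participant-visit:
#'       `participant_id`, `group`, `age_enroll`, `month`, one column per
#'       raw test.}
#'     \item{indicators}{`participant_id`, `month`, one 0/1/2/`NA` column
#'       per indicator.}
#'     \item{latent}{the ground-truth domain observations
#'       (`participant_id`, `month`, one column per domain) that the raw
#'       tests are built from, for validation.}
#'     \item{participants}{per-person truth: group, age, quartile, and the
#'       latent `(alpha, beta)` per domain.}
#'   }
#'   plus the `config` used.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_survivors = 12, n_controls = 8))
#' dplyr::count(sim$scores, month)
#' @export
simulate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  domains <- names(cfg$true_gammas)
  n <- cfg$n_survivors + cfg$n_controls
  if (n == 0L)
    cf_abort("config yields an empty cohort (no survivors, no controls)",
             "cogfrail_config_error")

  participants <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    group = rep(c("survivor", "control"), c(cfg$n_survivors, cfg$n_controls)),
    age_enroll = rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                            cfg$age_range[1], cfg$age_range[2])
  )
  participants$quartile <- age_quartile(participants$age_enroll,
                                        cfg$quartile_bins)
  S <- as.integer(participants$group == "survivor")
  cage <- participants$age_enroll - cfg$age_mean
  Xa <- cbind(1, cage, cage^2, S, S * cage, S * cage^2)
  Q <- outer(participants$quartile, 2:4, `==`) + 0
  Xb <- cbind(1, S, Q, S * Q)

  # latent (alpha, beta) per domain; domains independent given the design
  for (d in domains) {
    g <- cfg$true_gammas[[d]]
    mu_a <- drop(Xa %*% g[1:6])
    mu_b <- drop(Xb %*% g[7:14])
    sa <- cfg$sigma_alpha[[d]]; sb <- cfg$sigma_beta[[d]]; r <- cfg$rho[[d]]
    u <- rnorm(n, 0, sa)
    v <- rnorm(n, r * sb / sa * u, sb * sqrt(1 - r^2))
    participants[[paste0("alpha_", d)]] <- mu_a + u
    participants[[paste0("beta_", d)]] <- mu_b + v
  }

  # monotone dropout: participant completes the first k visits
  n_visits <- length(cfg$visit_months)
  k_obs <- if (n_visits == 1L) rep(1L, n) else {
    miss <- matrix(rbinom(n * (n_visits - 1L), 1L, cfg$dropout_hazard),
                   nrow = n)
    apply(miss, 1, function(m) {
      first <- which(m == 1L)
      if (length(first) == 0L) n_visits else first[1]
    })
  }

  visits <- tidyr::crossing(idx = seq_len(n),
                            month = cfg$visit_months) |>
    dplyr::mutate(visit_no = match(.data$month, cfg$visit_months)) |>
    dplyr::filter(.data$visit_no <= k_obs[.data$idx]) |>
    dplyr::arrange(.data$idx, .data$month)

  base <- tibble::tibble(
    participant_id = participants$participant_id[visits$idx],
    group = participants$group[visits$idx],
    age_enroll = participants$age_enroll[visits$idx],
    month = visits$month
  )
  nv <- nrow(base)

  # observed latent domain values: truth + residual
  latent <- base[, c("participant_id", "month")]
  for (d in domains) {
    truth <- participants[[paste0("alpha_", d)]][visits$idx] +
      participants[[paste0("beta_", d)]][visits$idx] * visits$month
    latent[[d]] <- truth + rnorm(nv, 0, cfg$sigma_eps[[d]])
  }

  # raw tests: offset + sign * loading * latent + skewed noise
  scores <- base
  ts <- cfg$test_schema
  for (j in seq_len(nrow(ts))) {
    sgn <- if (ts$direction[j] == "higher_worse") -1 else 1
    noise <- sinh_arcsinh_noise(nv, ts$skew[j]) * ts$noise_sd[j]
    scores[[ts$test[j]]] <-
      ts$offset[j] + sgn * ts$loading[j] * latent[[ts$domain[j]]] + noise
  }

  indicators <- simulate_indicators(cfg, base)

  structure(list(scores = scores, indicators = indicators, latent = latent,
                 participants = participants, config = config_as_class(cfg)),
            class = "cohort_sim")
}

config_as_class <- function(cfg) structure(cfg, class = "cohort_config")

# sinh-arcsinh tilt of standard normal noise; skew = 0 is exactly Gaussian
sinh_arcsinh_noise <- function(n, skew) {
  z <- rnorm(n)
  if (skew == 0) z else sinh(asinh(z) + skew)
}

simulate_indicators <- function(cfg, base) {
  sch <- cfg$indicator_schema
  out <- base[, c("participant_id", "month")]
  S <- as.integer(base$group == "survivor")
  cage <- base$age_enroll - cfg$age_mean
  nv <- nrow(base)
  for (j in seq_len(nrow(sch))) {
    lin <- sch$base_logit[j] + sch$group_beta[j] * S +
      sch$age_beta[j] * cage + sch$month_beta[j] * base$month
    p1 <- plogis(lin)              # P(score >= 1)
    p2 <- plogis(lin - sch$sev_gap[j])  # P(score == 2)
    u <- runif(nv)
    val <- ifelse(u < p2, 2L, ifelse(u < p1, 1L, 0L))
    val[runif(nv) < cfg$missing_rate] <- NA_integer_
    out[[sch$indicator[j]]] <- val
  }
  out
}

#' Ground-truth survivor-control gap over age
#'
#' Evaluates the generating cross-sectional difference between survivors
#' and controls, `gamma03 + gamma04*(a - center) + gamma05*(a - center)^2`,
#' on an age grid. Serves as the analytic oracle for [gap_curve()].
#'
#' @param config A [cohort_config()].
#' @param ages Numeric age grid (years), within `config$age_range`.
#' @param domain Which domain's coefficients to use.
#' @return A tibble with columns `age` and `diff` (outcome units,
#'   survivor minus control).
#' @examples
#' true_gap_curve(cohort_config(), ages = c(65, 72.5, 80))
#' @export
true_gap_curve <- function(config, ages = seq(60, 89, by = 0.1),
                           domain = names(config$true_gammas)[1]) {
  config <- validate_cohort_config(unclass(config))
  if (any(ages < config$age_range[1] - 1e-9 |
          ages > config$age_range[2] + 1e-9))
    cf_abort("ages outside config age_range", "cogfrail_config_error")
  g <- config$true_gammas[[domain]]
  if (is.null(g)) cf_abort(sprintf("unknown domain '%s'", domain))
  a <- ages - config$age_mean
  tibble::tibble(age = ages,
                 diff = g[["gamma03"]] + g[["gamma04"]] * a +
                   g[["gamma05"]] * a^2)
}

#' Write a simulated cohort to disk
#'
#' Writes the two visit-level CSV tables (raw test scores; frailty
#' indicators) and a JSON sidecar with the generating parameters.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scores = file.path(dir, "cohort_scores.csv"),
    indicators = file.path(dir, "cohort_indicators.csv"),
    truth = file.path(dir, "cohort_truth.json")
  )
  readr::write_csv(sim$scores, paths[["scores"]])
  readr::write_csv(sim$indicators, paths[["indicators"]])
  cfg <- unclass(sim$config)
  cfg$test_schema <- as.data.frame(cfg$test_schema)
  cfg$indicator_schema <- as.data.frame(cfg$indicator_schema)
  jsonlite::write_json(
    list(config = cfg, participants = as.data.frame(sim$participants)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>\n")
  cat(sprintf("  %d participants, %d visit records, %d tests, %d indicators\n",
              nrow(x$participants), nrow(x$scores),
              nrow(x$config$test_schema), nrow(x$config$indicator_schema)))
  invisible(x)
}
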