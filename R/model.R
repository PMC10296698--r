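#' MCMC preset configurations
#'
#' `"test"` is the desk-scale default (4 chains of 2,000 iterations with
#' 500 warmup, no thinning); `"paper"` is the heavyweight regime used for
#' publication-grade runs (4 chains of 60,000 iterations, 10,000 warmup,
#' thinning interval 5).
#'
#' @param preset `"test"` or `"paper"`, or a list with elements `chains`,
#'   `iterations` (total per chain, including warmup), `warmup`, `thin`,
#'   `adapt` which is passed through after validation.
#' @return A validated list of sampler settings.
#' @examples
#' mcmc_preset("test")
#' @export
mcmc_preset <- function(preset = "test") {
  if (is.list(preset)) {
    out <- utils::modifyList(
      list(chains = 4L, iterations = 2000L, warmup = 500L, thin = 1L,
           adapt = 500L), preset)
  } else {
    out <- switch(match.arg(preset, c("test", "paper")),
      test = list(chains = 4L, iterations = 2000L, warmup = 500L,
                  thin = 1L, adapt = 500L),
      paper = list(chains = 4L, iterations = 60000L, warmup = 10000L,
                   thin = 5L, adapt = 1000L))
  }
  stopifnot(out$chains >= 2L, out$iterations > out$warmup, out$thin >= 1L)
  out
}

# JAGS code for the varying-intercepts/varying-slopes model.
# Level 1: y_it ~ N(alpha_i + beta_i * month_it, sigma_eps^2).
# Level 2: alpha_i ~ N(Xa_i gamma_a, sigma_alpha^2); beta_i given alpha_i
# is the conditional of the bivariate normal with SDs (sigma_alpha,
# sigma_beta) and correlation rho — identical to the joint Omega
# formulation but samples far faster with JAGS's glm module.
trajectory_model_code <- "
model {
  for (j in 1:N) {
    y[j] ~ dnorm(alpha[pid[j]] + beta[pid[j]] * month[j], tau_eps)
  }
  for (i in 1:P) {
    mu_a[i] <- inprod(Xa[i, ], ga[])
    mu_b[i] <- inprod(Xb[i, ], gb[])
    alpha[i] ~ dnorm(mu_a[i], tau_a)
    beta[i] ~ dnorm(mu_b[i] + lam * (alpha[i] - mu_a[i]), tau_bc)
  }
  for (k in 1:Ka) { ga[k] ~ dnorm(prior_mean_a[k], pow(prior_sd_a[k], -2)) }
  for (k in 1:Kb) { gb[k] ~ dnorm(prior_mean_b[k], pow(prior_sd_b[k], -2)) }
  # small positive floors (0.1% of the prior scale) and a correlation
  # bound just inside (-1, 1) keep the conditional precisions finite when
  # degenerate data drive a variance component to zero
  sigma_alpha ~ dnorm(0, pow(sigma_scale_a, -2)) T(1.0E-3 * sigma_scale_a,)
  sigma_beta  ~ dnorm(0, pow(sigma_scale_b, -2)) T(1.0E-3 * sigma_scale_b,)
  sigma_eps   ~ dnorm(0, pow(sigma_scale_e, -2)) T(1.0E-3 * sigma_scale_e,)
  rho ~ dunif(-0.999, 0.999)
  lam    <- rho * sigma_beta / sigma_alpha
  tau_a  <- pow(sigma_alpha, -2)
  tau_bc <- pow(sigma_beta, -2) / (1 - rho^2)
  tau_eps <- pow(sigma_eps, -2)
}"

# weakly informative autoscaled prior SDs, rstanarm-style:
# 2.5 * sd(y) / sd(x) for intercept-block columns, additionally divided
# by sd(month) for slope-block columns (their coefficients act per month)
autoscale_priors <- function(input, gamma_scale = 2.5, sigma_scale = 2.5) {
  sdy <- sd(input$obs$y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  sdm <- sd(input$obs$month)
  if (!is.finite(sdm) || sdm == 0) sdm <- 1
  colsd <- function(X) {
    s <- apply(X, 2, sd)
    s[1] <- 1               # intercept column
    s[!is.finite(s) | s < 1e-8] <- 1  # degenerate columns keep unit scale
    s
  }
  list(prior_mean_a = rep(0, ncol(input$Xa)),
       prior_mean_b = rep(0, ncol(input$Xb)),
       prior_sd_a = gamma_scale * sdy / colsd(input$Xa),
       prior_sd_b = gamma_scale * sdy / (colsd(input$Xb) * sdm),
       sigma_scale_a = sigma_scale * sdy,
       sigma_scale_b = sigma_scale * sdy / sdm,
       sigma_scale_e = sigma_scale * sdy)
}

#' Fit the Bayesian varying-intercepts/varying-slopes model
#'
#' Fits, by MCMC (JAGS), the two-level growth model: each participant's
#' repeated outcomes are summarized by a latent intercept (their
#' practice-free first-assessment level) and slope (their longitudinal
#' change per month, confounded with practice). Intercepts follow a
#' quadratic function of centered enrollment age with separate survivor
#' offsets (`gamma03`-`gamma05`); slopes depend on group and baseline age
#' quartile (`gamma10`-`gamma13.4`); intercepts and slopes are correlated
#' (`rho`) with SDs `sigma_alpha`, `sigma_beta`; residual SD `sigma_eps`.
#'
#' Priors are weakly informative and autoscaled to the data (Normal with
#' SD `2.5 sd(y)/sd(x)` for fixed effects, half-Normal for SDs, uniform
#' on (-1, 1) for `rho`); override via `priors`.
#'
#' @param input A `model_input` from [build_design()].
#' @param mcmc Preset name or list, see [mcmc_preset()].
#' @param priors Optional named list overriding any element of the
#'   autoscaled prior list (`prior_mean_a`, `prior_sd_a`, `prior_mean_b`,
#'   `prior_sd_b`, `sigma_scale_a`, `sigma_scale_b`, `sigma_scale_e`).
#' @param seed Integer sampler seed (one RNG stream per chain is derived
#'   from it); recorded in the result.
#' @param rhat_threshold Convergence threshold (default 1.01). Parameters
#'   exceeding it trigger a warning and are flagged in the result — never
#'   silently.
#' @return An object of class `cog_fit`: posterior draw matrix (`draws`,
#'   merged across chains, named columns), the per-chain
#'   [coda::mcmc.list] (`chains`), a `summary` tibble (term, posterior
#'   mean, sd, 95% HDI, R-hat), convergence and identifiability flags,
#'   and the design metadata. Use [tidy()] / [glance()] to extract
#'   summaries and [gap_curve()] for survivor-control contrasts.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_config(n_survivors = 40, n_controls = 30))
#' pan <- dplyr::left_join(sim$latent,
#'   sim$participants[, c("participant_id", "group", "age_enroll")],
#'   by = "participant_id")
#' fit <- fit_trajectory_model(build_design(pan, "APE"),
#'                             mcmc = list(chains = 2, iterations = 600,
#'                                         warmup = 200))
#' tidy(fit)
#' }
#' @export
fit_trajectory_model <- function(input, mcmc = "test", priors = NULL,
                                 seed = 1L, rhat_threshold = 1.01) {
  stopifnot(inherits(input, "model_input"))
  mc <- mcmc_preset(mcmc)
  pr <- autoscale_priors(input)
  if (!is.null(priors)) pr <- utils::modifyList(pr, priors)

  slope_identified <- length(unique(input$obs$month)) >= 2L
  if (!slope_identified)
    warn(paste("only one distinct visit month: slope and random-slope",
               "parameters are not identified and revert to their priors"),
         class = "cogfrail_identifiability_warning")

  dat <- c(list(y = input$obs$y, pid = input$obs$pid,
                month = input$obs$month, N = nrow(input$obs),
                P = nrow(input$participants),
                Xa = input$Xa, Xb = input$Xb,
                Ka = ncol(input$Xa), Kb = ncol(input$Xb)),
           pr)

  # start the scale parameters strictly inside their support
  sdy0 <- sd(input$obs$y)
  if (!is.finite(sdy0) || sdy0 == 0) sdy0 <- 1
  inits <- lapply(seq_len(mc$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 97L + k) %% 2147483629L + 1L,
         sigma_alpha = sdy0, sigma_beta = sdy0 / 20, sigma_eps = sdy0,
         rho = 0))

  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(trajectory_model_code),
                          data = dat, inits = inits,
                          n.chains = mc$chains, n.adapt = mc$adapt,
                          quiet = TRUE)
  stats::update(jm, mc$warmup, progress.bar = "none")
  monitors <- c("ga", "gb", "sigma_alpha", "sigma_beta", "rho",
                "sigma_eps")
  chains <- rjags::coda.samples(jm, monitors,
                                n.iter = mc$iterations - mc$warmup,
                                thin = mc$thin, progress.bar = "none")

  chains <- rename_chains(chains)
  draws <- as.matrix(chains)
  terms <- colnames(draws)
  rhats <- vapply(terms, function(p)
    rhat(sapply(chains, function(ch) as.numeric(ch[, p]))), numeric(1))
  hdis <- t(apply(draws, 2, hdi_unchecked, prob = 0.95))
  summary <- tibble::tibble(
    term = terms,
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    hdi_lower = unname(hdis[, 1]), hdi_upper = unname(hdis[, 2]),
    rhat = unname(rhats))

  converged <- all(is.nan(rhats) | rhats <= rhat_threshold)
  if (!converged)
    warn(sprintf("R-hat above %g for: %s (max %.3f); increase iterations",
                 rhat_threshold,
                 paste(terms[!is.nan(rhats) & rhats > rhat_threshold],
                       collapse = ", "),
                 max(rhats, na.rm = TRUE)),
         class = "cogfrail_convergence_warning")

  structure(list(draws = draws, chains = chains, summary = summary,
                 converged = converged, rhat_threshold = rhat_threshold,
                 slope_identified = slope_identified,
                 input = input, mcmc = mc, seed = as.integer(seed),
                 priors = pr),
            class = "cog_fit")
}

# map JAGS node names (ga[1], gb[3], ...) onto the canonical gamma names
rename_chains <- function(chains) {
  nm <- coda::varnames(chains)
  gn <- gamma_names()
  map <- setNames(nm, nm)
  for (k in 1:6) map[sprintf("ga[%d]", k)] <- gn[k]
  for (k in 1:8) map[sprintf("gb[%d]", k)] <- gn[6 + k]
  for (i in seq_along(chains)) colnames(chains[[i]]) <- unname(map[nm])
  chains
}

#' @export
print.cog_fit <- function(x, ...) {
  cat(sprintf("<cog_fit> outcome '%s': %d obs, %d participants; %d chains x %d kept draws\n",
              x$input$outcome, nrow(x$input$obs), nrow(x$input$participants),
              x$mcmc$chains, nrow(x$draws) / x$mcmc$chains))
  cat(sprintf("  converged (R-hat <= %g): %s\n", x$rhat_threshold,
              if (x$converged) "yes" else "NO"))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Tidy a fitted trajectory model
#'
#' One row per model parameter with posterior mean, posterior SD, 95%
#' highest-density interval and split R-hat.
#'
#' @param x A `cog_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `hdi_lower`, `hdi_upper`, `rhat`.
#' @export
tidy.cog_fit <- function(x, ...) x$summary

#' One-row model fit summary
#'
#' @param x A `cog_fit`.
#' @param ... Unused.
#' @return A one-row tibble: data/draw sizes, max R-hat, convergence and
#'   slope-identifiability flags, centering constant and seed.
#' @export
glance.cog_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$input$outcome,
    n_obs = nrow(x$input$obs),
    n_participants = nrow(x$input$participants),
    chains = x$mcmc$chains,
    draws = nrow(x$draws),
    max_rhat = suppressWarnings(max(x$summary$rhat, na.rm = TRUE)),
    converged = x$converged,
    slope_identified = x$slope_identified,
    center = x$input$center,
    seed = x$seed)
}
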