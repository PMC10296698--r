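# shared fixtures: small configs and a joined latent-outcome panel

tiny_mcmc <- list(chains = 2L, iterations = 700L, warmup = 250L,
                  adapt = 200L)

small_config <- function(...) {
  cohort_config(n_survivors = 40, n_controls = 30, seed = 42, ...)
}

# panel of ground-truth domain observations with participant covariates,
# the natural input for parameter-recovery fits
latent_panel <- function(sim) {
  dplyr::left_join(
    sim$latent,
    sim$participants[, c("participant_id", "group", "age_enroll")],
    by = "participant_id")
}

# independent DAFI oracle: plain arithmetic, no package code
dafi_oracle <- function(values, min_assessed = 35) {
  n <- sum(!is.na(values))
  if (n < min_assessed) return(NA_real_)
  sum(values[!is.na(values)]) / (2 * n)
}
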