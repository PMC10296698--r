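test_that("record count is participants x visits when dropout is off", {
  cfg <- cohort_config(n_survivors = 0, n_controls = 10,
                       dropout_hazard = 0, seed = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$scores), 40L)
  expect_true(all(sim$scores$group == "control"))
  expect_equal(nrow(sim$indicators), 40L)
})

test_that("identical config and seed give identical output tables", {
  cfg <- small_config()
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$indicators, s2$indicators)
  expect_identical(s1$participants, s2$participants)
})

test_that("with variance switched off the domain truth equals the level-2 polynomial", {
  schema <- default_test_schema()[c(1, 8), ]
  schema$offset <- 0; schema$loading <- 1
  schema$noise_sd <- 1e-12; schema$skew <- 0
  schema$direction <- "higher_better"
  cfg <- cohort_config(n_survivors = 25, n_controls = 25,
                       sigma_alpha = 1e-9, sigma_beta = 1e-9,
                       sigma_eps = 1e-9, dropout_hazard = 0,
                       test_schema = schema, seed = 9)
  sim <- simulate_cohort(cfg)
  base <- dplyr::filter(sim$scores, month == 0)
  # oracle: evaluate the intercept polynomial directly
  cage <- base$age_enroll - cfg$age_mean
  S <- as.integer(base$group == "survivor")
  g <- cfg$true_gammas$APE
  truth <- g[["gamma00"]] + g[["gamma01"]] * cage + g[["gamma02"]] * cage^2 +
    S * (g[["gamma03"]] + g[["gamma04"]] * cage + g[["gamma05"]] * cage^2)
  expect_equal(base$digit_symbol, truth, tolerance = 1e-6)
})

test_that("age marginals match the config at large n and rho sign is recoverable", {
  cfg <- cohort_config(n_survivors = 2500, n_controls = 2500,
                       rho = 0.6, sigma_beta = 0.02, sigma_eps = 0.1,
                       dropout_hazard = 0, seed = 11)
  sim <- simulate_cohort(cfg)
  age <- sim$participants$age_enroll
  expect_lt(abs(mean(age) - cfg$age_mean) / cfg$age_mean, 0.02)
  expect_lt(abs(sd(age) - cfg$age_sd) / cfg$age_sd, 0.1)
  expect_true(all(age >= 60 & age <= 89))
  # per-person OLS intercept/slope correlation carries the sign of rho
  pan <- latent_panel(sim)
  ols <- pan |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(int = coef(lm(APE ~ month))[1],
                     slp = coef(lm(APE ~ month))[2])
  expect_gt(cor(ols$int, ols$slp), 0)
})

test_that("dropout is monotone: no visit without all earlier visits", {
  cfg <- cohort_config(n_survivors = 80, n_controls = 40,
                       dropout_hazard = 0.3, seed = 13)
  sim <- simulate_cohort(cfg)
  by_p <- split(sim$scores$month, sim$scores$participant_id)
  for (m in by_p) {
    expect_equal(sort(m), cfg$visit_months[seq_along(m)])
  }
  expect_lt(length(unlist(by_p)), 120 * 4)  # some dropout happened
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(cohort_config(n_survivors = -1), "n_survivors")
  expect_error(cohort_config(visit_months = c(8, 16)), "visit_months")
  expect_error(cohort_config(rho = 1.2), "rho")
  expect_error(cohort_config(sigma_eps = 0), "sigma_eps")
  expect_error(cohort_config(missing_rate = 2), "missing_rate")
  expect_error(cohort_config(true_gammas = list(APE = 1:3)), "true_gammas")
})

test_that("true_gap_curve evaluates the group-difference quadratic", {
  zeros <- setNames(rep(0, 14), cogfrail:::gamma_names())
  cfg0 <- small_config(true_gammas = list(APE = zeros, LM = zeros))
  expect_true(all(true_gap_curve(cfg0, 60:89)$diff == 0))
  # at the centering age only the intercept difference remains
  cfg <- cohort_config()
  expect_equal(true_gap_curve(cfg, 72.5, domain = "LM")$diff, -0.205)
  # hand-evaluated quadratic at age 65
  expect_equal(true_gap_curve(cfg, 65, domain = "APE")$diff,
               -0.130 + 0.016 * (-7.5) + (-0.001) * 56.25)
  expect_error(true_gap_curve(cfg, 120), "age_range")
})

test_that("simulated indicators are valid ordinal codes with missingness", {
  sim <- simulate_cohort(small_config(missing_rate = 0.1))
  vals <- unlist(sim$indicators[, -(1:2)])
  expect_true(all(is.na(vals) | vals %in% 0:2))
  expect_gt(mean(is.na(vals)), 0.05)
  expect_lt(mean(is.na(vals)), 0.15)
})

test_that("write_cohort writes the CSV tables and truth sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cohort_config(n_survivors = 5, n_controls = 5))
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["scores"]], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$scores))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$config$n_survivors, 5L)
})
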