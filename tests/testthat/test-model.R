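test_that("HDI is the shortest window of sorted draws", {
  # uniform 1..100 at 95%: window of 95 values, lowest start wins ties
  h <- hdi(1:100, prob = 0.95)
  expect_equal(unname(h), c(1, 95))
  # all draws equal: zero-width interval at that value
  expect_equal(unname(hdi(rep(3.5, 200))), c(3.5, 3.5))
  expect_error(hdi(rnorm(200), prob = 1.2), "between 0 and 1")
  expect_error(hdi(rnorm(50)), "100 draws")
})

test_that("HDI approximates the equal-tailed interval for symmetric draws", {
  set.seed(10)
  x <- rnorm(100000)
  h <- hdi(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_equal(unname(h), unname(q), tolerance = 0.05)
})

test_that("split R-hat detects chain disagreement and accepts agreement", {
  set.seed(11)
  base <- rnorm(1000)
  expect_equal(rhat(cbind(base, base)), 1, tolerance = 0.01)
  far <- cbind(rnorm(1000, -10), rnorm(1000, 10))
  expect_gt(rhat(far), 5)
  # direct-formula oracle on the split chains
  split <- cbind(far[1:500, ], far[501:1000, ])
  W <- mean(apply(split, 2, var))
  B <- 500 * var(colMeans(split))
  expect_equal(rhat(far), sqrt((499 / 500 * W + B / 500) / W))
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(6), ncol = 2)), "length")
})

test_that("design builder centers age, assigns quartiles and reports rejects", {
  pan <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    group = c("survivor", "control", "survivor", "control", NA, "survivor"),
    age_enroll = c(72.5, 68, 69, 77, 70, NA),
    month = 0, y = rnorm(6))
  inp <- build_design(pan, "y", center = 72.5)
  expect_equal(nrow(inp$rejects), 2L)
  pp <- inp$participants
  expect_equal(pp$cage[pp$age_enroll == 72.5], 0)
  expect_equal(pp$quartile[pp$age_enroll == 68], 1L)
  expect_equal(pp$quartile[pp$age_enroll == 69], 2L)
  expect_equal(pp$quartile[pp$age_enroll == 77], 4L)
  # auto-centering rounds the mean age to 0.1
  inp2 <- build_design(pan, "y")
  expect_equal(inp2$center, round(mean(pp$age_enroll), 1))
})

test_that("model recovers generating coefficients on a clean synthetic cohort", {
  cfg <- cohort_config(n_survivors = 120, n_controls = 80, seed = 21)
  sim <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_trajectory_model(build_design(latent_panel(sim), "APE",
                                      center = 72.5),
                         mcmc = "test", seed = 22))
  s <- tidy(fit)
  # the strongly identified parameters sit near their generating values
  g01 <- s[s$term == "gamma01", ]
  expect_true(g01$hdi_lower <= -0.047 && -0.047 <= g01$hdi_upper)
  expect_equal(s$estimate[s$term == "sigma_alpha"], 0.60, tolerance = 0.15)
  expect_equal(s$estimate[s$term == "sigma_eps"], 0.194, tolerance = 0.15)
  expect_true(all(s$hdi_lower <= s$estimate & s$estimate <= s$hdi_upper))
})

test_that("null data give null posteriors", {
  pan <- tidyr::crossing(participant_id = sprintf("P%d", 1:40),
                         month = c(0, 8, 16, 24)) |>
    dplyr::mutate(group = rep(c("survivor", "control"), each = 80),
                  age_enroll = rep(seq(61, 88, length.out = 40), each = 4),
                  y = 0)
  fit <- suppressWarnings(
    fit_trajectory_model(build_design(pan, "y"), mcmc = tiny_mcmc,
                         seed = 5))
  s <- dplyr::filter(tidy(fit), grepl("^gamma", term))
  expect_true(all(s$hdi_lower <= 0 & 0 <= s$hdi_upper))
  expect_true(all(abs(s$estimate) < 0.5))
})

test_that("single-visit data complete with a non-identified slope flag", {
  pan <- tibble::tibble(participant_id = sprintf("P%d", 1:30),
                        group = rep(c("survivor", "control"), 15),
                        age_enroll = seq(61, 88, length.out = 30),
                        month = 0, y = rnorm(30))
  expect_warning(
    fit <- suppressWarnings(
      fit_trajectory_model(build_design(pan, "y"), mcmc = tiny_mcmc,
                           seed = 6),
      classes = "cogfrail_convergence_warning"),
    class = "cogfrail_identifiability_warning")
  expect_false(fit$slope_identified)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("a degenerate age design (all ages equal) still fits", {
  pan <- tidyr::crossing(participant_id = sprintf("P%d", 1:20),
                         month = c(0, 8)) |>
    dplyr::mutate(group = rep(c("survivor", "control"), each = 20),
                  age_enroll = 72.5, y = rnorm(40))
  fit <- suppressWarnings(
    fit_trajectory_model(build_design(pan, "y", center = 72.5),
                         mcmc = tiny_mcmc, seed = 7))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 18L)
})

test_that("swapping group labels negates the survivor-difference terms", {
  cfg <- cohort_config(n_survivors = 60, n_controls = 60, seed = 31)
  sim <- simulate_cohort(cfg)
  pan <- latent_panel(sim)
  swapped <- dplyr::mutate(pan, group = ifelse(group == "survivor",
                                               "control", "survivor"))
  f1 <- suppressWarnings(fit_trajectory_model(
    build_design(pan, "APE", center = 72.5), mcmc = tiny_mcmc, seed = 32))
  f2 <- suppressWarnings(fit_trajectory_model(
    build_design(swapped, "APE", center = 72.5), mcmc = tiny_mcmc,
    seed = 33))
  for (term in c("gamma03", "gamma11")) {
    m1 <- tidy(f1)$estimate[tidy(f1)$term == term]
    m2 <- tidy(f2)$estimate[tidy(f2)$term == term]
    se <- tidy(f1)$std.error[tidy(f1)$term == term] +
      tidy(f2)$std.error[tidy(f2)$term == term]
    expect_lt(abs(m1 + m2), 3 * se + 0.01)
  }
})

test_that("with one nearly uninformative observation posteriors revert to priors", {
  pan <- tibble::tibble(participant_id = "P1", group = "control",
                        age_enroll = 72.5, month = 0, y = 0)
  inp <- build_design(pan, "y", center = 72.5)
  fit <- suppressWarnings(fit_trajectory_model(
    inp, mcmc = tiny_mcmc, seed = 8,
    priors = list(prior_sd_a = rep(2, 6), prior_sd_b = rep(0.1, 8),
                  sigma_scale_e = 50)))
  s <- tidy(fit)
  # location parameters outside the single point's reach keep prior scale
  expect_gt(s$std.error[s$term == "gamma01"], 1)
  expect_lt(abs(s$estimate[s$term == "gamma01"]), 0.5)
})

test_that("sampler runs are reproducible given the same seed", {
  pan <- latent_panel(simulate_cohort(small_config()))
  inp <- build_design(pan, "APE")
  f1 <- suppressWarnings(fit_trajectory_model(inp, mcmc = tiny_mcmc,
                                              seed = 99))
  f2 <- suppressWarnings(fit_trajectory_model(inp, mcmc = tiny_mcmc,
                                              seed = 99))
  expect_identical(f1$draws, f2$draws)
})
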