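test_that("normality screen keys on absolute skewness", {
  x <- rnorm(200)
  sym <- c(x, 2 * mean(x) - x)  # exactly mirrored: skewness 0
  expect_equal(assess_normality(sym), "normal")
  set.seed(1)
  expect_equal(assess_normality(rexp(500)), "non_normal")
  expect_error(assess_normality(rep(1, 50)), "variance")
  expect_error(assess_normality(rnorm(10)), "at least 20")
})

test_that("Box-Cox recovers the log transform for lognormal data", {
  set.seed(2)
  x <- rlnorm(2000)
  bc <- fit_boxcox(x)
  expect_lte(abs(bc$lambda), 0.15)
  expect_equal(bc$shift, 0)
  # cross-check against the classical profile-likelihood implementation
  ml <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  expect_equal(bc$lambda, ml$x[which.max(ml$y)], tolerance = 0.02)
})

test_that("Box-Cox shifts non-positive samples so the minimum becomes 1", {
  set.seed(3)
  x <- rexp(300) - min(rexp(300))
  x[1] <- 0
  bc <- fit_boxcox(x)
  expect_equal(bc$shift, 1 - min(x))
  expect_equal(min(x + bc$shift), 1)
})

test_that("Box-Cox never increases absolute skewness", {
  set.seed(4)
  for (x in list(rlnorm(400), rnorm(400, 50, 5), rexp(400),
                 -rlnorm(400) + 20)) {
    bc <- fit_boxcox(x)
    y <- cogfrail:::apply_transform(x, bc$lambda, bc$shift)
    expect_lte(abs(skewness(y)), abs(skewness(x)) + 1e-8)
  }
  expect_error(fit_boxcox(rep(2, 100)), "non-degenerate")
})

test_that("standardizing the reference sample gives mean 0 and SD 1 per test", {
  sim <- simulate_cohort(small_config())
  ref <- fit_reference(sim$scores, sim$config$test_schema)
  z <- standardize_scores(sim$scores, ref, sim$config$test_schema)
  base <- dplyr::filter(z, group == "control", month == 0)
  stats <- base |>
    dplyr::group_by(test) |>
    dplyr::summarise(m = mean(z, na.rm = TRUE), s = sd(z, na.rm = TRUE))
  expect_equal(stats$m, rep(0, nrow(stats)), tolerance = 1e-9)
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-9)
})

test_that("a raw value at the reference mean maps to z = 0 and direction flips the sign", {
  schema <- tibble::tibble(test = c("speed", "time"),
                           domain = c("APE", "APE"),
                           direction = c("higher_better", "higher_worse"))
  ref <- structure(
    tibble::tibble(test = c("speed", "time"), lambda = 1, shift = 0,
                   transformed = FALSE, ref_mean = c(10, 30),
                   ref_sd = c(2, 5)),
    class = c("standardization_reference", "tbl_df", "tbl", "data.frame"))
  scores <- tibble::tibble(participant_id = "A", month = 0,
                           speed = 10, time = 35)
  z <- standardize_scores(scores, ref, schema)
  expect_equal(z$z[z$test == "speed"], 0)
  # one reference SD above the mean on a timed test: z = -1 after the flip
  expect_equal(z$z[z$test == "time"], -1)
  scores$unknown <- 1
  schema2 <- dplyr::bind_rows(schema,
    tibble::tibble(test = "unknown", domain = "APE",
                   direction = "higher_better"))
  expect_error(standardize_scores(scores, ref, schema2), "unknown")
})

test_that("positive affine rescaling of a raw test leaves z-scores unchanged", {
  sim <- simulate_cohort(small_config())
  schema <- sim$config$test_schema
  z1 <- standardize_scores(sim$scores,
                           fit_reference(sim$scores, schema,
                                         transform = "never"), schema)
  rescaled <- sim$scores
  rescaled$digit_symbol <- 3.7 * rescaled$digit_symbol + 11
  z2 <- standardize_scores(rescaled,
                           fit_reference(rescaled, schema,
                                         transform = "never"), schema)
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("increasing the raw value of a timed test strictly decreases z", {
  schema <- tibble::tibble(test = "time", domain = "APE",
                           direction = "higher_worse")
  ref <- structure(
    tibble::tibble(test = "time", lambda = 1, shift = 0,
                   transformed = FALSE, ref_mean = 30, ref_sd = 5),
    class = c("standardization_reference", "tbl_df", "tbl", "data.frame"))
  raw <- seq(20, 60, by = 5)
  z <- standardize_scores(
    tibble::tibble(participant_id = "A", month = 0, time = raw)[
      rep(1, length(raw)), ] |>
      dplyr::mutate(time = raw),
    ref, schema)
  expect_true(all(diff(z$z) < 0))
})

test_that("domain means follow the half-of-tests availability rule", {
  schema <- default_test_schema()
  ape_tests <- schema$test[schema$domain == "APE"]
  z <- tidyr::crossing(participant_id = "A", month = 0,
                       test = ape_tests) |>
    dplyr::left_join(schema[, c("test", "domain")], by = "test") |>
    dplyr::mutate(z = 0.5)
  pan <- domain_scores(z, schema)
  expect_equal(pan$APE, 0.5)
  # 3 of 7 APE tests present: below ceiling(7/2) = 4, so missing
  z3 <- dplyr::mutate(z, z = ifelse(test %in% ape_tests[1:3], 0.5, NA))
  expect_true(is.na(domain_scores(z3, schema)$APE))
  z4 <- dplyr::mutate(z, z = ifelse(test %in% ape_tests[1:3],
                                    c(1, -1, 0)[match(test, ape_tests[1:3])],
                                    NA))
  pan4 <- domain_scores(z4, schema, min_tests = c(APE = 3, LM = 5))
  expect_equal(pan4$APE, 0)
})
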