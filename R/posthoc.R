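#' Convert a per-year coefficient to a per-decade effect
#'
#' Linear age coefficients in the model are on a per-year scale; reports
#' conventionally quote the change per decade of aging, i.e. ten times
#' the coefficient (signed; take the magnitude for prose like "worsening
#' by 0.47 z-scores per decade").
#'
#' @param gamma_linear Per-year coefficient(s).
#' @return `10 * gamma_linear`.
#' @examples
#' per_decade_effect(-0.047)
#' @export
per_decade_effect <- function(gamma_linear) {
  stopifnot(is.numeric(gamma_linear))
  10 * gamma_linear
}

#' Posterior survivor-control gap curve over age
#'
#' For every posterior draw and grid age `a`, evaluates the
#' cross-sectional group difference
#' `Delta(a) = gamma03 + gamma04 (a - center) + gamma05 (a - center)^2`,
#' then summarizes across draws: posterior mean and per-age 95% HDI. The
#' band is computed from the draw-level `Delta(a)` distribution, so
#' posterior correlations between the three coefficients are respected.
#'
#' @param fit A `cog_fit`, or any matrix/data frame of draws with columns
#'   `gamma03`, `gamma04`, `gamma05` (a single row is treated as a
#'   point-mass posterior, giving a degenerate band).
#' @param ages Age grid in years (default 60-89 by 0.1).
#' @param center Age-centering constant; taken from the fit when
#'   available.
#' @param prob Mass of the per-age HDI band (default 0.95).
#' @return A tibble of class `gap_curve`: `age`, `mean_diff`, `hdi_lo`,
#'   `hdi_hi`, `significant` (band excludes 0). Attributes carry
#'   `crossing_age`, `crossing_flag` and `center`. Grid points outside
#'   the fitted age range are flagged in an `extrapolated` column (with a
#'   warning) when the fit's data are available.
#' @examples
#' pm <- data.frame(gamma03 = -0.13, gamma04 = 0.016, gamma05 = -0.001)
#' gap_curve(pm, ages = c(65, 72.5), center = 72.5)
#' @export
gap_curve <- function(fit, ages = seq(60, 89, by = 0.1), center = NULL,
                      prob = 0.95) {
  if (inherits(fit, "cog_fit")) {
    draws <- fit$draws
    center <- center %||% fit$input$center
    age_obs <- range(fit$input$participants$age_enroll)
  } else {
    draws <- as.matrix(fit)
    age_obs <- NULL
    if (is.null(center))
      cf_abort("center must be supplied when fit is a draw matrix",
               "cogfrail_data_error")
  }
  need <- c("gamma03", "gamma04", "gamma05")
  if (!all(need %in% colnames(draws)))
    cf_abort("draws must contain gamma03, gamma04, gamma05",
             "cogfrail_data_error")
  D <- draws[, need, drop = FALSE]
  a <- ages - center
  delta <- D %*% rbind(1, a, a^2)   # draws x ages
  band <- apply(delta, 2, hdi_unchecked, prob = prob)
  out <- tibble::tibble(
    age = ages,
    mean_diff = colMeans(delta),
    hdi_lo = band[1, ], hdi_hi = band[2, ])
  out$significant <- !(out$hdi_lo <= 0 & out$hdi_hi >= 0)
  if (!is.null(age_obs)) {
    out$extrapolated <- ages < age_obs[1] | ages > age_obs[2]
    if (any(out$extrapolated))
      warn(sprintf("%d grid point(s) outside the observed age range %.1f-%.1f",
                   sum(out$extrapolated), age_obs[1], age_obs[2]),
           class = "cogfrail_extrapolation_warning")
  }
  out <- structure(out, class = c("gap_curve", class(out)),
                   center = center, prob = prob)
  cr <- crossing_age(out)
  attr(out, "crossing_age") <- cr
  attr(out, "crossing_flag") <- attr(cr, "flag")
  out
}

#' First age at which the gap's credible band crosses the null
#'
#' Scans the age grid in ascending order and returns the first age at
#' which the HDI band contains zero — the age beyond which the
#' survivor-control difference is no longer statistically discernible.
#' Returns `NA` when the band excludes zero everywhere; when the band
#' already contains zero at the grid start, returns the grid start with
#' attribute `flag = "contains_null_at_start"` (other significance
#' patterns, e.g. a significant window at intermediate ages, are
#' recoverable from the `significant` column).
#'
#' @param curve A `gap_curve` (or any tibble with `age`, `hdi_lo`,
#'   `hdi_hi`).
#' @return Age in years (grid resolution), or `NA`; attribute `flag` is
#'   `"crossed"`, `"contains_null_at_start"` or `"never_crosses"`.
#' @examples
#' pm <- data.frame(gamma03 = -0.13, gamma04 = 0.016, gamma05 = -0.001)
#' crossing_age(gap_curve(pm, center = 72.5))
#' @export
crossing_age <- function(curve) {
  check_columns(curve, c("age", "hdi_lo", "hdi_hi"), "gap curve")
  contains0 <- curve$hdi_lo <= 0 & curve$hdi_hi >= 0
  if (!any(contains0))
    return(structure(NA_real_, flag = "never_crosses"))
  i <- which(contains0)[1]
  flag <- if (i == 1L) "contains_null_at_start" else "crossed"
  structure(curve$age[i], flag = flag)
}

#' Plot a survivor-control gap curve
#'
#' Posterior mean difference over age with its credible band, a null
#' reference line, and (when present) the null-crossing age.
#'
#' @param object A `gap_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gap_curve <- function(object, ...) {
  cr <- attr(object, "crossing_age")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi_lo,
                                      ymax = .data$hdi_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_diff),
                       color = "steelblue4", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Age at enrollment (years)",
                  y = "Survivor - control difference",
                  title = "Estimated survivor-control gap over age")
  if (!is.na(cr) && identical(attr(object, "crossing_flag"), "crossed"))
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(cr),
                                 linetype = "dotted") +
      ggplot2::annotate("text", x = as.numeric(cr), y = Inf,
                        label = sprintf("null crossing %.1f", cr),
                        vjust = 1.5, hjust = -0.05, size = 3)
  p
}

#' Trajectory panel for a fitted model
#'
#' The model's own picture of the data: cross-sectional quadratic age
#' curves per group (posterior mean with credible band) and, as filled
#' circles, the model-estimated longitudinal change over follow-up within
#' each baseline age quartile (quartile mean-age intercept plus the
#' quartile/group slope times months, displaced along the age axis by
#' months/12). Quartiles with no participants in a group are omitted with
#' a message.
#'
#' @param object A `cog_fit`.
#' @param months Follow-up months to display (defaults to the observed
#'   visit months).
#' @param ages Age grid for the cross-sectional curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cog_fit <- function(object, months = NULL, ages = NULL, ...) {
  pp <- object$input$participants
  draws <- object$draws
  months <- months %||% sort(unique(object$input$obs$month))
  ages <- ages %||% seq(floor(min(pp$age_enroll)),
                        ceiling(max(pp$age_enroll)), by = 0.25)
  center <- object$input$center
  a <- ages - center

  curve_one <- function(surv) {
    X <- rbind(1, a, a^2, surv, surv * a, surv * a^2)
    cu <- draws[, gamma_names()[1:6], drop = FALSE] %*% X
    band <- apply(cu, 2, hdi_unchecked, prob = 0.95)
    tibble::tibble(age = ages, fit = colMeans(cu),
                   lo = band[1, ], hi = band[2, ],
                   group = if (surv == 1) "survivor" else "control")
  }
  cross <- dplyr::bind_rows(curve_one(0), curve_one(1))

  segs <- list()
  for (g in c(0, 1)) for (q in 1:4) {
    in_cell <- pp$quartile == q & (pp$group == "survivor") == (g == 1)
    if (!any(in_cell)) {
      message(sprintf("no %s participants in age quartile %d; segment omitted",
                      if (g == 1) "survivor" else "control", q))
      next
    }
    ma <- mean(pp$age_enroll[in_cell])
    ca <- ma - center
    # intercept at the quartile mean age + slope * months
    gi <- draws[, gamma_names()[1:6], drop = FALSE] %*%
      c(1, ca, ca^2, g, g * ca, g * ca^2)
    qind <- as.numeric(2:4 == q)
    sl <- draws[, gamma_names()[7:14], drop = FALSE] %*%
      c(1, g, qind, g * qind)
    segs[[length(segs) + 1L]] <- tibble::tibble(
      age = ma + months / 12,
      fit = mean(gi) + mean(sl) * months,
      group = if (g == 1) "survivor" else "control",
      quartile = q)
  }
  segs <- dplyr::bind_rows(segs)

  p <- ggplot2::ggplot(cross, ggplot2::aes(x = .data$age,
                                           color = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$group),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), linewidth = 0.8) +
    ggplot2::labs(x = "Age (years)", y = object$input$outcome,
                  title = sprintf("Model-estimated %s over age",
                                  object$input$outcome),
                  subtitle = "curves: cross-sectional trend; points: longitudinal change by age quartile")
  if (nrow(segs) > 0L)
    p <- p + ggplot2::geom_point(
      data = segs, ggplot2::aes(y = .data$fit, group = .data$quartile),
      size = 1.6) +
      ggplot2::geom_line(data = segs,
                         ggplot2::aes(y = .data$fit,
                                      group = interaction(.data$group,
                                                          .data$quartile)),
                         linewidth = 0.4, alpha = 0.7)
  p
}

#' Save the standard figure set for a fitted outcome
#'
#' Writes the trajectory panel and the gap curve as PNG files.
#'
#' @param fit A `cog_fit`.
#' @param curve A `gap_curve` for the same outcome.
#' @param dir Output directory.
#' @param width,height Inches.
#' @return Invisibly, the file paths.
#' @export
save_figures <- function(fit, curve, dir, width = 7, height = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(
    trajectories = file.path(dir, sprintf("trajectories_%s.png",
                                          fit$input$outcome)),
    gap = file.path(dir, sprintf("gap_%s.png", fit$input$outcome)))
  ggplot2::ggsave(out[["trajectories"]], autoplot(fit),
                  width = width, height = height, dpi = 150)
  ggplot2::ggsave(out[["gap"]], autoplot(curve),
                  width = width, height = height, dpi = 150)
  invisible(out)
}
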