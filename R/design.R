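#' Build the model input from an outcome panel
#'
#' Converts a visit-level outcome panel (domain scores or DAFI series)
#' into the design the growth model needs: per-observation outcome and
#' month; per-participant survivor indicator, centered enrollment age and
#' its square (for the quadratic cross-sectional trend), and the baseline
#' age-quartile indicator (for the practice-effect slopes). Visits with a
#' missing outcome are dropped observation-wise; participants with a
#' missing age or group are excluded and listed in a rejects report.
#'
#' @param panel Tibble with `participant_id`, `group` (`"survivor"` /
#'   `"control"`), `age_enroll`, `month`, and the outcome column.
#' @param outcome Name of the outcome column (e.g. `"APE"`, `"LM"`,
#'   `"dafi"`).
#' @param bins Upper edges of the first three age-quartile bins (default
#'   69, 73, 77 giving bins 60-68, 69-72, 73-76, 77+).
#' @param center Centering constant for age in years, or `"auto"` for the
#'   participant mean age rounded to 0.1.
#' @return An object of class `model_input`: list with `obs`
#'   (participant index, `y`, `month`), `participants` (id, group,
#'   `age_enroll`, `cage`, `quartile`), design matrices `Xa` (intercept
#'   block) and `Xb` (slope block), `center`, `bins`, `outcome`, and a
#'   `rejects` tibble.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_survivors = 15, n_controls = 10))
#' inp <- build_design(dplyr::left_join(sim$latent,
#'   sim$participants[, c("participant_id", "group", "age_enroll")],
#'   by = "participant_id"), outcome = "APE")
#' dim(inp$Xa)
#' @export
build_design <- function(panel, outcome, bins = default_quartile_bins(),
                         center = "auto") {
  check_columns(panel, c("participant_id", "group", "age_enroll", "month",
                         outcome), "outcome panel")
  if (nrow(panel) == 0L)
    cf_abort("outcome panel is empty", "cogfrail_data_error")

  pp <- dplyr::distinct(panel, .data$participant_id, .data$group,
                        .data$age_enroll)
  rej <- dplyr::filter(pp, is.na(.data$group) | is.na(.data$age_enroll) |
                         !(.data$group %in% c("survivor", "control")))
  pp <- dplyr::anti_join(pp, rej, by = "participant_id")
  obs <- panel |>
    dplyr::filter(.data$participant_id %in% pp$participant_id,
                  !is.na(.data[[outcome]])) |>
    dplyr::transmute(participant_id = .data$participant_id,
                     y = .data[[outcome]], month = .data$month)
  pp <- dplyr::filter(pp, .data$participant_id %in% obs$participant_id)
  if (nrow(pp) == 0L)
    cf_abort("no usable observations after exclusions",
             "cogfrail_data_error")

  if (identical(center, "auto")) center <- round(mean(pp$age_enroll), 1)
  pp$cage <- pp$age_enroll - center
  pp$quartile <- age_quartile(pp$age_enroll, bins)
  S <- as.integer(pp$group == "survivor")
  Xa <- cbind(1, pp$cage, pp$cage^2, S, S * pp$cage, S * pp$cage^2)
  colnames(Xa) <- gamma_names()[1:6]
  Q <- outer(pp$quartile, 2:4, `==`) + 0
  Xb <- cbind(1, S, Q, S * Q)
  colnames(Xb) <- gamma_names()[7:14]
  obs$pid <- match(obs$participant_id, pp$participant_id)

  structure(list(obs = obs, participants = pp, Xa = Xa, Xb = Xb,
                 center = center, bins = bins, outcome = outcome,
                 rejects = rej),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf(
    "<model_input> outcome '%s': %d observations on %d participants (center %g)\n",
    x$outcome, nrow(x$obs), nrow(x$participants), x$center))
  if (nrow(x$rejects) > 0L)
    cat(sprintf("  %d participant(s) rejected (missing age/group)\n",
                nrow(x$rejects)))
  invisible(x)
}
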