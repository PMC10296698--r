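#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' where inputs come from (simulate on the fly, or CSV paths), scoring
#' and DAFI thresholds, model settings, seeds and the output directory.
#'
#' @param outdir Output directory for all artifacts.
#' @param seed Integer root seed (generator and sampler seeds derive from
#'   it).
#' @param simulate If `TRUE` (default) the `simulate` stage generates the
#'   input tables; otherwise `scores_path` / `indicators_path` must point
#'   at existing CSVs with the documented column contracts.
#' @param cohort Named list of overrides passed to [cohort_config()].
#' @param scores_path,indicators_path Input CSVs when `simulate = FALSE`.
#' @param outcome Outcome to fit: `"APE"`, `"LM"` or `"DAFI"`.
#' @param mcmc_preset Sampler preset, see [mcmc_preset()].
#' @param quartile_bins,center Passed to [build_design()].
#' @param skew_threshold Normality screen threshold for scoring.
#' @param min_assessed DAFI validity threshold.
#' @param age_grid Age grid for the gap curve.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = "cogfrail_run", seed = 1L,
                       simulate = TRUE, cohort = list(),
                       scores_path = NULL, indicators_path = NULL,
                       outcome = "APE", mcmc_preset = "test",
                       quartile_bins = default_quartile_bins(),
                       center = "auto", skew_threshold = 1,
                       min_assessed = 35,
                       age_grid = seq(60, 89, by = 0.1)) {
  if (!outcome %in% c("APE", "LM", "DAFI"))
    cf_abort("outcome must be one of APE, LM, DAFI",
             "cogfrail_config_error")
  if (!simulate && (is.null(scores_path) || is.null(indicators_path)))
    cf_abort("scores_path and indicators_path are required when simulate = FALSE",
             "cogfrail_config_error")
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, cohort = cohort,
                 scores_path = scores_path,
                 indicators_path = indicators_path,
                 outcome = outcome, mcmc_preset = mcmc_preset,
                 quartile_bins = quartile_bins, center = center,
                 skew_threshold = skew_threshold,
                 min_assessed = min_assessed, age_grid = age_grid),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cf_abort(sprintf("config file not found: %s", path),
             "cogfrail_config_error")
  do.call(run_config, yaml::read_yaml(path))
}

log_line <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = state$log, append = TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end, each reading the previous stage's
#' CSV contract from `config$outdir`:
#' \describe{
#'   \item{simulate}{generate the synthetic cohort tables
#'     (`cohort_scores.csv`, `cohort_indicators.csv`, `cohort_truth.json`).}
#'   \item{score}{control-referenced domain scoring
#'     (`domain_scores.csv`, `standardization_reference.csv`).}
#'   \item{dafi}{per-visit frailty index (`dafi_scores.csv`).}
#'   \item{fit}{fit the growth model for `config$outcome`
#'     (`posterior_draws_<outcome>.csv`, `posterior_summary_<outcome>.csv`).}
#'   \item{report}{gap curve, crossing report and figures
#'     (`gap_curve_<outcome>.csv`, `crossing_<outcome>.json`, PNGs).}
#'   \item{all}{everything above in order.}
#' }
#' Every run writes a resolved-config snapshot (`resolved_config.yaml`)
#' and a log (`run_log.txt`) with package versions, seeds and stage
#' completions.
#'
#' @param stage One of `"simulate"`, `"score"`, `"dafi"`, `"fit"`,
#'   `"report"`, `"all"`.
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a named list of artifact paths and in-memory
#'   results produced by the stages run.
#' @examples
#' \donttest{
#' cfg <- run_config(outdir = tempfile(), seed = 7,
#'                   cohort = list(n_survivors = 20, n_controls = 15),
#'                   mcmc_preset = list(chains = 2, iterations = 400,
#'                                      warmup = 200))
#' run_pipeline("all", cfg)
#' }
#' @export
run_pipeline <- function(stage = c("all", "simulate", "score", "dafi",
                                   "fit", "report"),
                         config = run_config()) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$log <- file.path(config$outdir, "run_log.txt")
  state$out <- list()

  snap <- unclass(config)
  snap$age_grid <- range(config$age_grid)
  yaml::write_yaml(snap, file.path(config$outdir, "resolved_config.yaml"))
  log_line(state, "cogfrail %s | R %s | seed %d | stage %s",
           as.character(packageVersion("cogfrail")),
           paste(R.version$major, R.version$minor, sep = "."),
           config$seed, stage)

  stages <- if (stage == "all")
    c("simulate", "score", "dafi", "fit", "report") else stage
  if (!config$simulate) stages <- setdiff(stages, "simulate")
  for (s in stages) {
    t0 <- Sys.time()
    switch(s,
           simulate = stage_simulate(config, state),
           score = stage_score(config, state),
           dafi = stage_dafi(config, state),
           fit = stage_fit(config, state),
           report = stage_report(config, state))
    log_line(state, "stage %s done in %.1fs", s,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  invisible(state$out)
}

path_scores <- function(config) {
  if (!config$simulate && !is.null(config$scores_path)) config$scores_path
  else file.path(config$outdir, "cohort_scores.csv")
}
path_indicators <- function(config) {
  if (!config$simulate && !is.null(config$indicators_path))
    config$indicators_path
  else file.path(config$outdir, "cohort_indicators.csv")
}

read_table <- function(path, required, what) {
  if (!file.exists(path))
    cf_abort(sprintf("%s not found: %s (run the earlier stages first?)",
                     what, path), "cogfrail_config_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what)
  df
}

stage_simulate <- function(config, state) {
  cfg <- do.call(cohort_config, c(config$cohort,
                                  list(seed = config$seed)))
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, config$outdir)
  readr::write_csv(sim$latent,
                   file.path(config$outdir, "cohort_latent_truth.csv"))
  state$out$sim <- sim
  state$out$paths <- c(state$out$paths, paths)
}

stage_score <- function(config, state) {
  scores <- read_table(path_scores(config),
                       c("participant_id", "group", "month"),
                       "visit-level scores table")
  schema <- default_test_schema()
  schema <- schema[schema$test %in% names(scores), ]
  if (nrow(schema) == 0L)
    cf_abort("scores table contains none of the schema's tests",
             "cogfrail_schema_error")
  sc <- score_cohort(scores, schema,
                     skew_threshold = config$skew_threshold)
  p1 <- file.path(config$outdir, "domain_scores.csv")
  p2 <- file.path(config$outdir, "standardization_reference.csv")
  readr::write_csv(sc$panel, p1)
  readr::write_csv(sc$reference, p2)
  state$out$scoring <- sc
  state$out$paths <- c(state$out$paths,
                       c(domain_scores = p1, reference = p2))
}

stage_dafi <- function(config, state) {
  ind <- read_table(path_indicators(config), c("participant_id", "month"),
                    "indicator table")
  res <- dafi_scores(ind, min_assessed = config$min_assessed)
  p <- file.path(config$outdir, "dafi_scores.csv")
  readr::write_csv(res, p)
  state$out$dafi <- res
  state$out$paths <- c(state$out$paths, c(dafi = p))
}

stage_fit <- function(config, state) {
  scores <- read_table(path_scores(config),
                       c("participant_id", "group", "age_enroll", "month"),
                       "visit-level scores table")
  info <- dplyr::distinct(scores, .data$participant_id, .data$group,
                          .data$age_enroll)
  if (config$outcome == "DAFI") {
    panel <- read_table(file.path(config$outdir, "dafi_scores.csv"),
                        c("participant_id", "month", "dafi"),
                        "DAFI table")
    outcome_col <- "dafi"
  } else {
    panel <- read_table(file.path(config$outdir, "domain_scores.csv"),
                        c("participant_id", "month", config$outcome),
                        "domain-score panel")
    outcome_col <- config$outcome
  }
  if (!all(c("group", "age_enroll") %in% names(panel)))
    panel <- dplyr::left_join(panel, info, by = "participant_id")
  input <- build_design(panel, outcome_col, bins = config$quartile_bins,
                        center = config$center)
  fit <- fit_trajectory_model(input, mcmc = config$mcmc_preset,
                              seed = config$seed)
  p1 <- file.path(config$outdir,
                  sprintf("posterior_draws_%s.csv", config$outcome))
  p2 <- file.path(config$outdir,
                  sprintf("posterior_summary_%s.csv", config$outcome))
  readr::write_csv(tibble::as_tibble(fit$draws), p1)
  readr::write_csv(tidy(fit), p2)
  log_line(state, "fit %s: max R-hat %.4f, converged: %s",
           config$outcome, max(tidy(fit)$rhat, na.rm = TRUE),
           fit$converged)
  state$out$fit <- fit
  state$out$paths <- c(state$out$paths,
                       c(posterior_draws = p1, posterior_summary = p2))
}

stage_report <- function(config, state) {
  fit <- state$out$fit
  if (is.null(fit))
    cf_abort("report stage needs a fitted model in the same run (stage 'fit')",
             "cogfrail_config_error")
  grid <- config$age_grid
  rng <- range(fit$input$participants$age_enroll)
  grid <- grid[grid >= rng[1] & grid <= rng[2]]
  if (length(grid) < 2L) grid <- seq(rng[1], rng[2], by = 0.1)
  curve <- gap_curve(fit, ages = grid)
  cr <- attr(curve, "crossing_age")
  p1 <- file.path(config$outdir,
                  sprintf("gap_curve_%s.csv", config$outcome))
  p2 <- file.path(config$outdir,
                  sprintf("crossing_%s.json", config$outcome))
  readr::write_csv(tibble::as_tibble(curve), p1)
  jsonlite::write_json(
    list(outcome = config$outcome,
         crossing_age = if (is.na(cr)) NULL else as.numeric(cr),
         flag = attr(curve, "crossing_flag"),
         grid_step = diff(grid[1:2]),
         per_decade_effect =
           per_decade_effect(tidy(fit)$estimate[
             tidy(fit)$term == "gamma01"])),
    p2, auto_unbox = TRUE, digits = NA, null = "null")
  figs <- save_figures(fit, curve, config$outdir)
  log_line(state, "report %s: crossing %s (%s)", config$outcome,
           if (is.na(cr)) "none" else sprintf("%.1f", cr),
           attr(curve, "crossing_flag"))
  state$out$gap <- curve
  state$out$paths <- c(state$out$paths,
                       c(gap_curve = p1, crossing = p2, figs))
}
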