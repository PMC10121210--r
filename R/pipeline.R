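#' Run the full simulated-trial pipeline
#'
#' Chains the whole analysis end to end on synthetic data: simulate a
#' cohort, apply the device missingness mechanism, classify wear status,
#' apply the baseline adherence filter, impute and smooth missing minutes,
#' estimate per-participant treatment effects by feasible GLS under AR(1)
#' errors, and aggregate the cohort summaries (optionally rendering the
#' static report).
#'
#' @param n_participants Cohort size.
#' @param params A [sim_params()] object.
#' @param design A [trial_design()] object.
#' @param seed Integer seed driving all randomness.
#' @param out_dir If non-`NULL`, input CSVs and the rendered report are
#'   written here.
#' @param impute Use the imputed daily series (default TRUE); `FALSE`
#'   analyzes zero-filled observed totals instead.
#' @param smooth Apply spline smoothing to imputed minutes (default TRUE).
#' @param min_adherent_days,day_threshold Baseline adherence filter
#'   parameters (see [baseline_adherence_pass()]).
#' @param carryover_lag_days,include_baseline Passed to [build_design()].
#' @param render Render the HTML report into `out_dir` (default
#'   `!is.null(out_dir)`).
#' @return List with `effects`, `daily`, `counts`, `forest`, `sequences`,
#'   `excluded` (participants failing the adherence filter), and `cohort`
#'   (the simulation object, ground truth included).
#' @export
run_nof1_pipeline <- function(n_participants = 26L, params = sim_params(),
                              design = trial_design(), seed = 1L,
                              out_dir = NULL, impute = TRUE, smooth = TRUE,
                              min_adherent_days = 11L, day_threshold = 0.8,
                              carryover_lag_days = 0L,
                              include_baseline = FALSE,
                              render = !is.null(out_dir)) {
  cohort <- simulate_cohort(n_participants, params, design, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_minute_csv(cohort$observed, file.path(out_dir, "minutes.csv"))
    write_covariate_csv(cohort$covariates,
                        file.path(out_dir, "covariates.csv"))
  }
  classified <- classify_minutes(cohort$observed)
  classified[, day_index := as.integer(date - min(date))]
  cov <- data.table::copy(cohort$covariates)
  cov[, day_index := as.integer(date - min(date))]
  cov[, weekday := as.integer(format(date, "%u") <= 5L)]

  effects <- list()
  daily <- list()
  excluded <- character(0L)
  for (pid in names(cohort$participants)) {
    pc <- classified[participant_id == pid]
    if (!baseline_adherence_pass(pc, design$baseline_days,
                                 min_adherent_days, day_threshold)) {
      excluded <- c(excluded, pid)
      next
    }
    sequence <- cohort$sequences[[pid]]
    ds <- if (impute)
      impute_participant(pc, cov, design, sequence, smooth = smooth)$daily
    else
      observed_daily_totals(pc, cov, design, sequence)
    daily[[pid]] <- ds
    effects[[pid]] <- analyze_participant(
      ds, include_baseline = include_baseline,
      carryover_lag_days = carryover_lag_days)
  }
  if (!length(effects))
    stop("no participant passed the baseline adherence filter",
         call. = FALSE)
  effects <- data.table::rbindlist(effects)
  daily <- data.table::rbindlist(daily)
  counts <- counts_table(effects)
  forest <- forest_table(effects)
  if (render && !is.null(out_dir))
    render_report(effects, daily, file.path(out_dir, "report"))
  if (!is.null(out_dir)) {
    data.table::fwrite(effects, file.path(out_dir, "effects.csv"))
    data.table::fwrite(daily, file.path(out_dir, "daily.csv"))
  }
  list(effects = effects, daily = daily, counts = counts, forest = forest,
       sequences = cohort$sequences, excluded = excluded, cohort = cohort)
}
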