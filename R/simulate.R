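#' Randomize participants to treatment sequences
#'
#' Block randomization at the configured allocation ratio: participants are
#' assigned in permuted blocks of size `sum(ratio)`, so for a 1:1 ratio the
#' two sequence arms never differ in size by more than one.
#'
#' @param n_participants Number of participants (>= 1).
#' @param design An [trial_design()] object.
#' @param seed Integer RNG seed; assignment is deterministic given the seed.
#' @return Character vector of sequence names (one per participant).
#' @export
#' @examples
#' table(assign_sequences(26, trial_design(), seed = 1))
assign_sequences <- function(n_participants, design = trial_design(),
                             seed = NULL) {
  if (n_participants < 1L)
    stop("`n_participants` must be >= 1", call. = FALSE)
  ratio <- design$randomization_ratio
  if (any(ratio <= 0L))
    stop("invalid design: randomization ratio entries must be positive",
         call. = FALSE)
  arms <- names(design$sequences)
  block <- rep(arms, times = ratio)
  n_blocks <- ceiling(n_participants / length(block))
  with_seed(seed, {
    out <- unlist(lapply(seq_len(n_blocks), function(i) sample(block)))
    out[seq_len(n_participants)]
  })
}

ar1_series <- function(n, rho, marginal_sd) {
  if (marginal_sd == 0 || n == 0L) return(numeric(n))
  e <- numeric(n)
  e[1L] <- rnorm(1L, 0, marginal_sd)
  if (n > 1L) {
    innov <- rnorm(n - 1L, 0, marginal_sd * sqrt(1 - rho^2))
    for (i in 2:n) e[i] <- rho * e[i - 1L] + innov[i - 1L]
  }
  e
}

# expected daily totals and their building blocks for one participant
day_level_truth <- function(params, design, sequence, dates, temperature) {
  nd <- n_trial_days(design)
  weekday <- as.integer(format(dates, "%u") <= 5L)
  blocks <- day_blocks(design, sequence)
  scale <- exp(params$weekday_log_effect * weekday +
               params$temp_log_effect * (temperature - params$temp_mean))
  base_total <- sum(params$minute_intensity) * scale
  delta <- numeric(nd)
  for (trt in TREATMENTS)
    delta[blocks == trt] <- params$treatment_daily_effect[[trt]]
  list(weekday = weekday, blocks = blocks, scale = scale,
       base_total = base_total, delta = delta)
}

#' Simulate one participant's minute-level trial data
#'
#' Generates the full latent record for one participant: per-minute true step
#' counts drawn from a Poisson log-linear model (diurnal intensity profile
#' times weekday, temperature, treatment and day-level AR(1) adjustments) and
#' the true per-minute wear status. Treatment effects are specified on the
#' daily-steps scale and injected multiplicatively on the minute rates, so
#' the expected daily total under treatment k equals the usual-care
#' expectation plus `treatment_daily_effect[k]` exactly.
#'
#' The returned object is ground truth: it is consumed by
#' [apply_missingness()] to produce the observable device stream, and kept
#' alongside it for parameter-recovery tests. Analysis stages never read it.
#'
#' @param params A [sim_params()] object.
#' @param design A [trial_design()] object.
#' @param sequence Sequence name (e.g. `"A"`) or 6 block labels.
#' @param seed Integer RNG seed.
#' @param participant_id Identifier stored in the records.
#' @param start_date First baseline day (default a Monday).
#' @param temperature Optional length-`n_trial_days(design)` vector of daily
#'   temperatures (deg F); drawn from `N(temp_mean, temp_sd)` when `NULL`.
#'   Pass a shared vector to give a cohort common weather.
#' @return An object of class `nof1_participant`: list with `minutes` (true
#'   steps + wear status), `days` (covariates, block labels, true totals) and
#'   `truth` (the generating parameters).
#' @export
generate_participant <- function(params, design = trial_design(),
                                 sequence = "A", seed = NULL,
                                 participant_id = "P01",
                                 start_date = as.Date("2020-01-06"),
                                 temperature = NULL) {
  nd <- n_trial_days(design)
  with_seed(seed, {
    dates <- start_date + 0:(nd - 1L)
    z <- if (is.null(temperature))
      rnorm(nd, params$temp_mean, params$temp_sd)
    else {
      stopifnot(length(temperature) == nd)
      as.numeric(temperature)
    }
    tr <- day_level_truth(params, design, sequence, dates, z)
    e <- ar1_series(nd, params$ar1_rho, params$daily_sd)
    mu_total <- pmax(tr$base_total + tr$delta + e, 0)
    day_factor <- ifelse(tr$base_total > 0, mu_total / tr$base_total, 0)
    lam <- params$minute_intensity %o% (tr$scale * day_factor)
    true_steps <- matrix(rpois(length(lam), lam), nrow = MINUTES_PER_DAY)
    wear <- matrix(runif(length(lam)), nrow = MINUTES_PER_DAY) <
      params$wear_prob_profile
    minutes <- data.table::data.table(
      participant_id = participant_id,
      date = rep(dates, each = MINUTES_PER_DAY),
      day_index = rep(0:(nd - 1L), each = MINUTES_PER_DAY),
      minute = rep(0:(MINUTES_PER_DAY - 1L), nd),
      true_steps = as.integer(true_steps),
      wear = as.vector(wear))
    days <- data.table::data.table(
      participant_id = participant_id,
      day_index = 0:(nd - 1L), date = dates, block = tr$blocks,
      weekday = tr$weekday, temperature_f = z, day_effect = e,
      expected_total = tr$base_total + tr$delta,
      true_total = colSums(true_steps))
    structure(
      list(participant_id = participant_id, minutes = minutes, days = days,
           truth = list(treatment_daily_effect = params$treatment_daily_effect,
                        ar1_rho = params$ar1_rho, daily_sd = params$daily_sd,
                        sequence = resolve_sequence(design, sequence))),
      class = "nof1_participant")
  })
}

#' Simulate daily step totals directly
#'
#' Fast path for simulation studies: because a day's total over 1440
#' independent Poisson minute counts is itself Poisson with the summed rate,
#' drawing the daily total directly is distributionally identical to
#' generating and summing minute-level counts (no missingness applied). Used
#' by the Monte-Carlo acceptance checks where only daily totals enter the
#' regression.
#'
#' @inheritParams generate_participant
#' @return A daily-series `data.table` (`participant_id`, `day_index`,
#'   `block`, `total_steps`, `fraction_imputed` = 0, `weekday`,
#'   `temperature_f`), the same shape [daily_totals()] emits.
#' @export
simulate_daily_series <- function(params, design = trial_design(),
                                  sequence = "A", seed = NULL,
                                  participant_id = "P01",
                                  start_date = as.Date("2020-01-06"),
                                  temperature = NULL) {
  nd <- n_trial_days(design)
  with_seed(seed, {
    dates <- start_date + 0:(nd - 1L)
    z <- if (is.null(temperature))
      rnorm(nd, params$temp_mean, params$temp_sd)
    else as.numeric(temperature)
    tr <- day_level_truth(params, design, sequence, dates, z)
    e <- ar1_series(nd, params$ar1_rho, params$daily_sd)
    mu_total <- pmax(tr$base_total + tr$delta + e, 0)
    data.table::data.table(
      participant_id = participant_id, day_index = 0:(nd - 1L),
      block = tr$blocks, total_steps = as.numeric(rpois(nd, mu_total)),
      fraction_imputed = 0, weekday = tr$weekday, temperature_f = z)
  })
}

#' Apply the device missingness mechanism
#'
#' Converts a participant's latent record into the observable device stream:
#' worn minutes keep their step count and record a heart rate; non-wear
#' minutes lose the heart rate, and only a `carry_prob` fraction of them
#' (device carried but not worn) retain their step counts -- the rest record
#' 0, the signature confounded zero of wrist-worn trackers.
#'
#' @param participant An `nof1_participant` from [generate_participant()],
#'   or a `data.table` with columns `participant_id`, `date`, `minute`,
#'   `true_steps`, `wear`.
#' @param params A [sim_params()] object (supplies `carry_prob`).
#' @param seed Integer RNG seed.
#' @return `data.table` with columns `participant_id, date, minute, steps,
#'   heart_rate` (heart rate `NA` when not worn).
#' @export
apply_missingness <- function(participant, params, seed = NULL) {
  rec <- if (inherits(participant, "nof1_participant"))
    participant$minutes else data.table::as.data.table(participant)
  stopifnot(all(c("participant_id", "date", "minute", "true_steps", "wear")
                %in% names(rec)))
  with_seed(seed, {
    n <- nrow(rec)
    carried <- !rec$wear & (runif(n) < params$carry_prob)
    steps <- ifelse(rec$wear | carried, rec$true_steps, 0L)
    hr <- rep(NA_integer_, n)
    worn <- which(rec$wear)
    if (length(worn))
      hr[worn] <- as.integer(round(pmax(
        45, 70 + 0.25 * pmin(steps[worn], 140) + rnorm(length(worn), 0, 4))))
    data.table::data.table(
      participant_id = rec$participant_id, date = rec$date,
      minute = rec$minute, steps = as.integer(steps), heart_rate = hr)
  })
}

#' Write minute-level and covariate CSV files
#'
#' The minute dialect is `participant_id,date,minute,steps,heart_rate` with
#' ISO-8601 dates, minute 0-1439, and an *empty* heart-rate field for
#' non-wear minutes; the covariate dialect is `date,temperature_f`. Both
#' round-trip losslessly through [read_minute_csv()] /
#' [read_covariate_csv()].
#'
#' @param records Minute records (as from [apply_missingness()]), sorted by
#'   (participant, date, minute).
#' @param path Output file path.
#' @export
write_minute_csv <- function(records, path) {
  rec <- data.table::as.data.table(records)
  need <- c("participant_id", "date", "minute", "steps", "heart_rate")
  stopifnot(all(need %in% names(rec)))
  rec <- rec[order(rec$participant_id, rec$date, rec$minute)]
  data.table::fwrite(rec[, need, with = FALSE], path, na = "")
  invisible(path)
}

#' @rdname write_minute_csv
#' @param days Day-level table with columns `date` and `temperature_f`.
#' @export
write_covariate_csv <- function(days, path) {
  d <- data.table::as.data.table(days)
  stopifnot(all(c("date", "temperature_f") %in% names(d)))
  d <- unique(d[, c("date", "temperature_f"), with = FALSE], by = "date")
  data.table::fwrite(d[order(d$date)], path, na = "")
  invisible(path)
}

#' Simulate a cohort of participants
#'
#' Randomizes `n_participants` to the design's two sequences, draws one
#' shared daily temperature series (common weather), and generates each
#' participant's latent record plus the observed device stream.
#'
#' @inheritParams generate_participant
#' @param n_participants Cohort size.
#' @return List with `participants` (latent `nof1_participant`s), `observed`
#'   (combined observed minute records), `covariates` (`date`,
#'   `temperature_f`), `sequences`, `design`, `params`.
#' @export
simulate_cohort <- function(n_participants, params = sim_params(),
                            design = trial_design(), seed = NULL,
                            start_date = as.Date("2020-01-06")) {
  nd <- n_trial_days(design)
  with_seed(seed, {
    sub_seed <- sample.int(.Machine$integer.max, 2L * n_participants + 2L)
    temperature <- rnorm(nd, params$temp_mean, params$temp_sd)
    sequences <- assign_sequences(n_participants, design, seed = sub_seed[1L])
    ids <- sprintf("P%02d", seq_len(n_participants))
    participants <- vector("list", n_participants)
    observed <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      participants[[i]] <- generate_participant(
        params, design, sequences[i], seed = sub_seed[2L * i],
        participant_id = ids[i], start_date = start_date,
        temperature = temperature)
      observed[[i]] <- apply_missingness(
        participants[[i]], params, seed = sub_seed[2L * i + 1L])
    }
    names(participants) <- ids
    list(participants = participants,
         observed = data.table::rbindlist(observed),
         covariates = data.table::data.table(
           date = start_date + 0:(nd - 1L), temperature_f = temperature),
         sequences = stats::setNames(sequences, ids),
         design = design, params = params)
  })
}
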