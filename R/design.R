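#' @importFrom stats rnorm rpois runif acf coef glm.fit lm.fit optim
#'   pnorm poisson predict qnorm qt quantile sd smooth.spline var
#' @importFrom utils head tail
NULL

# block labels used throughout; BASELINE is reserved for pre-randomization days
TREATMENTS <- c("YOGA", "MASSAGE")
BLOCK_LABELS <- c("YOGA", "MASSAGE", "USUAL_CARE")
MINUTES_PER_DAY <- 1440L

#' Crossover trial design
#'
#' Describes the structure of a personalized (N-of-1) activity trial: a
#' baseline wear-adherence period followed by six treatment blocks drawn from
#' yoga, massage and usual care, with participants randomized 1:1 (by
#' default) to one of two time-balanced block sequences.
#'
#' The two default sequences place each condition twice, mirrored across
#' sequences so every condition occupies early and late positions; they are
#' fully configurable.
#'
#' @param baseline_days Length of the baseline assessment period in days
#'   (default 14).
#' @param block_days Length of each treatment block in days (default 14).
#' @param sequences Named list of two character vectors, each an ordered set
#'   of 6 block labels from `YOGA`, `MASSAGE`, `USUAL_CARE`. Both sequences
#'   must contain the same multiset of labels.
#' @param randomization_ratio Integer pair giving the allocation ratio
#'   between the two sequences (default `c(1, 1)`).
#'
#' @return An object of class `nof1_design`.
#' @export
#' @examples
#' d <- trial_design()
#' n_trial_days(d)  # 14 + 6 * 14 = 98
trial_design <- function(baseline_days = 14L,
                         block_days = 14L,
                         sequences = list(
                           A = c("YOGA", "USUAL_CARE", "MASSAGE",
                                 "YOGA", "USUAL_CARE", "MASSAGE"),
                           B = c("MASSAGE", "USUAL_CARE", "YOGA",
                                 "MASSAGE", "USUAL_CARE", "YOGA")),
                         randomization_ratio = c(1L, 1L)) {
  baseline_days <- as.integer(baseline_days)
  block_days <- as.integer(block_days)
  if (is.na(baseline_days) || baseline_days < 0L)
    stop("`baseline_days` must be a non-negative integer", call. = FALSE)
  if (is.na(block_days) || block_days < 1L)
    stop("`block_days` must be a positive integer", call. = FALSE)
  if (!is.list(sequences) || length(sequences) != 2L)
    stop("`sequences` must be a list of exactly two block sequences",
         call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- c("A", "B")
  for (s in sequences) {
    if (length(s) != 6L)
      stop("each sequence must contain exactly 6 blocks", call. = FALSE)
    bad <- setdiff(s, BLOCK_LABELS)
    if (length(bad))
      stop("unknown block label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!identical(sort(sequences[[1L]]), sort(sequences[[2L]])))
    stop("the two sequences must contain the same multiset of block labels",
         call. = FALSE)
  ratio <- as.integer(randomization_ratio)
  if (length(ratio) != 2L || anyNA(ratio) || any(ratio <= 0L))
    stop("`randomization_ratio` must be two positive integers", call. = FALSE)
  structure(
    list(baseline_days = baseline_days, block_days = block_days,
         sequences = sequences, randomization_ratio = ratio),
    class = "nof1_design")
}

#' @rdname trial_design
#' @param design An `nof1_design` object.
#' @export
n_trial_days <- function(design) {
  design$baseline_days + 6L * design$block_days
}

#' Block label for every trial day
#'
#' @param design An `nof1_design` object.
#' @param sequence Either the name of a sequence in `design$sequences` or a
#'   character vector of 6 block labels.
#' @return Character vector of length [n_trial_days()] with entries
#'   `BASELINE`, `YOGA`, `MASSAGE` or `USUAL_CARE`.
#' @export
day_blocks <- function(design, sequence) {
  seq_labels <- resolve_sequence(design, sequence)
  c(rep("BASELINE", design$baseline_days),
    rep(seq_labels, each = design$block_days))
}

resolve_sequence <- function(design, sequence) {
  if (length(sequence) == 1L && sequence %in% names(design$sequences))
    return(design$sequences[[sequence]])
  if (length(sequence) == 6L && all(sequence %in% BLOCK_LABELS))
    return(as.character(sequence))
  stop("`sequence` must name one of the design's sequences or give 6 block labels",
       call. = FALSE)
}

#' Baseline daytime activity profile
#'
#' A smooth diurnal steps-per-minute profile: near-zero overnight, peaks
#' around the morning and evening commutes and a broad midday plateau,
#' normalized so the expected daily total at reference covariates (weekend,
#' mean temperature) equals `daily_total`.
#'
#' @param daily_total Expected daily step total at reference covariates.
#' @return Numeric vector of length 1440 (minute 0 = midnight).
#' @export
default_minute_intensity <- function(daily_total = 8000) {
  t <- 0:1439
  shape <- 0.02 +
    exp(-((t - 540) / 130)^2) +          # ~9am peak
    0.9 * exp(-((t - 1080) / 160)^2) +   # ~6pm peak
    0.5 * exp(-((t - 810) / 240)^2)      # midday plateau
  shape[t < 360 | t >= 1410] <- 0.02     # asleep midnight-6am
  shape / sum(shape) * daily_total
}

#' Default wear-probability profile
#'
#' Per-minute probability the device is on the wrist: slightly lower
#' overnight (chargers, sleep discomfort) than during the day. The average
#' (~0.91) matches a cohort described as wearing the device at least 80% of
#' the time.
#'
#' @return Numeric vector of length 1440 of probabilities.
#' @export
default_wear_profile <- function() {
  p <- rep(0.95, MINUTES_PER_DAY)
  p[1:360] <- 0.80
  p
}

#' Simulation parameters for the synthetic Fitbit generator
#'
#' Collects every knob of the data-generating process the analysis assumes:
#' a minute-level Poisson intensity profile, log-linear weekday and
#' temperature effects, additive daily-step treatment effects, a day-level
#' AR(1) disturbance, and the wear/carry missingness mechanism in which
#' non-wear minutes record step count 0 and no heart rate.
#'
#' @param minute_intensity Length-1440 non-negative vector of baseline
#'   steps/minute rates at reference covariates (weekend, mean temperature).
#' @param weekday_log_effect Additive log-rate effect of a weekday (shared
#'   across minutes); default 0.05, i.e. ~5% more steps Mon-Fri.
#' @param temp_log_effect Additive log-rate effect per degree Fahrenheit
#'   above `temp_mean`; default 0.002.
#' @param treatment_daily_effect Named numeric vector giving the expected
#'   change in *daily* steps versus usual care for `YOGA` and `MASSAGE`.
#' @param ar1_rho Lag-1 autocorrelation of the day-level disturbance,
#'   in (-1, 1).
#' @param daily_sd Marginal standard deviation (daily steps) of the
#'   day-level disturbance.
#' @param wear_prob_profile Length-1440 vector of per-minute wear
#'   probabilities.
#' @param carry_prob Probability that a non-wear minute still accrues its
#'   true step count (device carried in a pocket or bag).
#' @param temp_mean,temp_sd Mean and SD of the simulated daily temperature
#'   (degrees Fahrenheit).
#'
#' @return An object of class `nof1_params`.
#' @export
sim_params <- function(minute_intensity = default_minute_intensity(),
                       weekday_log_effect = 0.05,
                       temp_log_effect = 0.002,
                       treatment_daily_effect = c(YOGA = 0, MASSAGE = 0),
                       ar1_rho = 0.3,
                       daily_sd = 2000,
                       wear_prob_profile = default_wear_profile(),
                       carry_prob = 0.1,
                       temp_mean = 60,
                       temp_sd = 10) {
  if (length(minute_intensity) != MINUTES_PER_DAY ||
      any(!is.finite(minute_intensity)) || any(minute_intensity < 0))
    stop("`minute_intensity` must be 1440 non-negative finite rates",
         call. = FALSE)
  if (!is.finite(ar1_rho) || abs(ar1_rho) >= 1)
    stop("`ar1_rho` must lie strictly inside (-1, 1)", call. = FALSE)
  if (!is.finite(daily_sd) || daily_sd < 0)
    stop("`daily_sd` must be non-negative", call. = FALSE)
  if (length(wear_prob_profile) != MINUTES_PER_DAY ||
      any(wear_prob_profile < 0 | wear_prob_profile > 1))
    stop("`wear_prob_profile` must be 1440 probabilities in [0, 1]",
         call. = FALSE)
  if (carry_prob < 0 || carry_prob > 1)
    stop("`carry_prob` must be a probability", call. = FALSE)
  eff <- c(YOGA = 0, MASSAGE = 0)
  if (length(treatment_daily_effect)) {
    bad <- setdiff(names(treatment_daily_effect), TREATMENTS)
    if (length(bad) || is.null(names(treatment_daily_effect)))
      stop("`treatment_daily_effect` must be named with YOGA / MASSAGE",
           call. = FALSE)
    eff[names(treatment_daily_effect)] <- treatment_daily_effect
  }
  structure(
    list(minute_intensity = as.numeric(minute_intensity),
         weekday_log_effect = weekday_log_effect,
         temp_log_effect = temp_log_effect,
         treatment_daily_effect = eff,
         ar1_rho = ar1_rho, daily_sd = daily_sd,
         wear_prob_profile = as.numeric(wear_prob_profile),
         carry_prob = carry_prob,
         temp_mean = temp_mean, temp_sd = temp_sd),
    class = "nof1_params")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
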