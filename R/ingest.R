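#' Read minute-level device records
#'
#' Reads the minute CSV dialect (`participant_id,date,minute,steps,
#' heart_rate`), validates every row, and derives a 0-based `day_index` per
#' participant from the first calendar day present. An empty heart-rate
#' field parses as "absent" (`heart_rate_present = FALSE`), the device's
#' encoding of non-wear.
#'
#' @param path Path to the CSV file.
#' @return `data.table` sorted by (participant, day, minute) with columns
#'   `participant_id, date, day_index, minute, steps, heart_rate,
#'   heart_rate_present`.
#' @export
read_minute_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = "",
                          colClasses = list(character = "participant_id"))
  need <- c("participant_id", "date", "minute", "steps", "heart_rate")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("minute CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt[, date := as.Date(date)]
  bad <- which(is.na(dt$date) | is.na(dt$minute) | is.na(dt$steps) |
                 dt$minute < 0L | dt$minute > 1439L | dt$steps < 0L)
  if (length(bad))
    stop(sprintf("malformed minute record at data row %d of %s",
                 bad[1L], path), call. = FALSE)
  if (anyDuplicated(dt, by = c("participant_id", "date", "minute")))
    stop("duplicate (participant, date, minute) keys in ", path,
         call. = FALSE)
  dt[, day_index := as.integer(date - min(date)), by = "participant_id"]
  dt[, heart_rate_present := !is.na(heart_rate)]
  data.table::setorderv(dt, c("participant_id", "day_index", "minute"))
  data.table::setcolorder(dt, c("participant_id", "date", "day_index",
                                "minute", "steps", "heart_rate",
                                "heart_rate_present"))
  dt[]
}

#' Read the daily covariate table
#'
#' Reads `date,temperature_f` and derives the weekday indicator
#' (1 = Monday-Friday, 0 = weekend) from the calendar date.
#'
#' @param path Path to the CSV file.
#' @return `data.table` with columns `date, day_index, weekday,
#'   temperature_f`, sorted by date.
#' @export
read_covariate_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  miss <- setdiff(c("date", "temperature_f"), names(dt))
  if (length(miss))
    stop("covariate CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt[, date := as.Date(date)]
  bad <- which(is.na(dt$date) | !is.finite(dt$temperature_f))
  if (length(bad))
    stop(sprintf("malformed covariate record at data row %d of %s",
                 bad[1L], path), call. = FALSE)
  if (anyDuplicated(dt$date))
    stop("duplicate dates in covariate file ", path, call. = FALSE)
  data.table::setorderv(dt, "date")
  dt[, day_index := as.integer(date - min(date))]
  dt[, weekday := as.integer(format(date, "%u") <= 5L)]
  dt[, c("date", "day_index", "weekday", "temperature_f"), with = FALSE]
}

#' Classify each minute as worn, carried, or missing
#'
#' The device records heart rate only while on the wrist, so heart-rate
#' presence identifies wear. The three exhaustive, mutually exclusive cases
#' per minute are: heart rate present -> `WORN` (recorded steps are the
#' actual steps); absent with positive steps -> `CARRIED` (device in a
#' pocket: steps still actual); absent with zero steps -> `MISSING` (the
#' zero is uninformative and the actual count is unknown).
#'
#' @param records Minute records as from [read_minute_csv()] (needs
#'   `heart_rate_present` and `steps`).
#' @return The records with `wear` (`WORN`/`CARRIED`/`MISSING`) and
#'   `resolved_steps` (`NA` when `MISSING`) appended.
#' @export
classify_minutes <- function(records) {
  dt <- data.table::as.data.table(records)
  if (!"heart_rate_present" %in% names(dt)) {
    if (!"heart_rate" %in% names(dt))
      stop("records need `heart_rate_present` or `heart_rate`", call. = FALSE)
    dt[, heart_rate_present := !is.na(heart_rate)]
  }
  stopifnot("steps" %in% names(dt))
  if (any(dt$steps < 0, na.rm = TRUE))
    stop("negative step counts are invalid", call. = FALSE)
  dt[, wear := data.table::fifelse(
    heart_rate_present, "WORN",
    data.table::fifelse(steps > 0L, "CARRIED", "MISSING"))]
  dt[, resolved_steps := data.table::fifelse(
    wear == "MISSING", NA_real_, as.numeric(steps))]
  dt[]
}

#' Fraction of a day that was worn or carried
#'
#' @param wear Character vector of the day's 1440 wear classifications.
#' @return Fraction in `[0, 1]` of minutes whose actual step count is known
#'   (i.e. not `MISSING`).
#' @export
day_wear_fraction <- function(wear) {
  if (length(wear) != MINUTES_PER_DAY)
    stop("a day must supply exactly 1440 classified minutes", call. = FALSE)
  mean(wear != "MISSING")
}

#' Per-day wear summary
#'
#' @param classified Classified minute records ([classify_minutes()]).
#' @param day_threshold Fraction of the day's minutes that must be
#'   non-missing for the day to count as adherent (default 0.8).
#' @return `data.table` `participant_id, day_index, wear_fraction,
#'   adherent`, one row per (participant, day). Days with no records at all
#'   are not represented here; [baseline_adherence_pass()] treats them as
#'   fully missing.
#' @export
wear_summary <- function(classified, day_threshold = 0.8) {
  dt <- data.table::as.data.table(classified)
  out <- dt[, list(wear_fraction = day_wear_fraction(wear)),
            by = c("participant_id", "day_index")]
  out[, adherent := wear_fraction >= day_threshold]
  data.table::setorderv(out, c("participant_id", "day_index"))
  out[]
}

#' Baseline wear-adherence filter
#'
#' A participant passes the run-in filter when at least `min_adherent_days`
#' of the baseline days were adherent, a day being adherent when at least
#' `day_threshold` of its 1440 minutes are non-missing. Defaults encode the
#' "80% adherence, at least 11 of 14 days" rule. Baseline days with no
#' records at all count as non-adherent.
#'
#' @param classified One participant's classified minutes (baseline days are
#'   `day_index < baseline_days`).
#' @param baseline_days Number of baseline days (default 14).
#' @param min_adherent_days Minimum count of adherent baseline days
#'   (default 11).
#' @param day_threshold Per-day minute fraction defining adherence
#'   (default 0.8).
#' @return `TRUE` if the participant passes the filter.
#' @export
baseline_adherence_pass <- function(classified, baseline_days = 14L,
                                    min_adherent_days = 11L,
                                    day_threshold = 0.8) {
  dt <- data.table::as.data.table(classified)
  base <- dt[day_index < baseline_days]
  if (nrow(base) == 0L) return(min_adherent_days <= 0L)
  ws <- wear_summary(base, day_threshold = day_threshold)
  sum(ws$adherent) >= min_adherent_days
}
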