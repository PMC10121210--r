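# --- per-minute Poisson imputation -----------------------------------------
#
# The imputation model is a minute-indexed Poisson log-linear regression of
# the actual step count on the weekday indicator and daily temperature,
#   Y_ti ~ Poisson(lambda_ti),  log lambda_ti = alpha_t + beta_t r_i + gamma_t z_i,
# fit for each minute t across the days where that minute's count is known
# (WORN or CARRIED), then evaluated at the day's covariates to fill MISSING
# minutes, and finally smoothed along the minute axis with a GCV-penalized
# cubic smoothing spline.

# align a covariate table to a vector of day indices; prefers joining on
# calendar date when both sides carry one
covariates_for_days <- function(classified, covariates, day_index) {
  cov <- data.table::as.data.table(covariates)
  stopifnot(all(c("weekday", "temperature_f") %in% names(cov)))
  if ("day_index" %in% names(cov)) {
    idx <- match(day_index, cov$day_index)
  } else if ("date" %in% names(cov) && "date" %in% names(classified)) {
    day_date <- unique(data.table::as.data.table(classified)[
      , c("day_index", "date"), with = FALSE])
    idx <- match(day_date$date[match(day_index, day_date$day_index)],
                 cov$date)
  } else {
    stop("covariates need a `day_index` or `date` column", call. = FALSE)
  }
  if (anyNA(idx))
    stop("covariates missing for day(s): ",
         paste(day_index[is.na(idx)], collapse = ", "), call. = FALSE)
  list(weekday = cov$weekday[idx], temperature_f = cov$temperature_f[idx])
}

# single Poisson log-linear fit of y on (1, r, z); constant covariate
# columns are dropped (their coefficients reported as 0) so an
# intercept-only configuration reduces to alpha = log(mean(y))
fit_poisson_rz <- function(y, r, z) {
  if (all(y == 0))
    return(list(alpha = 0, beta = 0, gamma = 0, ok = TRUE, zero_rate = TRUE))
  use_r <- length(unique(r)) > 1L
  use_z <- isTRUE(sd(z) > 1e-10)
  X <- cbind(intercept = rep(1, length(y)),
             if (use_r) r, if (use_z) z)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = poisson())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$coefficients)))
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                ok = FALSE, zero_rate = FALSE))
  cf <- fit$coefficients
  k <- 1L
  beta <- gamma <- 0
  if (use_r) { k <- k + 1L; beta <- cf[k] }
  if (use_z) { k <- k + 1L; gamma <- cf[k] }
  # guard against quasi-separated fits whose covariate slopes explode when
  # extrapolated (e.g. |gamma| = 1/degF multiplies the rate by e^10 over
  # 10 degF); such fits are degenerate and defer to the pooled fallback
  if (abs(beta) > 10 || abs(gamma) > 1)
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                ok = FALSE, zero_rate = FALSE))
  list(alpha = unname(cf[1L]), beta = unname(beta), gamma = unname(gamma),
       ok = TRUE, zero_rate = FALSE)
}

#' Fit the per-minute Poisson imputation models
#'
#' For each minute of the day, fits the Poisson log-linear model of the
#' known step counts on weekday and temperature across the days where that
#' minute is non-missing. Minutes with fewer than `min_obs` usable days, or
#' whose fit fails, fall back to a model pooled over the enclosing hour and,
#' failing that, over the whole day (flagged `pooled = TRUE`). A minute
#' whose observed counts are all zero gets fitted rate exactly 0 (the
#' Poisson MLE limit) without storing an infinite coefficient
#' (`zero_rate = TRUE`).
#'
#' @param classified One participant's classified minutes
#'   ([classify_minutes()]).
#' @param covariates Day-level covariates with `weekday` and
#'   `temperature_f` (plus `date` or `day_index` to align on).
#' @param min_obs Minimum number of complete days for a minute-specific fit
#'   (default 5).
#' @return `data.table` with one row per minute: `minute, alpha, beta,
#'   gamma, n_complete, pooled, zero_rate`.
#' @export
fit_minute_models <- function(classified, covariates, min_obs = 5L) {
  dt <- data.table::as.data.table(classified)
  stopifnot(all(c("day_index", "minute", "resolved_steps") %in% names(dt)))
  if (length(unique(dt$participant_id)) > 1L)
    stop("fit_minute_models() expects a single participant", call. = FALSE)
  days <- sort(unique(dt$day_index))
  nd <- length(days)
  cov <- covariates_for_days(dt, covariates, days)
  Y <- matrix(NA_real_, MINUTES_PER_DAY, nd)
  Y[cbind(dt$minute + 1L, match(dt$day_index, days))] <- dt$resolved_steps
  if (!any(is.finite(Y)))
    stop("imputation infeasible: no complete (non-missing) minutes at all",
         call. = FALSE)

  out <- data.table::data.table(
    minute = 0:(MINUTES_PER_DAY - 1L),
    alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
    n_complete = 0L, pooled = FALSE, zero_rate = FALSE)

  pool_cache <- new.env(parent = emptyenv())
  pooled_fit <- function(rows) {
    # stack all observed (minute, day) cells of the given minute rows
    sub <- Y[rows, , drop = FALSE]
    obs <- which(is.finite(sub), arr.ind = TRUE)
    if (nrow(obs) < min_obs) return(NULL)
    f <- fit_poisson_rz(sub[obs],
                        cov$weekday[obs[, 2L]],
                        cov$temperature_f[obs[, 2L]])
    if (f$ok) f else NULL
  }
  day_pool <- NULL  # computed lazily once

  for (t in 1:MINUTES_PER_DAY) {
    y <- Y[t, ]
    obs <- is.finite(y)
    n_obs <- sum(obs)
    fit <- NULL
    if (n_obs >= min_obs)
      fit <- local({
        f <- fit_poisson_rz(y[obs], cov$weekday[obs], cov$temperature_f[obs])
        if (f$ok) f else NULL
      })
    pooled <- FALSE
    if (is.null(fit)) {
      pooled <- TRUE
      h <- as.character((t - 1L) %/% 60L)
      if (is.null(pool_cache[[h]]))
        pool_cache[[h]] <- list(fit = pooled_fit(((t - 1L) %/% 60L) * 60L + 1:60))
      fit <- pool_cache[[h]]$fit
      if (is.null(fit)) {
        if (is.null(day_pool)) day_pool <- pooled_fit(1:MINUTES_PER_DAY)
        fit <- day_pool
      }
      if (is.null(fit))
        stop("imputation infeasible: no usable complete data", call. = FALSE)
    }
    data.table::set(out, i = t, j = c("alpha", "beta", "gamma",
                                      "n_complete", "pooled", "zero_rate"),
                    value = list(fit$alpha, fit$beta, fit$gamma,
                                 n_obs, pooled, fit$zero_rate))
  }
  out
}

#' Evaluate the fitted minute rates for one day's covariates
#'
#' @param fits Output of [fit_minute_models()].
#' @param weekday 0/1 weekday indicator for the day.
#' @param temperature_f Temperature (deg F) for the day.
#' @param max_rate Physiological ceiling on a one-minute step rate
#'   (default 300 steps/min, above any sustained human cadence); caps
#'   extrapolation of the log-linear model outside the observed covariate
#'   range.
#' @return Length-1440 vector of fitted rates
#'   `exp(alpha_t + beta_t * weekday + gamma_t * temperature_f)` (0 where
#'   `zero_rate`), capped at `max_rate`.
#' @export
predict_minute_rates <- function(fits, weekday, temperature_f,
                                 max_rate = 300) {
  lam <- exp(fits$alpha + fits$beta * weekday + fits$gamma * temperature_f)
  lam[fits$zero_rate] <- 0
  pmin(lam, max_rate)
}

#' Impute one day's missing minutes
#'
#' WORN and CARRIED minutes keep their known counts; MISSING minutes receive
#' the fitted rate from the per-minute models evaluated at the day's
#' covariates.
#'
#' @param day_classified The day's classified minutes (at most 1440 rows;
#'   minutes absent from the records count as MISSING).
#' @param fits Output of [fit_minute_models()].
#' @param weekday,temperature_f The day's covariates.
#' @return List with `values` (length-1440 numeric) and `imputed_mask`
#'   (length-1440 logical).
#' @export
impute_day <- function(day_classified, fits, weekday, temperature_f) {
  if (length(weekday) != 1L || length(temperature_f) != 1L ||
      !is.finite(temperature_f))
    stop("a single weekday/temperature pair is required for the day",
         call. = FALSE)
  values <- rep(NA_real_, MINUTES_PER_DAY)
  if (!is.null(day_classified) && nrow(day_classified) > 0L) {
    dd <- data.table::as.data.table(day_classified)
    values[dd$minute + 1L] <- dd$resolved_steps
  }
  mask <- !is.finite(values)
  if (any(mask)) {
    lam <- predict_minute_rates(fits, weekday, temperature_f)
    values[mask] <- lam[mask]
  }
  list(values = values, imputed_mask = mask)
}

#' Smooth imputed minutes with a penalized spline
#'
#' Fits a GCV-penalized cubic smoothing spline over the minute index to the
#' full day's vector and replaces the values at *imputed* positions with the
#' smoothed curve (clamped at 0). Observed minutes are never altered. A day
#' with nothing imputed, or a constant day, passes through unchanged.
#'
#' @param values Length-1440 numeric vector (observed + raw imputed).
#' @param imputed_mask Length-1440 logical marking imputed positions.
#' @param ... Passed to [stats::smooth.spline()] (e.g. `spar` or `df` to
#'   override the GCV penalty choice).
#' @return List with smoothed `values` and the unchanged `imputed_mask`.
#' @export
smooth_imputed <- function(values, imputed_mask, ...) {
  stopifnot(length(values) == MINUTES_PER_DAY,
            length(imputed_mask) == MINUTES_PER_DAY)
  if (any(imputed_mask) && sd(values) > 0) {
    fit <- smooth.spline(x = 0:(MINUTES_PER_DAY - 1L), y = values, ...)
    sm <- predict(fit, x = which(imputed_mask) - 1L)$y
    values[imputed_mask] <- pmax(sm, 0)
  }
  list(values = values, imputed_mask = imputed_mask)
}

#' Aggregate imputed minutes into the daily analysis series
#'
#' @param minute_values `data.table` with columns `day_index, minute, value,
#'   imputed`, covering every trial day.
#' @param design A [trial_design()] object.
#' @param sequence Sequence name or 6 block labels.
#' @param covariates Day-level covariates (`weekday`, `temperature_f`).
#' @param participant_id Identifier for the output rows.
#' @return The daily series: `participant_id, day_index, block, total_steps,
#'   fraction_imputed, weekday, temperature_f`, one row per trial day.
#' @export
daily_totals <- function(minute_values, design, sequence, covariates,
                         participant_id = "P01") {
  mv <- data.table::as.data.table(minute_values)
  nd <- n_trial_days(design)
  days <- sort(unique(mv$day_index))
  if (length(days) != nd || !identical(as.integer(days), 0:(nd - 1L)))
    stop(sprintf("day count mismatch: design expects %d days 0..%d", nd,
                 nd - 1L), call. = FALSE)
  agg <- mv[, list(total_steps = sum(value),
                   fraction_imputed = mean(imputed)), by = "day_index"]
  data.table::setorderv(agg, "day_index")
  cov <- covariates_for_days(mv, covariates, agg$day_index)
  blocks <- day_blocks(design, sequence)
  data.table::data.table(
    participant_id = participant_id, day_index = agg$day_index,
    block = blocks[agg$day_index + 1L], total_steps = agg$total_steps,
    fraction_imputed = agg$fraction_imputed,
    weekday = cov$weekday, temperature_f = cov$temperature_f)
}

#' Run the full imputation stage for one participant
#'
#' Fits the per-minute models, imputes and (optionally) spline-smooths every
#' trial day, and aggregates to the daily analysis series. Trial days with
#' no records at all are treated as 1440 MISSING minutes and fully imputed.
#'
#' @param classified One participant's classified minutes.
#' @param covariates Day-level covariates (`weekday`, `temperature_f`).
#' @param design A [trial_design()] object.
#' @param sequence Sequence name or 6 block labels.
#' @param min_obs Passed to [fit_minute_models()].
#' @param smooth Apply [smooth_imputed()] per day (default TRUE).
#' @return List with `fits`, `minutes` (`day_index, minute, value, imputed`)
#'   and `daily` (see [daily_totals()]).
#' @export
impute_participant <- function(classified, covariates, design, sequence,
                               min_obs = 5L, smooth = TRUE) {
  dt <- data.table::as.data.table(classified)
  pid <- dt$participant_id[1L]
  nd <- n_trial_days(design)
  fits <- fit_minute_models(dt, covariates, min_obs = min_obs)
  cov <- covariates_for_days(dt, covariates, 0:(nd - 1L))
  day_list <- split(dt, by = "day_index", keep.by = TRUE)
  vals <- vector("list", nd)
  for (d in 0:(nd - 1L)) {
    dd <- day_list[[as.character(d)]]
    imp <- impute_day(dd, fits, cov$weekday[d + 1L],
                      cov$temperature_f[d + 1L])
    if (smooth)
      imp <- smooth_imputed(imp$values, imp$imputed_mask)
    vals[[d + 1L]] <- data.table::data.table(
      day_index = d, minute = 0:(MINUTES_PER_DAY - 1L),
      value = imp$values, imputed = imp$imputed_mask)
  }
  minutes <- data.table::rbindlist(vals)
  daily <- daily_totals(minutes, design, sequence, covariates,
                        participant_id = pid)
  list(fits = fits, minutes = minutes, daily = daily)
}

#' Daily totals without imputation (zero-filled)
#'
#' The comparison series the imputation is meant to improve on: MISSING
#' minutes contribute 0 (the device's recorded value), as if non-wear zeros
#' were taken at face value.
#'
#' @inheritParams impute_participant
#' @return Daily series in the same shape as [daily_totals()].
#' @export
observed_daily_totals <- function(classified, covariates, design, sequence) {
  dt <- data.table::as.data.table(classified)
  nd <- n_trial_days(design)
  agg <- dt[, list(total = sum(resolved_steps, na.rm = TRUE),
                   n_missing = sum(wear == "MISSING")), by = "day_index"]
  full <- data.table::data.table(day_index = 0:(nd - 1L))
  agg <- agg[full, on = "day_index"]
  agg[is.na(total), `:=`(total = 0, n_missing = MINUTES_PER_DAY)]
  data.table::setorderv(agg, "day_index")
  cov <- covariates_for_days(dt, covariates, agg$day_index)
  blocks <- day_blocks(design, sequence)
  data.table::data.table(
    participant_id = dt$participant_id[1L], day_index = agg$day_index,
    block = blocks[agg$day_index + 1L], total_steps = agg$total,
    fraction_imputed = agg$n_missing / MINUTES_PER_DAY,
    weekday = cov$weekday, temperature_f = cov$temperature_f)
}
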