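test_that("intercept-only minute fit returns log of the sample mean", {
  # r and z constant across complete days -> both columns collapse into the
  # intercept and alpha_t is the log sample mean (Poisson MLE)
  cl <- make_uniform_classified(c(2L, 4L, 6L), weekday = c(1L, 1L, 1L),
                                temperature_f = c(60, 60, 60))
  fits <- fit_minute_models(cl, cov_table(c(1L, 1L, 1L), c(60, 60, 60)),
                            min_obs = 3L)
  expect_equal(fits$alpha, rep(log(4), 1440), tolerance = 1e-8)
  expect_equal(fits$beta, rep(0, 1440))
  expect_equal(fits$gamma, rep(0, 1440))
  expect_false(any(fits$pooled))
  expect_equal(fits$n_complete, rep(3L, 1440))
})

test_that("all-zero minutes get fitted rate 0 with finite coefficients", {
  cl <- make_uniform_classified(c(0L, 0L, 0L), weekday = c(1L, 0L, 1L),
                                temperature_f = c(55, 60, 65))
  fits <- fit_minute_models(cl, cov_table(c(1L, 0L, 1L), c(55, 60, 65)),
                            min_obs = 3L)
  expect_true(all(fits$zero_rate))
  expect_true(all(is.finite(fits$alpha)))
  expect_equal(predict_minute_rates(fits, 1L, 60), rep(0, 1440))
})

test_that("minute fits recover known coefficients (oracle: direct ML optimization)", {
  set.seed(61)
  nd <- 200L
  truth <- c(alpha = log(3), beta = 0.15, gamma = 0.012)
  r <- rep(c(1L, 1L, 1L, 1L, 1L, 0L, 0L), length.out = nd)
  z <- rnorm(nd, 60, 10)
  lam <- exp(truth["alpha"] + truth["beta"] * r + truth["gamma"] * (z - 60))
  y <- rpois(nd, lam)
  dt <- data.table::CJ(day_index = 0:(nd - 1L), minute = 0:1439)
  dt[, `:=`(participant_id = "P01", steps = y[day_index + 1L],
            heart_rate_present = TRUE)]
  cl <- classify_minutes(dt)
  cov <- cov_table(r, z - 60)
  fits <- fit_minute_models(cl, cov, min_obs = 5L)

  X <- cbind(1, r, z - 60)
  b_oracle <- oracle_poisson_mle(y, X)
  # same MLE from both routes
  expect_equal(unname(unlist(fits[1L, c("alpha", "beta", "gamma")])),
               unname(b_oracle), tolerance = 1e-4)
  # and within 3 asymptotic SEs of the generating truth
  W <- exp(as.numeric(X %*% b_oracle))
  se <- sqrt(diag(solve(crossprod(X * sqrt(W)))))
  expect_true(all(abs(b_oracle - truth) < 3 * se))
})

test_that("imputation fills only MISSING minutes with model predictions", {
  fits <- data.table::data.table(
    minute = 0:1439, alpha = log(2), beta = 0.1, gamma = 0.01,
    n_complete = 10L, pooled = FALSE, zero_rate = FALSE)
  # a day with no missing minutes is returned unchanged
  day <- data.table::data.table(
    participant_id = "P01", day_index = 0L, minute = 0:1439,
    steps = rep(3L, 1440), heart_rate_present = TRUE)
  cl <- classify_minutes(day)
  out <- impute_day(cl, fits, weekday = 1L, temperature_f = 60)
  expect_equal(out$values, rep(3, 1440))
  expect_false(any(out$imputed_mask))
  # a missing weekday minute at temperature z -> exp(alpha + beta + gamma z)
  day$heart_rate_present[5L] <- FALSE
  day$steps[5L] <- 0L
  out <- impute_day(classify_minutes(day), fits, 1L, 55)
  expect_equal(out$values[5L], exp(log(2) + 0.1 + 0.01 * 55))
  expect_identical(which(out$imputed_mask), 5L)
  expect_error(impute_day(cl, fits, 1L, NA_real_), "temperature")
})

test_that("an all-missing day under intercept-only fits reproduces per-minute means", {
  set.seed(62)
  nd <- 30L
  counts <- matrix(rpois(1440 * nd, 4), 1440, nd)
  dt <- data.table::CJ(day_index = 0:(nd - 1L), minute = 0:1439)
  data.table::setorderv(dt, c("day_index", "minute"))
  dt[, `:=`(participant_id = "P01",
            steps = as.integer(counts[cbind(minute + 1L, day_index + 1L)]),
            heart_rate_present = TRUE)]
  cl <- classify_minutes(dt)
  cov <- cov_table(rep(1L, nd), rep(60, nd))
  fits <- fit_minute_models(cl, cov)
  out <- impute_day(NULL, fits, weekday = 1L, temperature_f = 60)
  expect_true(all(out$imputed_mask))
  expect_equal(out$values, rowMeans(counts), tolerance = 1e-6)
})

test_that("spline smoothing touches only imputed positions", {
  set.seed(63)
  v <- rpois(1440, 10)
  mask <- rep(FALSE, 1440)
  expect_identical(smooth_imputed(v, mask)$values, v)
  mask[300:400] <- TRUE
  out <- smooth_imputed(v, mask)
  expect_identical(out$values[!mask], as.numeric(v[!mask]))
  expect_false(identical(out$values[mask], as.numeric(v[mask])))
  expect_true(all(out$values >= 0))
  # constants are reproduced exactly
  expect_equal(smooth_imputed(rep(5, 1440), mask)$values, rep(5, 1440))
})

test_that("infinite smoothing penalty approaches the least-squares line", {
  set.seed(64)
  x <- 0:1439
  v <- 3 + 0.01 * x + rnorm(1440, 0, 4)
  mask <- rep(TRUE, 1440)
  out <- smooth_imputed(v, mask, spar = 2)
  line <- lm.fit(cbind(1, x), v)$fitted.values  # independent OLS oracle
  expect_lt(max(abs(out$values - pmax(line, 0))), 0.05)
})

test_that("daily totals aggregate correctly and label blocks from the design", {
  d <- tiny_design()
  nd <- n_trial_days(d)
  mv <- data.table::CJ(day_index = 0:(nd - 1L), minute = 0:1439)
  mv[, `:=`(value = 1, imputed = FALSE)]
  cov <- cov_table(rep(1L, nd), rep(60, nd))
  ds <- daily_totals(mv, d, "A", cov)
  expect_equal(ds$total_steps, rep(1440, nd))
  expect_equal(ds$block, day_blocks(d, "A"))
  mv[, value := 0]
  expect_equal(daily_totals(mv, d, "A", cov)$total_steps, rep(0, nd))
  expect_error(daily_totals(mv[day_index < 3L], d, "A", cov),
               "day count mismatch")
})

test_that("with zero missingness the imputation pipeline is the identity", {
  d <- tiny_design()
  p <- sim_params(wear_prob_profile = rep(1, 1440))
  part <- generate_participant(p, d, "A", seed = 65)
  obs <- apply_missingness(part, p, seed = 66)
  cl <- classify_minutes(obs)
  cl[, day_index := as.integer(date - min(date))]
  cov <- part$days[, c("day_index", "weekday", "temperature_f")]
  res <- impute_participant(cl, cov, d, "A")
  expect_equal(res$daily$total_steps, as.numeric(part$days$true_total))
  expect_true(all(res$daily$fraction_imputed == 0))
  # observed minutes are never altered (asserted on a lossy run too)
  p2 <- sim_params()
  part2 <- generate_participant(p2, d, "A", seed = 65)
  obs2 <- apply_missingness(part2, p2, seed = 67)
  cl2 <- classify_minutes(obs2)
  cl2[, day_index := as.integer(date - min(date))]
  res2 <- impute_participant(cl2, part2$days[
    , c("day_index", "weekday", "temperature_f")], d, "A")
  merged <- merge(res2$minutes, cl2[, c("day_index", "minute",
                                        "resolved_steps", "wear")],
                  by = c("day_index", "minute"))
  obs_rows <- merged[wear != "MISSING"]
  expect_equal(obs_rows$value, obs_rows$resolved_steps)
  expect_identical(unique(merged[wear == "MISSING"]$imputed), TRUE)
  expect_true(all(is.finite(res2$minutes$value)) &&
                all(res2$minutes$value >= 0))
})

test_that("imputed totals beat zero-filled totals under structured missingness", {
  # >= 20% of minutes missing, concentrated in the high-activity daytime
  wp <- rep(1, 1440)
  wp[481:1200] <- 0.5
  p <- sim_params(wear_prob_profile = wp, carry_prob = 0.1, daily_sd = 800)
  truth <- imputed <- zerofill <- numeric(0)
  for (i in 1:2) {  # 2 x 98 = 196 simulated days
    part <- generate_participant(p, trial_design(), "A", seed = 70 + i)
    obs <- apply_missingness(part, p, seed = 80 + i)
    cl <- classify_minutes(obs)
    cl[, day_index := as.integer(date - min(date))]
    cov <- part$days[, c("day_index", "weekday", "temperature_f")]
    expect_gt(mean(cl$wear == "MISSING"), 0.2)
    res <- impute_participant(cl, cov, trial_design(), "A")
    zf <- observed_daily_totals(cl, cov, trial_design(), "A")
    truth <- c(truth, part$days$true_total)
    imputed <- c(imputed, res$daily$total_steps)
    zerofill <- c(zerofill, zf$total_steps)
  }
  bias_imp <- abs(mean(imputed) - mean(truth))
  bias_zf <- abs(mean(zerofill) - mean(truth))
  expect_lt(bias_imp, bias_zf)
})
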