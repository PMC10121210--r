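test_that("build_design constructs the indicator matrix from block labels", {
  daily <- make_daily()
  pr <- build_design(daily)
  expect_equal(dim(pr$design_matrix), c(84L, 3L))
  expect_equal(sum(pr$design_matrix[, "yoga"]), 28)
  expect_equal(sum(pr$design_matrix[, "massage"]), 28)
  expect_equal(pr$n, 84L)
  pr_b <- build_design(daily, include_baseline = TRUE)
  expect_equal(pr_b$n, 98L)
  base_rows <- pr_b$day_labels == "BASELINE"
  expect_true(all(pr_b$design_matrix[base_rows, c("yoga", "massage")] == 0))
  # a treatment with no analysis days is a named rank-deficiency error
  no_massage <- daily[daily$block != "MASSAGE", ]
  expect_error(build_design(no_massage), "MASSAGE")
})

test_that("carryover column flags the first d days after an active block", {
  d <- trial_design()
  daily <- make_daily(d, "A")
  pr <- build_design(daily, carryover_lag_days = 2L)
  expect_true("carryover" %in% colnames(pr$design_matrix))
  # independent oracle: scan block boundaries directly
  blocks <- day_blocks(d, "A")[-(1:14)]
  expected <- numeric(84)
  for (i in seq_along(expected)) {
    b <- (i - 1) %/% 14 + 1         # block number 1..6
    pos <- (i - 1) %% 14 + 1        # day within block
    if (b > 1 && pos <= 2 &&
        blocks[(b - 2) * 14 + 1] %in% c("YOGA", "MASSAGE"))
      expected[i] <- 1
  }
  expect_equal(unname(pr$design_matrix[, "carryover"]), expected)
  expect_equal(sum(expected), 2 * 3)  # 3 blocks in sequence A follow active
})

test_that("OLS matches the normal-equations oracle", {
  set.seed(101)
  pr1 <- rand_problem(12L, 1L)
  pr1$design_matrix <- pr1$design_matrix[, 1L, drop = FALSE]
  pr1$p <- 1L
  expect_equal(unname(ols_fit(pr1)$beta), mean(pr1$response))
  # noiseless response is reproduced exactly
  pr2 <- rand_problem(20L, 3L, sd = 0)
  fit2 <- ols_fit(pr2)
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-10)
  for (i in 1:20) {
    pr <- rand_problem(10L, 3L)
    beta_oracle <- solve(t(pr$design_matrix) %*% pr$design_matrix,
                         t(pr$design_matrix) %*% pr$response)
    expect_equal(unname(ols_fit(pr)$beta), unname(drop(beta_oracle)),
                 tolerance = 1e-10)
  }
  pr$design_matrix[, 3L] <- pr$design_matrix[, 2L]
  expect_error(ols_fit(pr), "rank deficient")
})

test_that("AR(1) moment estimator behaves at the boundaries and under the null", {
  alt <- estimate_ar1(rep(c(1, -1), 3))
  expect_equal(alt$rho, -0.999)  # clamped perfect alternation
  set.seed(102)
  iid <- estimate_ar1(rnorm(1e4))
  expect_lt(abs(iid$rho), 3 / sqrt(1e4))
  expect_warning(z <- estimate_ar1(rep(0, 10)), "zero-variance")
  expect_equal(z$rho, 0)
  expect_error(estimate_ar1(c(1, 2)), "at least 3")
  # df-corrected variance
  set.seed(103)
  e <- rnorm(50)
  expect_equal(estimate_ar1(e, p = 3L)$sigma2, sum(e^2) / 47)
})

test_that("rho estimates carry the known small-sample bias at n = 84", {
  # E[rho_hat] sits below the truth by roughly (1+3rho)/n (first-order
  # small-sample bias), so the replicate mean should land just under 0.3
  set.seed(104)
  rhos <- replicate(2000, {
    e <- as.numeric(arima.sim(list(ar = 0.3), n = 84, sd = 1))
    estimate_ar1(e)$rho
  })
  expect_gt(mean(rhos), 0.22)
  expect_lt(mean(rhos), 0.30)
})

test_that("AR(1) covariance has the stated entries and is positive definite", {
  expect_equal(ar1_covariance(list(rho = 0, sigma2 = 4), 3L), diag(4, 3))
  V <- ar1_covariance(list(rho = 0.5, sigma2 = 1), 3L)
  expect_equal(V, matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3),
               ignore_attr = TRUE)
  set.seed(105)
  for (i in 1:25) {
    n <- sample(2:8, 1L)
    V <- ar1_covariance(list(rho = runif(1, -0.95, 0.95),
                             sigma2 = runif(1, 0.1, 5)), n)
    expect_true(all(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
  expect_error(ar1_covariance(list(rho = 1, sigma2 = 1), 3L), "rho")
})

test_that("GLS collapses to OLS under V = I and matches closed forms", {
  set.seed(106)
  for (i in 1:20) {
    pr <- rand_problem(sample(10:50, 1L), sample(2:4, 1L))
    g <- gls_fit(pr, diag(pr$n))
    o <- ols_fit(pr)
    expect_lt(max(abs(g$beta - o$beta)), 1e-8)
  }
  # intercept-only GLS is the precision-weighted mean
  n <- 8L
  pr <- rand_problem(n, 1L)
  pr$design_matrix <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  pr$p <- 1L
  V <- ar1_covariance(list(rho = 0.6, sigma2 = 2), n)
  g <- gls_fit(pr, V)
  ones <- rep(1, n)
  wmean <- drop(t(ones) %*% solve(V) %*% pr$response) /
    drop(t(ones) %*% solve(V) %*% ones)
  expect_equal(unname(g$beta), wmean, tolerance = 1e-10)
  expect_error(gls_fit(pr, matrix(-1, n, n)), "positive definite")
})

test_that("whitening-path GLS equals the direct dense-inverse formula", {
  set.seed(107)
  for (i in 1:20) {
    n <- sample(10:50, 1L)
    pr <- rand_problem(n, sample(2:4, 1L))
    V <- ar1_covariance(list(rho = runif(1, -0.9, 0.9),
                             sigma2 = runif(1, 0.5, 4)), n)
    g <- gls_fit(pr, V)
    Vi <- solve(V)
    direct <- solve(t(pr$design_matrix) %*% Vi %*% pr$design_matrix,
                    t(pr$design_matrix) %*% Vi %*% pr$response)
    expect_lt(max(abs(g$beta - drop(direct))), 1e-8)
  }
})

test_that("feasible GLS converges and is location-equivariant", {
  set.seed(108)
  # noiseless: beta recovered exactly at any iterate
  daily <- make_daily(totals = 8000 + 1500 * (day_blocks(trial_design(),
                                                         "A") == "YOGA"))
  pr <- build_design(daily)
  fit <- suppressWarnings(feasible_gls(pr))
  expect_equal(unname(fit$beta[c("yoga", "massage")]), c(1500, 0),
               tolerance = 1e-8)
  # rho = 0 data: rho_hat near 0 and beta near OLS
  p <- sim_params(ar1_rho = 0, daily_sd = 1200,
                  treatment_daily_effect = c(YOGA = 800, MASSAGE = -300))
  ds <- simulate_daily_series(p, seed = 109)
  pr <- build_design(ds)
  fit <- feasible_gls(pr)
  expect_lt(abs(fit$ar1$rho), 3 / sqrt(pr$n))
  expect_lt(max(abs(fit$beta - ols_fit(pr)$beta)), 200)
  expect_true(fit$converged)
  # adding a constant moves only the intercept
  pr2 <- pr
  pr2$response <- pr$response + 5000
  fit2 <- feasible_gls(pr2)
  expect_equal(unname(fit2$beta["intercept"] - fit$beta["intercept"]), 5000,
               tolerance = 1e-6)
  expect_equal(fit2$beta[c("yoga", "massage")],
               fit$beta[c("yoga", "massage")], tolerance = 1e-6)
})

test_that("effect classification follows the CI rule", {
  expect_equal(classify_effect(200, 800), "POSITIVE")
  expect_equal(classify_effect(-600, -50), "NEGATIVE")
  expect_equal(classify_effect(-100, 300), "NO_EFFECT")
  expect_error(classify_effect(3, 1))
})

test_that("contrasts propagate the coefficient covariance correctly", {
  beta <- c(intercept = 7000, yoga = 400, massage = 400)
  Sigma <- diag(c(50, 100, 100)^2)
  dimnames(Sigma) <- list(names(beta), names(beta))
  out <- effect_contrasts(beta, Sigma, df = 81L)
  expect_equal(out$beta_hat[out$contrast == "MASSAGE_VS_YOGA"], 0)
  expect_equal(out$se[out$contrast == "MASSAGE_VS_YOGA"], sqrt(2) * 100)
  # random covariance oracle: c' Sigma c with c = (0, -1, 1)
  set.seed(110)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    Sigma <- crossprod(A) + diag(0.1, 3)
    dimnames(Sigma) <- list(names(beta), names(beta))
    out <- effect_contrasts(beta, Sigma, df = 40L)
    cvec <- c(0, -1, 1)
    expect_equal(out$se[out$contrast == "MASSAGE_VS_YOGA"],
                 sqrt(drop(cvec %*% Sigma %*% cvec)), tolerance = 1e-10)
  }
  # t quantiles at the stated df
  expect_equal(out$ci_high - out$beta_hat, qt(0.975, 40) * out$se,
               tolerance = 1e-10)
})
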