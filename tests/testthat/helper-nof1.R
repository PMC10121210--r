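# shared fixture builders; everything is generated in code

# a small design that keeps minute-level tests fast
tiny_design <- function(baseline_days = 2L, block_days = 2L) {
  trial_design(baseline_days = baseline_days, block_days = block_days)
}

# daily series built directly from block labels (no simulation)
make_daily <- function(design = trial_design(), sequence = "A",
                       totals = NULL, participant_id = "P01",
                       start_date = as.Date("2020-01-06")) {
  blocks <- day_blocks(design, sequence)
  nd <- length(blocks)
  dates <- start_date + 0:(nd - 1L)
  if (is.null(totals)) totals <- rep(8000, nd)
  data.table::data.table(
    participant_id = participant_id, day_index = 0:(nd - 1L),
    block = blocks, total_steps = as.numeric(totals), fraction_imputed = 0,
    weekday = as.integer(format(dates, "%u") <= 5L),
    temperature_f = 60)
}

# random full-rank regression problem wrapped as an nof1_problem
rand_problem <- function(n, p, sd = 1) {
  X <- matrix(c(rep(1, n), rnorm(n * (p - 1L))), n, p)
  colnames(X) <- c("intercept",
                   if (p > 1L) paste0("x", seq_len(p - 1L)))
  beta <- rnorm(p, 0, 3)
  y <- as.numeric(X %*% beta + rnorm(n, 0, sd))
  structure(list(response = y, design_matrix = X,
                 day_labels = rep("USUAL_CARE", n), day_index = 0:(n - 1L),
                 n = n, p = p),
            class = "nof1_problem")
}

# classified-minute table where every minute shares the same per-day counts
make_uniform_classified <- function(counts_by_day, weekday, temperature_f,
                                    participant_id = "P01") {
  nd <- length(counts_by_day)
  dt <- data.table::CJ(day_index = 0:(nd - 1L), minute = 0:1439)
  dt[, `:=`(participant_id = participant_id,
            steps = counts_by_day[day_index + 1L],
            heart_rate_present = TRUE)]
  classify_minutes(dt)
}

cov_table <- function(weekday, temperature_f) {
  data.table::data.table(day_index = seq_along(weekday) - 1L,
                         weekday = weekday, temperature_f = temperature_f)
}

# independent Poisson log-likelihood maximizer (oracle for glm-based fits)
oracle_poisson_mle <- function(y, X, start = NULL) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(exp(eta)) - sum(y * eta)
  }
  if (is.null(start)) start <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1L))
  optim(start, nll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-12))$par
}
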