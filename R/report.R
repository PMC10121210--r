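# --- cohort summaries and the static per-participant report ----------------

#' Fixed-effect inverse-variance pooling
#'
#' Pools one contrast's per-participant estimates into the forest plot's
#' summary row: `beta_pool = sum(w_i beta_i) / sum(w_i)` with
#' `w_i = 1 / SE_i^2`, `SE_pool = (sum w_i)^(-1/2)`, normal-quantile 95% CI.
#'
#' @param estimates `data.table` of one contrast's per-participant rows
#'   (needs `beta_hat`, `se`).
#' @param level Confidence level (default 0.95).
#' @return One-row `data.table`: `participant_id = "POOLED", contrast,
#'   beta_hat, se, ci_low, ci_high, label, weight`.
#' @export
pool_effects <- function(estimates, level = 0.95) {
  est <- data.table::as.data.table(estimates)
  stopifnot(nrow(est) >= 1L)
  if (length(unique(est$contrast)) > 1L)
    stop("pool_effects() pools a single contrast at a time", call. = FALSE)
  if (any(!is.finite(est$se) | est$se <= 0))
    stop("all standard errors must be finite and positive", call. = FALSE)
  w <- 1 / est$se^2
  beta <- sum(w * est$beta_hat) / sum(w)
  se <- 1 / sqrt(sum(w))
  zq <- qnorm(1 - (1 - level) / 2)
  lo <- beta - zq * se
  hi <- beta + zq * se
  data.table::data.table(
    participant_id = "POOLED", contrast = est$contrast[1L],
    beta_hat = beta, se = se, ci_low = lo, ci_high = hi,
    label = classify_effect(lo, hi), weight = sum(w))
}

#' Forest-plot table: per-participant rows plus a pooled row per contrast
#'
#' @param effects Combined effects table ([analyze_participant()] rows for
#'   the whole cohort).
#' @return `data.table` with `3k + 3` rows for `k` participants (a pooled
#'   row closes each contrast), columns `participant_id, contrast,
#'   beta_hat, se, ci_low, ci_high, label, weight`.
#' @export
forest_table <- function(effects) {
  eff <- data.table::as.data.table(effects)
  keep <- c("participant_id", "contrast", "beta_hat", "se", "ci_low",
            "ci_high", "label")
  rows <- lapply(CONTRASTS, function(ct) {
    sub <- eff[contrast == ct, keep, with = FALSE]
    sub[, weight := 1 / se^2]
    data.table::rbindlist(list(sub, pool_effects(sub)), use.names = TRUE)
  })
  data.table::rbindlist(rows)
}

#' Count participants by effect classification
#'
#' The Table-1-style heterogeneity summary: for each contrast, how many
#' participants were classified positive, negative, or no-effect.
#'
#' @param effects Combined effects table; every participant must carry all
#'   three contrasts.
#' @return `data.table`: `contrast, n_positive, n_negative, n_no_effect`;
#'   rows sum to the cohort size.
#' @export
counts_table <- function(effects) {
  eff <- data.table::as.data.table(effects)
  ids <- unique(eff$participant_id)
  for (ct in CONTRASTS) {
    have <- eff[contrast == ct, participant_id]
    if (!setequal(have, ids) || anyDuplicated(have))
      stop("every participant needs exactly one estimate for contrast ", ct,
           call. = FALSE)
  }
  out <- eff[, list(
    n_positive = sum(label == "POSITIVE"),
    n_negative = sum(label == "NEGATIVE"),
    n_no_effect = sum(label == "NO_EFFECT")), by = "contrast"]
  out[match(CONTRASTS, out$contrast)]
}

forest_panel_png <- function(forest, path, title) {
  grDevices::png(path, width = 900, height = 200 + 28 * nrow(forest))
  on.exit(grDevices::dev.off())
  forest <- forest[order(forest$contrast, forest$participant_id == "POOLED",
                         forest$participant_id)]
  y <- rev(seq_len(nrow(forest)))
  xlim <- range(c(forest$ci_low, forest$ci_high, 0))
  graphics::par(mar = c(4, 12, 3, 2))
  graphics::plot(forest$beta_hat, y, xlim = xlim, pch = 18,
                 cex = ifelse(forest$participant_id == "POOLED", 1.8, 1.1),
                 yaxt = "n", xlab = "difference in daily steps",
                 ylab = "", main = title)
  graphics::segments(forest$ci_low, y, forest$ci_high, y)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::axis(2, at = y, las = 1, cex.axis = 0.8,
                 labels = paste(forest$contrast, forest$participant_id))
  invisible(path)
}

line_graph_png <- function(daily, path, title) {
  grDevices::png(path, width = 900, height = 420)
  on.exit(grDevices::dev.off())
  cols <- c(BASELINE = "grey55", YOGA = "#1b9e77", MASSAGE = "#7570b3",
            USUAL_CARE = "#d95f02")
  graphics::plot(daily$day_index, daily$total_steps, type = "l",
                 col = "grey75", xlab = "trial day", ylab = "daily steps",
                 main = title)
  graphics::points(daily$day_index, daily$total_steps, pch = 16, cex = 0.7,
                   col = cols[daily$block])
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", horiz = TRUE, cex = 0.8)
  invisible(path)
}

boxplot_png <- function(daily, path, title) {
  grDevices::png(path, width = 600, height = 420)
  on.exit(grDevices::dev.off())
  keep <- daily$block %in% BLOCK_LABELS
  graphics::boxplot(total_steps ~ factor(block, levels = BLOCK_LABELS),
                    data = daily[keep, ], xlab = "", ylab = "daily steps",
                    main = title)
  invisible(path)
}

html_table <- function(dt, digits = 1) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "f",
                                                digits = digits) else x
  cells <- vapply(seq_len(nrow(dt)), function(i) {
    paste0("<tr>", paste0("<td>", unlist(lapply(dt[i, ], fmt)),
                          "</td>", collapse = ""), "</tr>")
  }, character(1L))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>\n<tr>",
         paste0("<th>", names(dt), "</th>", collapse = ""), "</tr>\n",
         paste(cells, collapse = "\n"), "\n</table>")
}

#' Render the static trial report
#'
#' Writes the cohort artifacts (`forest.csv`, `counts.csv`, `effects.csv`, a
#' pooled forest panel and an `index.html` overview) plus, per participant,
#' the effects table, a forest panel, a daily-steps line graph colored by
#' block, and a per-treatment boxplot. When a non-imputed effects/daily pair
#' is supplied, each participant page carries both labeled panels. Data
#' tables are deterministic functions of the inputs.
#'
#' @param effects Combined effects table for the cohort.
#' @param daily Combined daily series for the cohort.
#' @param out_dir Output directory (created if needed).
#' @param effects_noimpute,daily_noimpute Optional comparison inputs from
#'   the zero-filled (non-imputed) pipeline.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(effects, daily, out_dir,
                          effects_noimpute = NULL, daily_noimpute = NULL) {
  eff <- data.table::as.data.table(effects)
  dd <- data.table::as.data.table(daily)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  forest <- forest_table(eff)
  counts <- counts_table(eff)
  data.table::fwrite(forest, file.path(out_dir, "forest.csv"))
  data.table::fwrite(counts, file.path(out_dir, "counts.csv"))
  data.table::fwrite(eff, file.path(out_dir, "effects.csv"))
  forest_panel_png(forest[participant_id == "POOLED"],
                   file.path(out_dir, "forest_pooled.png"),
                   "Pooled treatment effects (daily steps)")
  ids <- unique(eff$participant_id)
  sections <- character(0L)
  for (pid in ids) {
    pe <- eff[participant_id == pid]
    pd <- dd[participant_id == pid]
    stem <- file.path(out_dir, pid)
    forest_panel_png(forest[participant_id == pid],
                     paste0(stem, "_forest.png"),
                     paste(pid, "treatment effects"))
    line_graph_png(pd, paste0(stem, "_steps.png"),
                   paste(pid, "daily steps (imputed)"))
    boxplot_png(pd, paste0(stem, "_box.png"),
                paste(pid, "daily steps by treatment"))
    extra <- ""
    if (!is.null(effects_noimpute)) {
      pe2 <- data.table::as.data.table(effects_noimpute)[
        participant_id == pid]
      extra <- paste0("<h3>", pid,
                      " &mdash; non-imputed (zero-filled) comparison</h3>\n",
                      html_table(pe2))
    }
    sections <- c(sections, paste0(
      "<h2>", pid, "</h2>\n<h3>", pid, " &mdash; imputed</h3>\n",
      html_table(pe), "\n", extra,
      sprintf("\n<p><img src='%s_forest.png' width='700'></p>", pid),
      sprintf("<p><img src='%s_steps.png' width='700'></p>", pid),
      sprintf("<p><img src='%s_box.png' width='450'></p>", pid)))
  }
  html <- paste0(
    "<html><head><title>Personalized trial report</title></head><body>\n",
    "<h1>Personalized (N-of-1) activity trial report</h1>\n",
    "<h2>Cohort summary</h2>\n",
    "<p>Effect classification counts per contrast (rows sum to ",
    length(ids), " participants):</p>\n", html_table(counts, digits = 0),
    "\n<p>Pooled rows use fixed-effect inverse-variance weighting; ",
    "whether the original forest display pooled by fixed or random ",
    "effects is not documented, so the fixed-effect convention is used ",
    "here.</p>\n",
    "<p><img src='forest_pooled.png' width='700'></p>\n",
    paste(sections, collapse = "\n"), "\n</body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  invisible(out_dir)
}
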