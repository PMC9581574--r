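# Cross-animal signal-independence QC.
#
# Hour-long traces are compared pairwise with Pearson correlation in three
# categories: left-vs-right within a mouse in the same hour, same-hemisphere
# channels of different mice in the same hour, and the same cross-mouse pairs
# re-paired across different hours (chance level). ANOVA + Tukey across the
# three categories tests whether simultaneous cross-animal correlations
# exceed chance.

comparison_categories <- c("within_mouse_same_hour",
                           "between_mice_same_hour",
                           "between_mice_different_hours")

#' Enumerate the pairwise trace comparisons of the independence analysis
#'
#' Rules (a documented reconstruction of the published comparison matrix,
#' chosen to reproduce its category sizes of 96 / 288 / 288 for 4 mice over
#' 24 h):
#' * within-mouse, same hour: left vs right of each mouse, each hour
#'   (`n_mice * n_hours` pairs);
#' * between mice, same hour: each unordered mouse pair compared on the same
#'   hemisphere (L-L and R-R), each hour (`choose(n_mice,2) * 2 * n_hours`);
#' * between mice, different hours: the same cross-mouse pairs with the
#'   second trace taken from the next hour (circularly), giving an equal
#'   count of chance-level comparisons.
#' Self-comparisons and same-mouse different-hour comparisons are excluded.
#'
#' @param n_mice Number of mice (>= 2).
#' @param n_hours Number of hour-long segments (>= 2).
#' @param channels_per_mouse Channels per mouse (fixed bilateral pair, 2).
#' @return A data.frame with columns `category`, `mouse_a`, `channel_a`
#'   (1 = left, 2 = right), `hour_a`, `mouse_b`, `channel_b`, `hour_b`.
#' @export
enumerate_comparisons <- function(n_mice, n_hours, channels_per_mouse = 2) {
  if (n_mice < 2 || n_hours < 2) {
    lfp_abort("independence analysis needs >= 2 mice and >= 2 hours", "lfpmon_parameter_error")
  }
  if (channels_per_mouse != 2) {
    lfp_abort("the comparison matrix is defined for bilateral (2-channel) recordings",
              "lfpmon_parameter_error")
  }
  rows <- list()
  add <- function(cat, ma, ca, ha, mb, cb, hb) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = cat, mouse_a = ma, channel_a = ca, hour_a = ha,
      mouse_b = mb, channel_b = cb, hour_b = hb)
  }
  for (h in seq_len(n_hours)) {
    for (m in seq_len(n_mice)) add("within_mouse_same_hour", m, 1L, h, m, 2L, h)
  }
  pairs <- utils::combn(n_mice, 2)
  for (h in seq_len(n_hours)) {
    for (p in seq_len(ncol(pairs))) {
      for (ch in 1:2) {
        add("between_mice_same_hour", pairs[1, p], ch, h, pairs[2, p], ch, h)
      }
    }
  }
  for (h in seq_len(n_hours)) {
    h2 <- (h %% n_hours) + 1L
    for (p in seq_len(ncol(pairs))) {
      for (ch in 1:2) {
        add("between_mice_different_hours", pairs[1, p], ch, h, pairs[2, p], ch, h2)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = comparison_categories)
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 2, non-constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    lfp_abort("pearson_r needs two equal-length vectors of length >= 2", "lfpmon_parameter_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    lfp_abort("correlation undefined for a constant input", "lfpmon_parameter_error")
  }
  stats::cor(x, y)
}

#' Empirical cumulative distribution
#'
#' Right-continuous ECDF over the values.
#'
#' @param values Non-empty numeric vector.
#' @return List with sorted unique `x`, cumulative fractions `f`, and the step
#'   function `fun`.
#' @export
empirical_cdf <- function(values) {
  if (!length(values)) lfp_abort("empirical_cdf needs at least one value", "lfpmon_parameter_error")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  list(x = x, f = f(x), fun = f)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square ratio with an F-distribution p-value. Degenerate
#' all-identical input returns `F = 0`, `p = 1`.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return List `F`, `df1`, `df2`, `p`, plus the sums of squares `ss_between`,
#'   `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    lfp_abort("one_way_anova needs >= 2 groups with >= 2 values each", "lfpmon_parameter_error")
  }
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all_v) - length(groups)
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, ss_between = 0, ss_within = 0))
  }
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

#' Tukey's HSD post hoc comparisons
#'
#' Studentized-range comparisons of all group-mean pairs using the pooled
#' within-group variance from [one_way_anova()] (Tukey-Kramer for unequal
#' group sizes).
#'
#' @param groups List of numeric vectors; names label the groups.
#' @param alpha Significance level for the `significant` flag.
#' @return Data.frame `group_a`, `group_b`, `diff`, `q`, `p`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  mse <- an$ss_within / an$df2
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]])
  out$diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$q <- ifelse(se > 0, abs(out$diff) / se, ifelse(out$diff == 0, 0, Inf))
  out$p <- ifelse(is.infinite(out$q), 0,
                  stats::ptukey(out$q, nmeans = k, df = an$df2, lower.tail = FALSE))
  out$p[out$q == 0] <- 1
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Full signal-independence report
#'
#' Takes the session's hour-long microvolt matrices, enumerates the
#' comparison categories, correlates every pair (at a decimated rate to bound
#' memory), and assembles per-category summaries, ECDFs, one-way ANOVA and
#' Tukey post hoc into one report.
#'
#' @param segments List of `[channels x samples]` microvolt matrices, one per
#'   hour in chronological order.
#' @param config A [session_config()] whose `animals` map mice to channels.
#' @param correlate_at_hz Rate at which traces are compared; plain decimation
#'   from `sample_rate_hz` (set equal to `config$sample_rate_hz` for full
#'   rate).
#' @return A list of class `qc_report`: `comparisons` (pair table with `r`),
#'   `by_category` (mean, SEM, n), `ecdf` (per category), `anova`, `tukey`.
#' @export
independence_report <- function(segments, config, correlate_at_hz = 500) {
  stopifnot(inherits(config, "session_config"))
  n_mice <- length(config$animals)
  n_hours <- length(segments)
  if (n_mice < 2) lfp_abort("independence analysis needs >= 2 mice", "lfpmon_parameter_error")
  if (n_hours < 2) {
    lfp_abort("independence analysis needs >= 2 hour segments (the chance category pairs different hours)",
              "lfpmon_parameter_error")
  }
  k <- max(1L, as.integer(round(config$sample_rate_hz / correlate_at_hz)))
  get_trace <- function(mouse, channel, hour) {
    a <- config$animals[[mouse]]
    ch <- if (channel == 1L) a$left_channel else a$right_channel
    x <- segments[[hour]][ch + 1L, ]
    x[seq.int(1L, length(x), by = k)]
  }
  comp <- enumerate_comparisons(n_mice, n_hours)
  comp$r <- vapply(seq_len(nrow(comp)), function(i) {
    pearson_r(get_trace(comp$mouse_a[i], comp$channel_a[i], comp$hour_a[i]),
              get_trace(comp$mouse_b[i], comp$channel_b[i], comp$hour_b[i]))
  }, numeric(1))
  groups <- split(comp$r, comp$category)
  by_cat <- data.frame(category = names(groups),
                       mean = vapply(groups, mean, numeric(1)),
                       sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1)),
                       n = lengths(groups))
  rownames(by_cat) <- NULL
  structure(list(comparisons = comp,
                 by_category = by_cat,
                 ecdf = lapply(groups, empirical_cdf),
                 anova = one_way_anova(groups),
                 tukey = tukey_hsd(groups)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print.data.frame(x$by_category, digits = 4)
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  invisible(x)
}

#' Export a QC report (JSON summary + CSV of all correlations)
#'
#' @param report A `qc_report`.
#' @param out_dir Output directory (created if needed).
#' @return Named paths, invisibly.
#' @export
write_qc_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "qc_report.json")
  csv_path <- file.path(out_dir, "qc_correlations.csv")
  jsonlite::write_json(
    list(by_category = report$by_category,
         anova = report$anova[c("F", "df1", "df2", "p")],
         tukey = report$tukey),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$comparisons, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
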