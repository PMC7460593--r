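# The study's two-stage comparison procedure (variance F-test gating a
# pooled vs Welch t-test) and the endpoint summary computations.

#' Two-stage F-then-t comparison of two replicate sets
#'
#' Reproduces the comparison procedure used throughout the analysis:
#' first a two-sided F-test of variance equality (larger sample variance
#' in the numerator); if its p-value falls below `alpha_level` the two
#' groups are treated as having different variances and a Welch t-test
#' is used, otherwise a pooled-variance Student t-test. The t-test is
#' two-tailed and the difference is called significant when its p-value
#' is below `alpha_level`.
#'
#' The variance gate is driven by the F-test's *p-value*, not the raw F
#' statistic: an F statistic below 0.05 would not be a meaningful
#' variance-equality criterion.
#'
#' @param x,y Numeric vectors of replicate values, each with at least 2
#'   values and finite variance in at least one group.
#' @param alpha_level Significance level for both stages (default 0.05).
#' @return A `comparison_result`: list with `f_statistic`, `p_f`,
#'   `equal_variance_assumed`, `t_statistic`, `df`, `p_t`,
#'   `significant`, `mean_x`, `mean_y`, `n_x`, `n_y`, `labels`.
#' @examples
#' compare_groups(c(1, 2, 3), c(5, 6, 7))   # pooled t = -4.899, p ~ 0.008
#' @export
compare_groups <- function(x, y, alpha_level = 0.05) {
  assert_number(x, "x"); assert_number(y, "y")
  if (length(x) < 2 || length(y) < 2) {
    stop_config("each group needs at least 2 replicate values")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop_config("zero variance in both groups; nothing to compare")
  }
  labels <- c(deparse(substitute(x)), deparse(substitute(y)))
  # two-sided variance-ratio test, larger variance in the numerator
  if (vx >= vy) {
    f <- vx / vy; df1 <- length(x) - 1; df2 <- length(y) - 1
  } else {
    f <- vy / vx; df1 <- length(y) - 1; df2 <- length(x) - 1
  }
  p_f <- min(2 * stats::pf(f, df1, df2, lower.tail = FALSE), 1)
  equal_var <- p_f >= alpha_level
  tt <- stats::t.test(x, y, var.equal = equal_var)
  structure(
    list(f_statistic = unname(f), p_f = p_f,
         equal_variance_assumed = equal_var,
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_t = tt$p.value, significant = tt$p.value < alpha_level,
         mean_x = mean(x), mean_y = mean(y),
         n_x = length(x), n_y = length(y), labels = labels),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  branch <- if (x$equal_variance_assumed) "pooled" else "Welch"
  cat(sprintf("F = %.3f (p = %.4g) -> %s t-test: t = %.3f, df = %.2f, p = %.4g%s\n",
              x$f_statistic, x$p_f, branch, x$t_statistic, x$df, x$p_t,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' Compare many endpoint conditions at once
#'
#' Runs [compare_groups()] for each pair of matching conditions that
#' differ only in one factor (by default the delivery mode), e.g. PBS vs
#' DS at the same position, dose and time point. Optionally applies a
#' Holm adjustment across the comparisons (off by default, matching the
#' per-comparison 0.05 convention).
#'
#' @param measurements Endpoint data frame as produced by
#'   [generate_endpoint_data()].
#' @param compare Factor whose two levels are contrasted (default
#'   `"mode"`).
#' @param alpha_level Per-comparison significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data frame with one row per comparison: the grouping keys,
#'   `f`, `p_f`, `branch`, `t`, `df`, `p_t`, `significant`.
#' @export
compare_endpoint_conditions <- function(measurements, compare = "mode",
                                        alpha_level = 0.05,
                                        adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  keys <- setdiff(c("endpoint", "mode", "position", "dose", "time_h"),
                  compare)
  levels2 <- unique(measurements[[compare]])
  if (length(levels2) != 2) {
    stop_config("'", compare, "' must have exactly two levels, found ",
                length(levels2))
  }
  groups <- split(measurements,
                  measurements[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    x <- g$value[g[[compare]] == levels2[1]]
    y <- g$value[g[[compare]] == levels2[2]]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    if (stats::var(x) == 0 && stats::var(y) == 0) return(NULL)
    cr <- compare_groups(x, y, alpha_level)
    cbind(g[1, keys, drop = FALSE],
          data.frame(group1 = levels2[1], group2 = levels2[2],
                     f = cr$f_statistic, p_f = cr$p_f,
                     branch = if (cr$equal_variance_assumed) "pooled" else "welch",
                     t = cr$t_statistic, df = cr$df, p_t = cr$p_t,
                     significant = cr$significant))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  if (adjust == "holm") {
    out$p_t <- stats::p.adjust(out$p_t, "holm")
    out$significant <- out$p_t < alpha_level
  }
  out
}

#' Micronucleus scoring summary
#'
#' Summarises per-cell micronucleus counts from the cytokinesis-block
#' assay: the total number of micronuclei (MN), the number of
#' binucleated cells (BNC) carrying at least one MN, the percentage of
#' such cells, and the MN frequency (total MN per BNC). Since every
#' MN-bearing cell carries at least one MN, the frequency is always at
#' least `pct_bnc_with_mn / 100`.
#'
#' @param mn_counts_per_bnc Non-negative integer vector: MN count per
#'   scored binucleated cell.
#' @return An `mn_summary`: list with `total_mn`, `total_bnc`,
#'   `bnc_with_mn`, `pct_bnc_with_mn`, `mn_frequency`.
#' @examples
#' mn_summary(c(rep(0, 380), rep(1, 16), rep(2, 4)))
#' @export
mn_summary <- function(mn_counts_per_bnc) {
  if (!length(mn_counts_per_bnc)) stop_config("no scored cells")
  assert_number(mn_counts_per_bnc, "mn_counts_per_bnc", lower = 0)
  n <- length(mn_counts_per_bnc)
  with_mn <- sum(mn_counts_per_bnc > 0)
  structure(
    list(total_mn = sum(mn_counts_per_bnc), total_bnc = n,
         bnc_with_mn = with_mn,
         pct_bnc_with_mn = 100 * with_mn / n,
         mn_frequency = sum(mn_counts_per_bnc) / n),
    class = "mn_summary"
  )
}

#' @export
print.mn_summary <- function(x, ...) {
  cat(sprintf("MN summary: %d MN over %d BNC; %.2f%% BNC with MN; frequency %.4f MN/BNC\n",
              x$total_mn, x$total_bnc, x$pct_bnc_with_mn, x$mn_frequency))
  invisible(x)
}

#' Control-subtracted endpoint percentages
#'
#' Subtracts control (0 Gy) percentages from treated percentages,
#' element-wise. Negative excesses — possible when the control happens
#' to exceed a treated sample — are retained (keeping the mean
#' unbiased) and flagged via the `flagged_negative` attribute.
#'
#' @param values Treated percentages in [0, 100].
#' @param control Control percentages in [0, 100]; length 1 or matching
#'   `values`.
#' @return Excess percentages with attribute `flagged_negative`.
#' @examples
#' control_subtracted(c(15, 4), 5)   # 10 and -1 (flagged)
#' @export
control_subtracted <- function(values, control) {
  assert_number(values, "values", lower = 0, upper = 100)
  assert_number(control, "control", lower = 0, upper = 100)
  if (length(control) != 1 && length(control) != length(values)) {
    stop_config("'control' must have length 1 or length(values); ",
                "condition labels do not match")
  }
  out <- values - control
  structure(out, flagged_negative = which(out < 0))
}

#' Per-condition endpoint means and standard deviations
#'
#' Groups endpoint measurements by (endpoint, mode, position, dose, time
#' point) and reports the mean and sample (n-1) standard deviation of
#' the replicate values in each group, with the replicate count. Groups
#' with a single value get an `NA` standard deviation.
#'
#' @param measurements Endpoint data frame (columns `endpoint`, `mode`,
#'   `position`, `dose`, `time_h`, `value`).
#' @param by Grouping columns.
#' @return Data frame with the grouping keys plus `mean`, `sd`, `n`.
#' @export
summarize_endpoint <- function(measurements,
                               by = c("endpoint", "mode", "position",
                                      "dose", "time_h")) {
  by <- intersect(by, names(measurements))
  if (!nrow(measurements)) {
    warning("no measurements; empty summary")
    return(data.frame())
  }
  groups <- split(measurements, measurements[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(mean = mean(g$value),
                     sd = if (nrow(g) > 1) stats::sd(g$value) else NA_real_,
                     n = nrow(g)))
  }))
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
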