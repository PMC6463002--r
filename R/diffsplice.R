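#' Rank test for one splicing event
#'
#' Two-sided Wilcoxon test of tumor versus normal PSI values. In
#' `rank_sum` mode (Mann-Whitney, the default for unpaired cohorts) the
#' exact null distribution is used when the combined sample size is at
#' most 25 and no ties are present; otherwise the normal approximation
#' with tie-corrected variance is used (no continuity correction).
#' `signed_rank_paired` applies the one-sample signed-rank test to
#' paired differences.
#'
#' @param tumor_values,normal_values Numeric vectors (equal length for
#'   the paired mode).
#' @param mode `"rank_sum"` or `"signed_rank_paired"`.
#' @return A list with `statistic`, `p`, and `degenerate` (TRUE when
#'   the data carry no rank information and P is reported as 1).
#' @export
wilcoxon_event_test <- function(tumor_values, normal_values,
                                mode = c("rank_sum", "signed_rank_paired")) {
  mode <- match.arg(mode)
  nx <- length(tumor_values)
  ny <- length(normal_values)
  if (nx < 3 || ny < 3) abort("each group needs at least 3 values")
  if (mode == "signed_rank_paired") {
    if (nx != ny) abort("paired mode needs equal-length vectors")
    d <- tumor_values - normal_values
    if (all(d == 0)) {
      return(list(statistic = nx * (nx + 1) / 4, p = 1, degenerate = TRUE))
    }
    exact <- (nx <= 25) && !any(d == 0) && !anyDuplicated(abs(d))
    res <- suppressWarnings(
      stats::wilcox.test(tumor_values, normal_values, paired = TRUE,
                         exact = exact, correct = FALSE)
    )
    return(list(statistic = unname(res$statistic), p = min(1, res$p.value),
                degenerate = FALSE))
  }
  pooled <- c(tumor_values, normal_values)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = nx * ny / 2, p = 1, degenerate = TRUE))
  }
  exact <- (nx + ny <= 25) && !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(tumor_values, normal_values,
                       exact = exact, correct = FALSE)
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1  # zero-variance rank configuration
  list(statistic = unname(res$statistic), p = min(1, p), degenerate = FALSE)
}

#' Difference in mean PSI between tumor and normal groups
#'
#' @param tumor_values,normal_values Nonempty numeric vectors.
#' @param stat Summary used per group, `"mean"` (default) or `"median"`.
#' @return `stat(tumor) - stat(normal)`, in \[-1, 1\] for PSI input.
#' @export
delta_psi <- function(tumor_values, normal_values, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(tumor_values) == 0 || length(normal_values) == 0) {
    abort("delta_psi needs nonempty groups")
  }
  f <- if (stat == "mean") mean else median
  f(tumor_values) - f(normal_values)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p_values Numeric vector of raw P-values in \[0, 1\].
#' @return Vector of q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Identify differentially spliced events
#'
#' Tests every event of a filtered, imputed PSI matrix for a
#' tumor-versus-normal shift, adjusts P-values by Benjamini-Hochberg,
#' and flags events with `q < fdr_max` and `|delta PSI| > delta_min`
#' (both strict, matching FDR < 0.1 and |dPSI| > 0.1 defaults).
#'
#' @param m A complete `psi_matrix` with both groups present.
#' @param fdr_max FDR threshold (default 0.1, strict `<`).
#' @param delta_min Minimum absolute delta PSI (default 0.1, strict `>`).
#' @param mode Rank-test mode, see [wilcoxon_event_test()].
#' @param delta_stat Per-group summary for delta PSI, `"mean"` or
#'   `"median"`.
#' @return A tibble with one row per event: `event_id`, `gene_symbol`,
#'   `splice_class`, `statistic`, `p`, `q`, `delta_psi`,
#'   `is_differential`.
#' @export
select_differential <- function(m, fdr_max = 0.1, delta_min = 0.1,
                                mode = "rank_sum", delta_stat = "mean") {
  grp <- m$samples$group
  if (!any(grp == "tumor") || !any(grp == "normal")) {
    abort("both tumor and normal samples are required")
  }
  tum <- m$values[, grp == "tumor", drop = FALSE]
  nor <- m$values[, grp == "normal", drop = FALSE]
  tests <- lapply(seq_len(nrow(m$values)), function(i) {
    wilcoxon_event_test(tum[i, ], nor[i, ], mode = mode)
  })
  p <- vapply(tests, `[[`, numeric(1), "p")
  dpsi <- vapply(seq_len(nrow(tum)), function(i) {
    delta_psi(tum[i, ], nor[i, ], stat = delta_stat)
  }, numeric(1))
  q <- bh_fdr(p)
  out <- tibble(
    event_id = m$events$event_id,
    gene_symbol = m$events$gene_symbol,
    splice_class = m$events$splice_class,
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p = p, q = q, delta_psi = dpsi,
    is_differential = q < fdr_max & abs(dpsi) > delta_min
  )
  if (!any(out$is_differential)) {
    warn("no differential splicing events at the given thresholds")
  }
  out
}

#' Event ids flagged as differential
#' @param diff_table Output of [select_differential()].
#' @return Character vector of event ids.
#' @export
differential_events <- function(diff_table) {
  diff_table$event_id[diff_table$is_differential]
}
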