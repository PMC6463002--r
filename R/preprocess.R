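#' Filter splicing events by missingness
#'
#' Drops events that failed quantification in more than
#' `normal_missing_max` of normal samples or more than
#' `tumor_missing_max` of tumor samples. Thresholds are inclusive: an
#' event is retained when its missing fraction is less than or equal to
#' the maximum in both groups.
#'
#' @param m A `psi_matrix` with at least one normal and one tumor sample.
#' @param normal_missing_max Maximum tolerated missing fraction among
#'   normal samples (default 0.10).
#' @param tumor_missing_max Maximum tolerated missing fraction among
#'   tumor samples (default 0.01).
#' @return The `psi_matrix` restricted to retained events.
#' @export
filter_events <- function(m, normal_missing_max = 0.10,
                          tumor_missing_max = 0.01) {
  is_tumor <- m$samples$group == "tumor"
  if (!any(!is_tumor)) abort("filter_events needs at least one normal sample")
  if (!any(is_tumor)) abort("filter_events needs at least one tumor sample")
  miss <- is.na(m$values)
  frac_normal <- rowMeans(miss[, !is_tumor, drop = FALSE])
  frac_tumor <- rowMeans(miss[, is_tumor, drop = FALSE])
  keep <- frac_normal <= normal_missing_max & frac_tumor <= tumor_missing_max
  psi_subset(m, events = which(keep))
}

#' Filter tumor samples by missingness
#'
#' Removes tumor samples whose missing fraction exceeds
#' `sample_missing_max`. Normal samples are never removed by this rule.
#' Intended to run after [filter_events()], so the fraction is evaluated
#' on the event-filtered matrix.
#'
#' @param m A `psi_matrix`.
#' @param sample_missing_max Maximum tolerated missing fraction per
#'   tumor sample (default 0.001).
#' @return The `psi_matrix` restricted to retained samples.
#' @export
filter_samples <- function(m, sample_missing_max = 0.001) {
  frac <- colMeans(is.na(m$values))
  is_tumor <- m$samples$group == "tumor"
  keep <- !is_tumor | frac <= sample_missing_max
  if (!any(is_tumor & keep)) {
    abort("sample-missingness filter removed every tumor sample")
  }
  psi_subset(m, samples = which(keep))
}

#' k-nearest-neighbor imputation of missing PSI values
#'
#' For each missing cell, the k events nearest to the target event
#' (Euclidean distance over mutually observed samples) among events
#' observed at that sample are averaged. Observed values are never
#' changed; imputed values are clipped to \[0, 1\]. Distance ties are
#' broken by event order, so the result is deterministic.
#'
#' @param m A `psi_matrix`; every event must have at least one observed
#'   value.
#' @param k Number of neighbor events to average (default 10).
#' @param seed Unused (the procedure is deterministic); accepted so
#'   callers can treat imputation uniformly with stochastic stages.
#' @return A complete `psi_matrix`.
#' @export
impute_knn <- function(m, k = 10, seed = NULL) {
  v <- m$values
  miss <- is.na(v)
  if (!any(miss)) return(m)
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing)) {
    abort(paste0("event(s) with all values missing: ",
                 paste(m$events$event_id[which(all_missing)[1]], collapse = ", ")))
  }
  row_means <- rowMeans(v, na.rm = TRUE)
  target_rows <- which(rowSums(miss) > 0)
  for (i in target_rows) {
    # distances from event i to all others over mutually observed samples
    diffs <- sweep(v, 2, v[i, ], FUN = "-")
    sq <- diffs^2
    shared <- sweep(!miss, 2, !miss[i, ], FUN = "&")
    n_shared <- rowSums(shared)
    d2 <- rowSums(sq * shared, na.rm = TRUE) / pmax(n_shared, 1)
    d2[n_shared == 0] <- Inf
    d2[i] <- Inf
    for (j in which(miss[i, ])) {
      cand <- which(!miss[, j] & is.finite(d2))
      if (length(cand) == 0) {
        fill <- row_means[i]
      } else {
        ord <- cand[order(d2[cand], cand)]
        nb <- ord[seq_len(min(k, length(ord)))]
        fill <- mean(v[nb, j])
      }
      v[i, j] <- min(1, max(0, fill))
    }
  }
  m$values <- v
  validate_psi_matrix(m)
}
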