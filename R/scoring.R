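#' Normal-reference PSI profile
#'
#' Per-event summary of PSI over normal samples, used as the baseline
#' that tumor samples are compared against.
#'
#' @param m A `psi_matrix` with at least one normal sample.
#' @param events Event ids (default all).
#' @param stat `"mean"` or `"median"` over normal samples.
#' @return Named numeric vector, one reference value per event.
#' @export
reference_profile <- function(m, events = event_ids(m),
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  nor <- m$samples$group == "normal"
  if (!any(nor)) abort("reference_profile needs at least one normal sample")
  idx <- match(events, m$events$event_id)
  if (anyNA(idx)) abort("unknown event id in reference request")
  v <- m$values[idx, nor, drop = FALSE]
  f <- if (stat == "mean") rowMeans else function(x) apply(x, 1, median)
  setNames(f(v), events)
}

#' Per-sample module perturbation scores
#'
#' For each sample, signed deviations of the module's events from the
#' normal reference are aggregated (mean or median). A positive score
#' means the module's events are, on balance, spliced in more than in
#' normal tissue; the magnitude measures how strongly the module is
#' perturbed in that sample.
#'
#' @param m A complete `psi_matrix`.
#' @param module Event ids of one module (nonempty, all present in `m`).
#' @param reference Named per-event reference vector covering the
#'   module (see [reference_profile()]); built from `m`'s normals when
#'   omitted.
#' @param aggregate `"average"` or `"median"` over events.
#' @param samples `"tumor"` (default) or `"all"`.
#' @return Named numeric vector of scores in \[-1, 1\], one per sample.
#' @export
score_samples <- function(m, module, reference = NULL,
                          aggregate = c("average", "median"),
                          samples = c("tumor", "all")) {
  aggregate <- match.arg(aggregate)
  samples <- match.arg(samples)
  if (length(module) == 0) abort("empty module cannot be scored")
  idx <- match(module, m$events$event_id)
  if (anyNA(idx)) abort("module contains events absent from the matrix")
  if (is.null(reference)) {
    reference <- reference_profile(
      m, module, stat = if (aggregate == "average") "mean" else "median")
  }
  if (!all(module %in% names(reference))) {
    abort("reference must cover every module event")
  }
  keep <- if (samples == "tumor") m$samples$group == "tumor" else
    rep(TRUE, nrow(m$samples))
  dev <- m$values[idx, keep, drop = FALSE] - reference[module]
  f <- if (aggregate == "average") colMeans else function(x) apply(x, 2, median)
  setNames(f(dev), m$samples$sample_id[keep])
}

#' Score every module of a module set
#'
#' @param m A complete `psi_matrix`.
#' @param modules A `module_set` (see [cut_by_modularity()]).
#' @param aggregate `"average"` or `"median"`.
#' @param samples `"tumor"` or `"all"`.
#' @return A `module_scores` object: module-by-sample score matrix with
#'   the aggregation tag and reference profile attached.
#' @export
score_modules <- function(m, modules, aggregate = c("average", "median"),
                          samples = "tumor") {
  aggregate <- match.arg(aggregate)
  mods <- modules$census$module
  rows <- lapply(mods, function(mod) {
    score_samples(m, module_events(modules, mod), aggregate = aggregate,
                  samples = samples)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- mods
  ref_stat <- if (aggregate == "average") "mean" else "median"
  structure(
    list(scores = mat, aggregate = aggregate,
         reference = reference_profile(m, modules$membership$event_id,
                                       stat = ref_stat)),
    class = "module_scores"
  )
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("<module_scores> %d modules x %d samples (%s aggregation)\n",
              nrow(x$scores), ncol(x$scores), x$aggregate))
  invisible(x)
}

#' @export
as_tibble.module_scores <- function(x, ...) {
  tibble(
    module = rep(rownames(x$scores), times = ncol(x$scores)),
    sample_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}

#' Heatmap of module scores
#'
#' @param object A `module_scores`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_scores <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$module,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "sample", y = "module", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
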