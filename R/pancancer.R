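#' Apply a module from one cancer type to another cohort
#'
#' Scores a module's events in a foreign cohort over the intersection
#' of events quantified there, using that cohort's own normal samples
#' as the reference. Returns the per-sample scores and the number of
#' evaluable events; with no shared events the cell is not evaluable
#' and `NULL` scores are returned rather than an error.
#'
#' @param module Event ids of the module.
#' @param cohort A complete `psi_matrix` for the target cancer type.
#' @param aggregate `"average"` or `"median"`.
#' @return List with `scores` (named vector over tumor samples, or
#'   `NULL`), `n_events` (evaluable events), `evaluable` (logical).
#' @export
cross_score <- function(module, cohort, aggregate = "average") {
  shared <- intersect(module, event_ids(cohort))
  if (length(shared) == 0) {
    return(list(scores = NULL, n_events = 0L, evaluable = FALSE))
  }
  list(scores = score_samples(cohort, shared, aggregate = aggregate),
       n_events = length(shared), evaluable = TRUE)
}

#' Directional sign call for a score vector
#'
#' `"+"` when at least `threshold` of the samples score above 0 (module
#' higher than normal), `"-"` when at least that fraction score below
#' 0; otherwise `"0"`. Exact zeros count toward neither side.
#'
#' @param scores Nonempty numeric vector.
#' @param threshold Required fraction (default 0.80, inclusive).
#' @return One of `"+"`, `"-"`, `"0"`.
#' @export
sign_classify <- function(scores, threshold = 0.80) {
  if (length(scores) == 0) abort("sign_classify needs at least one score")
  f_pos <- mean(scores > 0)
  f_neg <- mean(scores < 0)
  if (f_pos >= threshold) "+" else if (f_neg >= threshold) "-" else "0"
}

#' Pan-cancer commonality of one module
#'
#' TRUE when one nonzero sign (`"+"` or `"-"`) occurs in at least
#' `common_min` of the evaluated cancer types.
#'
#' @param signs Character vector of `"+"`/`"-"`/`"0"` (NA = not
#'   evaluable) across cancer types.
#' @param common_min Required count; defaults to `ceiling(15/16 * T)`
#'   for `T` evaluated types, i.e. 15 when all 16 types are evaluable.
#' @return Logical.
#' @export
commonality <- function(signs, common_min = NULL) {
  signs <- signs[!is.na(signs)]
  if (length(signs) == 0) return(FALSE)
  if (is.null(common_min)) common_min <- ceiling(15 / 16 * length(signs))
  max(sum(signs == "+"), sum(signs == "-")) >= common_min
}

#' Pan-cancer summary of modules across cohorts
#'
#' Applies every module to every cohort ([cross_score()]), makes the
#' >=80 percent directional sign call per (module, type) cell, computes
#' mean scores, and flags modules whose sign is consistent in at least
#' 15/16 (scaled) of the evaluated types.
#'
#' @param module_sets Named list (by cancer type) of `module_set`
#'   objects; module names are prefixed `TYPE_M1`, ...
#' @param cohorts Named list (by cancer type) of complete `psi_matrix`
#'   cohorts.
#' @param sign_threshold Fraction for the sign call (default 0.80).
#' @param common_min Count for the commonality flag (default scaled
#'   15/16 rule).
#' @param aggregate Score aggregation.
#' @return A `pancancer_summary`: list with `signs` (module x type
#'   character matrix), `mean_scores`, `n_events` (evaluable events per
#'   cell), `common` (named logical per module).
#' @export
pancancer_summary <- function(module_sets, cohorts, sign_threshold = 0.80,
                              common_min = NULL, aggregate = "average") {
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)))
  mods <- purrr::imap(module_sets, function(ms, type) {
    setNames(ms$census$module, paste0(type, "_", ms$census$module))
  })
  mod_names <- unlist(lapply(mods, names), use.names = FALSE)
  types <- names(cohorts)
  signs <- matrix(NA_character_, length(mod_names), length(types),
                  dimnames = list(mod_names, types))
  means <- matrix(NA_real_, length(mod_names), length(types),
                  dimnames = list(mod_names, types))
  nev <- matrix(0L, length(mod_names), length(types),
                dimnames = list(mod_names, types))
  for (src in names(module_sets)) {
    for (local_name in module_sets[[src]]$census$module) {
      full <- paste0(src, "_", local_name)
      ev <- module_events(module_sets[[src]], local_name)
      for (ty in types) {
        cs <- cross_score(ev, cohorts[[ty]], aggregate = aggregate)
        nev[full, ty] <- cs$n_events
        if (!cs$evaluable) next
        signs[full, ty] <- sign_classify(cs$scores, sign_threshold)
        means[full, ty] <- mean(cs$scores)
      }
    }
  }
  common <- apply(signs, 1, commonality, common_min = common_min)
  structure(
    list(signs = signs, mean_scores = means, n_events = nev,
         common = common),
    class = "pancancer_summary"
  )
}

#' @export
print.pancancer_summary <- function(x, ...) {
  cat(sprintf("<pancancer_summary> %d modules x %d cancer types, %d common\n",
              nrow(x$signs), ncol(x$signs), sum(x$common)))
  invisible(x)
}

#' @export
tidy.pancancer_summary <- function(x, ...) {
  tibble(
    module = rep(rownames(x$signs), times = ncol(x$signs)),
    cancer_type = rep(colnames(x$signs), each = nrow(x$signs)),
    sign = as.vector(x$signs),
    mean_score = as.vector(x$mean_scores),
    n_events = as.vector(x$n_events),
    common = rep(unname(x$common), times = ncol(x$signs))
  )
}

#' Cluster cancer types by module-score profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of
#' cancer types over their per-module mean scores; cells that are not
#' evaluable are mean-imputed per module before clustering.
#'
#' @param mean_scores Module-by-type numeric matrix (e.g. from
#'   [pancancer_summary()]).
#' @return An `hclust` tree over cancer types (or a trivial one-leaf
#'   list for a single type).
#' @export
cluster_types <- function(mean_scores) {
  if (ncol(mean_scores) < 2) {
    return(structure(list(labels = colnames(mean_scores), trivial = TRUE),
                     class = "trivial_tree"))
  }
  x <- mean_scores
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (anyNA(row)) {
      fill <- mean(row, na.rm = TRUE)
      x[i, is.na(row)] <- if (is.nan(fill)) 0 else fill
    }
  }
  stats::hclust(stats::dist(t(x), method = "euclidean"), method = "average")
}

#' Heatmap of the pan-cancer sign matrix
#' @param object A `pancancer_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pancancer_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$cancer_type, .data$module,
                                   fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$sign), "",
                                                   .data$sign)), size = 2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "cancer type", y = "module", fill = "mean score") +
    ggplot2::theme_minimal()
}
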