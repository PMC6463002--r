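#' Construct a PSI matrix object
#'
#' The central container of the pipeline: an event-by-sample matrix of
#' percent-spliced-in (PSI) values in \[0, 1\] (missing values as `NA`),
#' together with per-event metadata (gene symbol, splice class, exon
#' descriptor) and per-sample tumor/normal labels.
#'
#' Splice classes follow the six standard categories: exon skipping (ES),
#' retained intron (RI), alternative donor (AD), alternative acceptor
#' (AA), mutually exclusive exons (ME) and alternative terminator (AT).
#'
#' @param values Numeric matrix, events in rows, samples in columns.
#'   Non-missing entries must lie in \[0, 1\].
#' @param events Data frame with one row per event and columns
#'   `event_id`, `gene_symbol`, `splice_class`, `exon_descriptor`.
#' @param samples Data frame with one row per sample and columns
#'   `sample_id` and `group` (`"tumor"` or `"normal"`).
#' @return An object of class `psi_matrix`.
#' @export
psi_matrix <- function(values, events, samples) {
  values <- as.matrix(values)
  events <- tibble::as_tibble(events)
  samples <- tibble::as_tibble(samples)
  if (!"exon_descriptor" %in% names(events)) events$exon_descriptor <- ""
  obj <- structure(
    list(values = values, events = events, samples = samples),
    class = "psi_matrix"
  )
  validate_psi_matrix(obj)
}

validate_psi_matrix <- function(m) {
  v <- m$values
  ev <- m$events
  sm <- m$samples
  required_ev <- c("event_id", "gene_symbol", "splice_class", "exon_descriptor")
  if (!all(required_ev %in% names(ev))) {
    abort(paste0("event metadata must have columns: ",
                 paste(required_ev, collapse = ", ")))
  }
  if (!all(c("sample_id", "group") %in% names(sm))) {
    abort("sample metadata must have columns sample_id, group")
  }
  if (nrow(ev) != nrow(v)) abort("event metadata rows must match value-matrix rows")
  if (nrow(sm) != ncol(v)) abort("sample metadata rows must match value-matrix columns")
  if (anyDuplicated(ev$event_id)) abort("event_ids must be unique")
  if (anyDuplicated(sm$sample_id)) abort("sample_ids must be unique")
  if (!all(sm$group %in% c("tumor", "normal"))) {
    abort("sample group labels must be 'tumor' or 'normal'")
  }
  bad_class <- setdiff(unique(ev$splice_class), SPLICE_CLASSES)
  if (length(bad_class) > 0) {
    abort(paste0("unknown splice class(es): ", paste(bad_class, collapse = ", ")))
  }
  obs <- v[!is.na(v)]
  if (length(obs) > 0 && (min(obs) < 0 || max(obs) > 1)) {
    abort("PSI values must lie in [0, 1]")
  }
  rownames(m$values) <- ev$event_id
  colnames(m$values) <- sm$sample_id
  m
}

#' @export
print.psi_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf(
    "<psi_matrix> %d events x %d samples (%d tumor, %d normal), %d missing (%.2f%%)\n",
    nrow(x$values), ncol(x$values),
    sum(x$samples$group == "tumor"), sum(x$samples$group == "normal"),
    n_missing, 100 * n_missing / length(x$values)
  ))
  cat("splice classes: ",
      paste(sprintf("%s=%d", names(table(x$events$splice_class)),
                    table(x$events$splice_class)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.psi_matrix <- function(x) dim(x$values)

#' Event and sample identifiers of a PSI matrix
#' @param m A `psi_matrix`.
#' @return Character vector.
#' @export
event_ids <- function(m) m$events$event_id

#' @rdname event_ids
#' @export
sample_ids <- function(m) m$samples$sample_id

#' Per-sample tumor/normal labels of a PSI matrix
#' @param m A `psi_matrix`.
#' @return Character vector aligned with the matrix columns.
#' @export
sample_groups <- function(m) m$samples$group

#' Subset a PSI matrix by events and/or samples
#'
#' @param m A `psi_matrix`.
#' @param events Event ids or row indices to keep (default all).
#' @param samples Sample ids or column indices to keep (default all).
#' @return A `psi_matrix` restricted to the selection.
#' @export
psi_subset <- function(m, events = NULL, samples = NULL) {
  ei <- if (is.null(events)) seq_len(nrow(m$values)) else {
    if (is.character(events)) match(events, m$events$event_id) else events
  }
  si <- if (is.null(samples)) seq_len(ncol(m$values)) else {
    if (is.character(samples)) match(samples, m$samples$sample_id) else samples
  }
  if (anyNA(ei)) abort("unknown event id in subset")
  if (anyNA(si)) abort("unknown sample id in subset")
  psi_matrix(m$values[ei, si, drop = FALSE],
             m$events[ei, , drop = FALSE],
             m$samples[si, , drop = FALSE])
}

#' Tidy long form of a PSI matrix
#'
#' @param x A `psi_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `event_id`, `gene_symbol`,
#'   `splice_class`, `sample_id`, `group`, `psi`.
#' @export
as_tibble.psi_matrix <- function(x, ...) {
  long <- tibble::tibble(
    event_id = rep(x$events$event_id, times = ncol(x$values)),
    gene_symbol = rep(x$events$gene_symbol, times = ncol(x$values)),
    splice_class = rep(x$events$splice_class, times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    group = rep(x$samples$group, each = nrow(x$values)),
    psi = as.vector(x$values)
  )
  long
}
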