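#' Pearson correlation matrix over splicing events
#'
#' Correlations between PSI profiles of the given events, by default
#' computed over tumor samples only (the network describes covariation
#' in the cancer state). Zero-variance events get correlation 0 with a
#' warning.
#'
#' @param m A complete `psi_matrix`.
#' @param events Event ids (default: all events of `m`).
#' @param use_samples `"tumor"` (default) or `"all"`.
#' @param method `"pearson"` or `"kendall"` (tau-b).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(m, events = event_ids(m), use_samples = c("tumor", "all"),
                           method = "pearson") {
  use_samples <- match.arg(use_samples)
  idx <- match(events, m$events$event_id)
  if (anyNA(idx)) abort("unknown event id in correlation request")
  keep <- if (use_samples == "tumor") m$samples$group == "tumor" else
    rep(TRUE, nrow(m$samples))
  x <- t(m$values[idx, keep, drop = FALSE])
  if (nrow(x) < 3) abort("need at least 3 samples for correlations")
  sds <- apply(x, 2, sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(paste0(sum(flat), " zero-variance event(s); their correlations set to 0"))
    x[, flat] <- x[, flat] + 0  # keep dims; handled below
  }
  r <- suppressWarnings(cor(x, method = method))
  r[is.na(r)] <- 0
  r[flat, ] <- 0
  r[, flat] <- 0
  diag(r) <- 1
  dimnames(r) <- list(events, events)
  r
}

#' @rdname pearson_matrix
#' @export
kendall_matrix <- function(m, events = event_ids(m), use_samples = "tumor") {
  pearson_matrix(m, events, use_samples, method = "kendall")
}

#' Build the correlation-weighted splicing graph
#'
#' Turns a correlation matrix into an undirected weighted graph over
#' events. Because the random-walk machinery needs nonnegative weights,
#' correlations are transformed: `abs` (default, preserves
#' anticorrelated co-membership) or `positive_only` (negative
#' correlations dropped). An edge is present when the transformed
#' weight exceeds `min_weight`.
#'
#' @param corr Square symmetric correlation matrix with event ids as
#'   dimnames.
#' @param weight_transform `"abs"` or `"positive_only"`.
#' @param min_weight Minimum transformed weight for an edge (default 0,
#'   i.e. only exact zeros are excluded).
#' @return A `splicing_graph`: list with `vertices` (event ids) and
#'   `weights` (symmetric matrix, zero diagonal).
#' @export
build_graph <- function(corr, weight_transform = c("abs", "positive_only"),
                        min_weight = 0) {
  weight_transform <- match.arg(weight_transform)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    abort("correlation matrix must be square and symmetric")
  }
  w <- switch(weight_transform, abs = abs(corr), positive_only = pmax(corr, 0))
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w <= min_weight] <- 0
  if (all(w == 0)) abort("graph has zero edges after weight transform")
  vertices <- rownames(corr) %||% as.character(seq_len(nrow(corr)))
  dimnames(w) <- list(vertices, vertices)
  structure(list(vertices = vertices, weights = w), class = "splicing_graph")
}

#' @export
print.splicing_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<splicing_graph> %d vertices, %d edges, total weight %.3f\n",
              length(x$vertices), ne, sum(x$weights) / 2))
  invisible(x)
}

#' Vertex strengths of a splicing graph
#' @param g A `splicing_graph`.
#' @return Named vector of weighted degrees d(i).
#' @export
vertex_strength <- function(g) rowSums(g$weights)

#' Edge list of a splicing graph
#' @param g A `splicing_graph`.
#' @return Tibble `event_a`, `event_b`, `weight` (each edge once).
#' @export
graph_edges <- function(g) {
  ut <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  tibble(
    event_a = g$vertices[ut[, 1]],
    event_b = g$vertices[ut[, 2]],
    weight = g$weights[ut]
  )
}

#' Connected components of a splicing graph
#' @param g A `splicing_graph`.
#' @return Integer vector of component labels per vertex.
#' @export
graph_components <- function(g) {
  n <- length(g$vertices)
  comp <- integer(n)
  cur <- 0L
  adj <- g$weights > 0
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Convert a splicing graph to an igraph object
#'
#' Convenience for interoperability (layout, export formats). Requires
#' the igraph package.
#'
#' @param g A `splicing_graph`.
#' @return An igraph weighted undirected graph.
#' @export
as_igraph <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("as_igraph requires the igraph package")
  }
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write the graph edge list as TSV
#' @param g A `splicing_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  write.table(as.data.frame(graph_edges(g)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
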