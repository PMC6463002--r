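# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use brute force / enumeration, never the
# package's own code paths.

toy_psi <- function(values, groups, classes = NULL, genes = NULL) {
  values <- as.matrix(values)
  ne <- nrow(values)
  ns <- ncol(values)
  psi_matrix(
    values,
    events = data.frame(
      event_id = sprintf("e%02d", seq_len(ne)),
      gene_symbol = genes %||% sprintf("G%02d", seq_len(ne)),
      splice_class = classes %||% rep("ES", ne),
      exon_descriptor = ""
    ),
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(ns)),
                         group = groups)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# graph from an edge matrix (rows: i, j, weight)
toy_graph <- function(edges, n = max(edges[, 1:2])) {
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    w[edges[r, 1], edges[r, 2]] <- edges[r, 3]
    w[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  diag(w) <- 1
  rownames(w) <- colnames(w) <- sprintf("v%02d", seq_len(n))
  build_graph(w)
}

two_triangles_bridge <- function() {
  toy_graph(cbind(rbind(c(1, 2), c(1, 3), c(2, 3),
                        c(4, 5), c(4, 6), c(5, 6), c(3, 4)), 1))
}

# step-up FDR by literal definition: q_i = min over p_(j) >= p_i of
# p_(j) * m / rank(j), capped at 1
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(ranked >= p[i] - 1e-15)
    q[i] <- min(1, min(ranked[js] * m / js))
  }
  q
}

# exact two-sided rank-sum P by enumeration of all group assignments
ranksum_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  min(1, 2 * min(mean(sums >= obs - 1e-12), mean(sums <= obs + 1e-12)))
}

# exact signed-rank P by enumeration of all sign patterns
signedrank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- signs %*% r
  min(1, 2 * min(mean(sums >= obs - 1e-12), mean(sums <= obs + 1e-12)))
}

# weighted modularity straight from the definition
modularity_brute <- function(w, partition) {
  diag(w) <- 0
  m <- sum(w) / 2
  d <- rowSums(w)
  q <- 0
  for (lab in unique(partition)) {
    sel <- partition == lab
    q <- q + sum(w[sel, sel]) / (2 * m) - (sum(d[sel]) / (2 * m))^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

random_weighted_graph <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
  }
  # keep connected enough: chain fallback
  for (i in seq_len(n - 1)) if (sum(w[i, ]) == 0) w[i, i + 1] <- w[i + 1, i] <- 0.5
  if (sum(w[n, ]) == 0) w[n, n - 1] <- w[n - 1, n] <- 0.5
  rownames(w) <- colnames(w) <- sprintf("v%02d", seq_len(n))
  diag(w) <- 1
  build_graph(w)
}
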