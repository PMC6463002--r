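#' Random-walk profiles of a weighted graph
#'
#' Computes the t-step transition probabilities of the natural random
#' walk on a weighted graph: `P[i, j] = w_ij / d(i)` raised to the t-th
#' power by repeated multiplication. Two vertices whose t-step
#' distributions are similar tend to belong to the same community.
#'
#' @param g A `splicing_graph` with no isolated vertex (process
#'   components separately; see [walktrap_dendrogram()]).
#' @param t Walk length in steps (default 4).
#' @return A `walk_state`: list with `P`, `Pt`, `t`, `strength`.
#' @export
walk_profiles <- function(g, t = 4) {
  if (t < 1) abort("walk length t must be >= 1")
  d <- vertex_strength(g)
  if (any(d == 0)) {
    abort("graph has isolated vertices; process components separately")
  }
  P <- g$weights / d
  Pt <- P
  if (t > 1) for (s in seq_len(t - 1)) Pt <- Pt %*% P
  structure(list(P = P, Pt = Pt, t = t, strength = d), class = "walk_state")
}

#' Random-walk distance between two vertices
#'
#' The strength-weighted Euclidean distance between t-step walk
#' profiles: `r_ij = sqrt(sum_k (Pt[i,k] - Pt[j,k])^2 / d(k))`.
#'
#' @param state A `walk_state` from [walk_profiles()].
#' @param i,j Vertex indices or names.
#' @return Nonnegative distance; 0 for `i == j`.
#' @export
vertex_distance <- function(state, i, j) {
  if (is.character(i)) i <- match(i, rownames(state$Pt))
  if (is.character(j)) j <- match(j, rownames(state$Pt))
  sqrt(sum((state$Pt[i, ] - state$Pt[j, ])^2 / state$strength))
}

# Agglomerate one connected component (vertex indices `idx` into g).
# Local community ids: singletons 1..k; the community merged at local
# step s gets id -s. The caller maps these to global ids. Tie-breaks
# compare global-order keys: singleton j -> idx[j], merged -s -> n+s.
agglomerate_component <- function(w, d, idx, t, n_total) {
  k <- length(idx)
  if (k == 1) return(list())
  P <- w / d
  Pt <- P
  if (t > 1) for (s in seq_len(t - 1)) Pt <- Pt %*% P
  # profiles scaled so squared Euclidean distance equals r^2
  A <- sweep(Pt, 2, sqrt(d), FUN = "/")
  sizes <- rep(1L, k)
  profiles <- A                       # one row per community slot
  adj <- w > 0
  members <- as.list(seq_len(k))      # local vertex indices per community
  active <- rep(TRUE, k)
  ids <- seq_len(k)
  id_key <- function(id) if (id > 0) idx[id] else n_total + (-id)
  merges <- vector("list", k - 1)
  for (step in seq_len(k - 1)) {
    act <- which(active)
    S <- profiles[act, , drop = FALSE]
    sq <- rowSums(S^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(S)
    d2[d2 < 0] <- 0
    s <- sizes[act]
    ds <- (d2 * outer(s, s) / outer(s, s, "+")) / n_total
    cand <- adj[act, act, drop = FALSE]
    diag(cand) <- FALSE
    ds[!cand] <- Inf
    best <- min(ds)
    hits <- which(ds <= best + 1e-15 & cand, arr.ind = TRUE)
    keys <- vapply(ids[act], id_key, numeric(1))
    pair_keys <- cbind(pmin(keys[hits[, 1]], keys[hits[, 2]]),
                       pmax(keys[hits[, 1]], keys[hits[, 2]]))
    h <- hits[order(pair_keys[, 1], pair_keys[, 2])[1], ]
    ia <- act[h[1]]; ib <- act[h[2]]
    if (id_key(ids[ia]) > id_key(ids[ib])) { tmp <- ia; ia <- ib; ib <- tmp }
    sa <- sizes[ia]; sb <- sizes[ib]
    merges[[step]] <- list(a = ids[ia], b = ids[ib],
                           delta_sigma = ds[h[1], h[2]],
                           members_a = members[[ia]],
                           members_b = members[[ib]])
    # slot ia now carries the merged community
    profiles[ia, ] <- (sa * profiles[ia, ] + sb * profiles[ib, ]) / (sa + sb)
    sizes[ia] <- sa + sb
    adj[ia, ] <- adj[ia, ] | adj[ib, ]
    adj[, ia] <- adj[, ia] | adj[, ib]
    adj[ia, ia] <- FALSE
    members[[ia]] <- c(members[[ia]], members[[ib]])
    active[ib] <- FALSE
    ids[ia] <- -step
  }
  merges
}

#' Walktrap merge dendrogram
#'
#' Pons-Latapy agglomeration: starting from singleton communities,
#' repeatedly merge the adjacent pair with the smallest increase in the
#' mean squared walk distance, `delta_sigma = (1/n) * |C1||C2|/(|C1|+|C2|)
#' * r^2(C1, C2)`, where community profiles are means of member t-step
#' walk rows. Ties are broken toward the lexicographically smallest
#' community-id pair, so the tree is deterministic. Disconnected
#' components are agglomerated independently and their merges
#' concatenated; modularity is tracked on the global partition after
#' each merge.
#'
#' @param g A `splicing_graph`.
#' @param t Walk length (default 4; 3-5 are sensible).
#' @return A `merge_tree`: list with `merges` (tibble: `step`, `a`, `b`,
#'   `delta_sigma`, `new_id`, `modularity`), `n_vertices`, `vertices`,
#'   and `t`. Singleton community ids are 1..n (vertex order); merged
#'   communities get ids n+step.
#' @export
walktrap_dendrogram <- function(g, t = 4) {
  if (t < 1) abort("walk length t must be >= 1")
  build_merge_tree(g, t)
}

build_merge_tree <- function(g, t) {
  n <- length(g$vertices)
  comp <- graph_components(g)
  merges <- list()
  membership <- seq_len(n)
  step_global <- 0L
  for (ci in sort(unique(comp))) {
    idx <- which(comp == ci)
    if (length(idx) == 1) next
    w <- g$weights[idx, idx, drop = FALSE]
    d <- rowSums(w)
    local <- agglomerate_component(w, d, idx, t, n)
    # local ids: singletons 1..k map to global idx; merged -step maps to
    # the global id assigned when that local step was emitted
    merged_global <- integer(length(local))
    for (s in seq_along(local)) {
      lm <- local[[s]]
      to_global <- function(id) {
        if (id > 0) idx[id] else merged_global[-id]
      }
      step_global <- step_global + 1L
      new_id <- n + step_global
      merged_global[s] <- new_id
      members <- idx[c(lm$members_a, lm$members_b)]
      membership[members] <- new_id
      merges[[step_global]] <- tibble(
        step = step_global,
        a = to_global(lm$a), b = to_global(lm$b),
        delta_sigma = lm$delta_sigma, new_id = new_id,
        modularity = modularity_q(g, membership)
      )
    }
  }
  merges <- if (length(merges) > 0) dplyr::bind_rows(merges) else
    tibble(step = integer(), a = integer(), b = integer(),
           delta_sigma = numeric(), new_id = integer(), modularity = numeric())
  structure(
    list(merges = merges, n_vertices = n, vertices = g$vertices, t = t,
         q_singletons = modularity_q(g, seq_len(n))),
    class = "merge_tree"
  )
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %d vertices, %d merges, max modularity %.4f\n",
              x$n_vertices, nrow(x$merges),
              max(c(x$q_singletons, x$merges$modularity))))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `m` the total edge weight,
#' `e_c` the weight inside community c and `d_c` the total strength of
#' its vertices.
#'
#' @param g A `splicing_graph`.
#' @param partition Community label per vertex (any atomic labels).
#' @return Modularity in \[-1, 1\].
#' @export
modularity_q <- function(g, partition) {
  if (length(partition) != length(g$vertices)) {
    abort("partition must label every vertex exactly once")
  }
  if (anyNA(partition)) abort("partition labels must not be missing")
  m_w <- sum(g$weights) / 2
  d <- vertex_strength(g)
  q <- 0
  for (lab in unique(partition)) {
    sel <- partition == lab
    e_c <- sum(g$weights[sel, sel]) / 2
    d_c <- sum(d[sel])
    q <- q + e_c / m_w - (d_c / (2 * m_w))^2
  }
  q
}

# Membership vector (community ids) after the first `level` merges.
membership_at_level <- function(tree, level) {
  membership <- seq_len(tree$n_vertices)
  if (level == 0) return(membership)
  id_members <- as.list(seq_len(tree$n_vertices))
  for (s in seq_len(level)) {
    row <- tree$merges[s, ]
    members <- c(id_members[[row$a]], id_members[[row$b]])
    id_members[[row$new_id]] <- members
    membership[members] <- row$new_id
  }
  membership
}

#' Cut the walktrap dendrogram at maximal modularity
#'
#' Scans every merge level (including the all-singletons level),
#' evaluates weighted modularity of the global partition, and returns
#' the level with the largest Q; ties are resolved toward fewer
#' communities. Modules are then named M1, M2, ... by decreasing event
#' count (ties by decreasing gene count, then smallest member event
#' id), and a per-module splice-class census is tabulated when event
#' metadata are supplied.
#'
#' @param tree A `merge_tree`.
#' @param g The `splicing_graph` the tree was built from.
#' @param events Optional event metadata (columns `event_id`,
#'   `gene_symbol`, `splice_class`) for gene counts and the census.
#' @param min_module_size Drop modules with fewer events (default 1,
#'   i.e. keep all).
#' @return A `module_set`: list with `membership` (tibble `event_id`,
#'   `module`), `census` (tibble `module`, `genes`, `events`, `AA`,
#'   `AD`, `AT`, `ES`, `ME`, `RI`), `modularity`, `level`.
#' @export
cut_by_modularity <- function(tree, g, events = NULL, min_module_size = 1) {
  q_by_level <- c(tree$q_singletons, tree$merges$modularity)
  best_level <- max(which(q_by_level == max(q_by_level))) - 1L
  membership <- membership_at_level(tree, best_level)
  module_set(membership, tree$vertices, events = events,
             min_module_size = min_module_size,
             modularity = q_by_level[best_level + 1L], level = best_level)
}

#' Assemble a named module set from a membership vector
#'
#' @param membership Community label per vertex.
#' @param vertex_ids Event ids aligned with `membership`.
#' @param events Optional event metadata for gene counts and census.
#' @param min_module_size Drop modules smaller than this.
#' @param modularity,level Optional provenance recorded on the object.
#' @return A `module_set`.
#' @export
module_set <- function(membership, vertex_ids, events = NULL,
                       min_module_size = 1, modularity = NA_real_,
                       level = NA_integer_) {
  groups <- split(vertex_ids, membership)
  sizes <- lengths(groups)
  if (!is.null(events)) {
    meta <- events[match(vertex_ids, events$event_id), ]
    genes_per <- vapply(groups, function(ids) {
      length(unique(meta$gene_symbol[match(ids, vertex_ids)]))
    }, integer(1))
  } else {
    genes_per <- sizes
  }
  first_event <- vapply(groups, function(ids) sort(ids)[1], character(1))
  ord <- order(-sizes, -genes_per, first_event)
  groups <- groups[ord]
  sizes <- sizes[ord]
  genes_per <- genes_per[ord]
  keep <- sizes >= min_module_size
  groups <- groups[keep]
  sizes <- sizes[keep]
  genes_per <- genes_per[keep]
  mod_names <- paste0("M", seq_along(groups))
  membership_tbl <- tibble(
    event_id = unlist(groups, use.names = FALSE),
    module = rep(mod_names, times = sizes)
  )
  census <- tibble(module = mod_names, genes = unname(genes_per),
                   events = unname(sizes))
  for (cl in SPLICE_CLASSES) census[[cl]] <- 0L
  if (!is.null(events)) {
    meta <- events[match(membership_tbl$event_id, events$event_id), ]
    tab <- table(membership_tbl$module, meta$splice_class)
    for (cl in intersect(colnames(tab), SPLICE_CLASSES)) {
      census[[cl]] <- as.integer(tab[match(census$module, rownames(tab)), cl])
    }
  }
  structure(
    list(membership = membership_tbl, census = census,
         modularity = modularity, level = level),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules over %d events (Q = %.4f)\n",
              nrow(x$census), nrow(x$membership), x$modularity))
  print(x$census, n = 10)
  invisible(x)
}

#' Events of one module
#' @param ms A `module_set`.
#' @param module Module name, e.g. `"M1"`.
#' @return Character vector of event ids.
#' @export
module_events <- function(ms, module) {
  ids <- ms$membership$event_id[ms$membership$module == module]
  if (length(ids) == 0) abort(paste0("unknown or empty module: ", module))
  ids
}

#' @export
tidy.module_set <- function(x, ...) x$membership

#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = nrow(x$census), n_events = nrow(x$membership),
         modularity = x$modularity, level = x$level)
}

#' Newick export of a walktrap merge tree
#'
#' Writes the dendrogram with `delta_sigma` of each merge as the branch
#' length from the merged node to its children; multiple components
#' hang from a zero-length artificial root.
#'
#' @param tree A `merge_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  n <- tree$n_vertices
  label <- function(id) {
    if (id <= n) return(gsub("[,;:() ]", "_", tree$vertices[id]))
    row <- tree$merges[tree$merges$new_id == id, ]
    sprintf("(%s:%.8g,%s:%.8g)", label(row$a), row$delta_sigma,
            label(row$b), row$delta_sigma)
  }
  merged_ids <- tree$merges$new_id
  absorbed <- c(tree$merges$a, tree$merges$b)
  roots <- c(setdiff(merged_ids, absorbed), setdiff(seq_len(n), absorbed))
  nw <- if (length(roots) == 1) paste0(label(roots), ";") else
    paste0("(", paste0(vapply(roots, label, character(1)), ":0",
                       collapse = ","), ");")
  writeLines(nw, path)
  invisible(path)
}
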