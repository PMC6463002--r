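test_that("walk profiles are row-stochastic transition powers", {
  # path graph 1-2-3 at t=2, computed by hand
  g <- toy_graph(cbind(rbind(c(1, 2), c(2, 3)), 1))
  st <- walk_profiles(g, t = 2)
  expect_equal(unname(st$Pt[1, ]), c(0.5, 0, 0.5))
  expect_equal(unname(st$Pt[2, ]), c(0, 1, 0))
  # t = 1 is the transition matrix itself
  st1 <- walk_profiles(g, t = 1)
  expect_identical(st1$Pt, st1$P)
  # single edge at t = 4: period-2 walk returns home
  ge <- toy_graph(cbind(1, 2, 1))
  expect_equal(unname(walk_profiles(ge, t = 4)$Pt), diag(2))
  # rows sum to 1 on random graphs
  set.seed(17)
  for (rep in 1:5) {
    gr <- random_weighted_graph(sample(10:60, 1), seed = rep)
    st <- walk_profiles(gr, t = 4)
    expect_lt(max(abs(rowSums(st$Pt) - 1)), 1e-9)
    expect_true(all(st$Pt >= -1e-12))
  }
})

test_that("vertex distances follow the strength-weighted profile formula", {
  g <- toy_graph(cbind(rbind(c(1, 2), c(2, 3)), 1))
  st <- walk_profiles(g, t = 2)
  expect_equal(vertex_distance(st, 1, 1), 0)
  expect_equal(vertex_distance(st, 1, 3), 0)  # automorphic endpoints
  ge <- toy_graph(cbind(1, 2, 1))
  expect_equal(vertex_distance(walk_profiles(ge, 1), 1, 2), sqrt(2))
  # symmetry
  expect_equal(vertex_distance(st, 1, 2), vertex_distance(st, 2, 1))
})

test_that("agglomeration merges the two triangles across the bridge last", {
  g <- two_triangles_bridge()
  tree <- walktrap_dendrogram(g, t = 4)
  expect_identical(nrow(tree$merges), 5L)
  expect_true(all(tree$merges$delta_sigma >= 0))
  # the final merge joins the two 3-vertex communities
  last <- tree$merges[5, ]
  ms <- cut_by_modularity(tree, g)
  expect_identical(sort(ms$census$events), c(3L, 3L))
  groups <- split(ms$membership$event_id, ms$membership$module)
  expect_setequal(vapply(groups, function(x) paste(sort(x), collapse = ","),
                         character(1)),
                  c("v01,v02,v03", "v04,v05,v06"))
  expect_equal(ms$modularity, 5 / 14)
})

test_that("complete-graph ties break deterministically by lowest pair", {
  g <- toy_graph(cbind(rbind(c(1, 2), c(1, 3), c(2, 3)), 1))
  tree <- walktrap_dendrogram(g)
  expect_identical(tree$merges$a[1], 1L)
  expect_identical(tree$merges$b[1], 2L)
  tree2 <- walktrap_dendrogram(g)
  expect_identical(tree$merges, tree2$merges)
})

test_that("disconnected components are agglomerated independently", {
  g <- toy_graph(cbind(rbind(c(1, 2), c(3, 4)), 1), n = 4)
  tree <- walktrap_dendrogram(g)
  expect_identical(nrow(tree$merges), 2L)  # |V| - components
  expect_setequal(paste(tree$merges$a, tree$merges$b),
                  c("1 2", "3 4"))
  ms <- cut_by_modularity(tree, g)
  expect_identical(nrow(ms$census), 2L)
})

test_that("modularity matches brute force and igraph on random partitions", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (rep in 1:20) {
    g <- random_weighted_graph(sample(6:25, 1), seed = 100 + rep)
    n <- length(g$vertices)
    for (trial in 1:5) {
      part <- sample(1:3, n, replace = TRUE)
      q <- modularity_q(g, part)
      expect_equal(q, modularity_brute(g$weights, part), tolerance = 1e-12)
      ig <- as_igraph(g)
      expect_equal(q, igraph::modularity(ig, part,
                                         weights = igraph::E(ig)$weight),
                   tolerance = 1e-10)
    }
  }
  # degenerate and reference values
  g2 <- two_triangles_bridge()
  expect_equal(modularity_q(g2, rep(1, 6)), 0)
  expect_equal(modularity_q(g2, c(1, 1, 1, 2, 2, 2)), 5 / 14)
  expect_error(modularity_q(g2, c(1, 1, 1)), "every vertex")
})

test_that("the modularity cut is optimal among all partitions of the toy graph", {
  g <- two_triangles_bridge()
  parts <- all_partitions(6)
  qs <- vapply(parts, function(p) modularity_q(g, p), numeric(1))
  expect_equal(max(qs), 5 / 14, tolerance = 1e-12)
  best <- parts[[which.max(qs)]]
  expect_identical(best[1:3], rep(best[1], 3))
  expect_identical(best[4:6], rep(best[4], 3))
})

test_that("planted two-block graphs are recovered exactly across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    n_blk <- 20
    n <- 2 * n_blk
    w <- matrix(0, n, n)
    w[1:n_blk, 1:n_blk] <- 0.8
    w[(n_blk + 1):n, (n_blk + 1):n] <- 0.8
    w[1:n_blk, (n_blk + 1):n] <- 0.05
    w[(n_blk + 1):n, 1:n_blk] <- 0.05
    jitter <- matrix(runif(n * n, 0, 0.01), n)
    w <- w + (jitter + t(jitter)) / 2
    diag(w) <- 1
    rownames(w) <- colnames(w) <- sprintf("v%02d", 1:n)
    g <- build_graph(w)
    ms <- cut_by_modularity(walktrap_dendrogram(g), g)
    truth <- rep(1:2, each = n_blk)
    det <- ms$membership$module[match(g$vertices, ms$membership$event_id)]
    expect_equal(adjusted_rand_index(truth, det), 1)
  }
})

test_that("walktrap partition matches igraph's reference implementation", {
  skip_if_not_installed("igraph")
  # strong planted structure: both implementations must find the blocks
  set.seed(404)
  n <- 30
  w <- matrix(0.05, n, n)
  w[1:10, 1:10] <- 0.9; w[11:20, 11:20] <- 0.9; w[21:30, 21:30] <- 0.9
  diag(w) <- 1
  rownames(w) <- colnames(w) <- sprintf("v%02d", 1:n)
  g <- build_graph(w)
  ours <- cut_by_modularity(walktrap_dendrogram(g, t = 4), g)
  det <- ours$membership$module[match(g$vertices, ours$membership$event_id)]
  ig <- as_igraph(g)
  ref <- igraph::cluster_walktrap(ig, steps = 4)
  expect_equal(adjusted_rand_index(det, igraph::membership(ref)), 1)
})

test_that("modules are named by size with census accounting", {
  membership <- c(rep(1, 5), rep(2, 9), rep(3, 7))
  ids <- sprintf("e%02d", 1:21)
  events <- data.frame(
    event_id = ids,
    gene_symbol = c(rep("GA", 5), sprintf("GB%d", 1:9), rep("GC", 7)),
    splice_class = c(rep("ES", 5), rep(c("ES", "RI", "AT"), 3), rep("AA", 7)),
    exon_descriptor = ""
  )
  ms <- module_set(membership, ids, events = events)
  expect_identical(ms$census$module, c("M1", "M2", "M3"))
  expect_identical(ms$census$events, c(9L, 7L, 5L))
  # census sums to module size
  class_cols <- c("AA", "AD", "AT", "ES", "ME", "RI")
  expect_identical(unname(rowSums(ms$census[class_cols])),
                   as.double(ms$census$events))
  expect_identical(ms$census$genes, c(9L, 1L, 1L))
  # M2 census: classes of the 7 'GC'/AA events
  expect_identical(ms$census$AA[2], 7L)
  # min_module_size drops small modules
  ms2 <- module_set(membership, ids, events = events, min_module_size = 6)
  expect_identical(ms2$census$module, c("M1", "M2"))
})

test_that("tidy and glance summarize a module set", {
  g <- two_triangles_bridge()
  ms <- cut_by_modularity(walktrap_dendrogram(g), g)
  td <- tidy(ms)
  expect_named(td, c("event_id", "module"))
  expect_identical(nrow(td), 6L)
  gl <- glance(ms)
  expect_identical(gl$n_modules, 2L)
  expect_equal(gl$modularity, 5 / 14)
})

test_that("newick export writes a readable tree with branch lengths", {
  skip_if_not_installed("ape")
  g <- two_triangles_bridge()
  tree <- walktrap_dendrogram(g)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, sprintf("v%02d", 1:6))
})
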