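test_that("sign calls follow the 80 percent rule with inclusive boundary", {
  expect_identical(sign_classify(c(rep(1, 9), -1)), "+")
  expect_identical(sign_classify(c(rep(1, 8), -1, -1)), "+")
  expect_identical(sign_classify(c(rep(1, 7), rep(-1, 3))), "0")
  expect_identical(sign_classify(c(rep(-1, 8), 1, 1)), "-")
  expect_identical(sign_classify(rep(0, 5)), "0")
  # zeros count toward neither side
  expect_identical(sign_classify(c(rep(1, 8), 0, 0), threshold = 0.8), "+")
  # equivariance under negation
  set.seed(71)
  for (rep in 1:20) {
    sc <- rnorm(25)
    s <- sign_classify(sc)
    flipped <- sign_classify(-sc)
    expect_identical(flipped, switch(s, "+" = "-", "-" = "+", "0" = "0"))
  }
})

test_that("sign calls match a direct-count oracle on random score vectors", {
  set.seed(72)
  for (rep in 1:50) {
    sc <- rnorm(sample(5:40, 1), mean = runif(1, -0.3, 0.3), sd = 0.2)
    expected <- if (sum(sc > 0) / length(sc) >= 0.8) "+" else
      if (sum(sc < 0) / length(sc) >= 0.8) "-" else "0"
    expect_identical(sign_classify(sc), expected)
  }
})

test_that("commonality requires one dominant sign in 15 of 16 types", {
  expect_true(commonality(c(rep("+", 15), "0")))
  expect_false(commonality(c(rep("+", 8), rep("-", 8))))
  expect_false(commonality(c(rep("+", 14), rep("-", 2))))
  expect_true(commonality(rep("-", 16)))
  # invariant to ordering
  signs <- c(rep("+", 15), "0")
  expect_identical(commonality(signs), commonality(rev(signs)))
  # scaled threshold: ceil(15/16 * 8) = 8
  expect_true(commonality(rep("+", 8)))
  expect_false(commonality(c(rep("+", 7), "0")))
  expect_false(commonality(rep(NA_character_, 4)))
})

test_that("cross scoring restricts to shared events and self-reproduces", {
  sim <- generate_cohort(synthetic_config(seed = 81, missing_rate = 0))
  events <- names(sim$truth$module_assignment)[sim$truth$module_assignment == 1]
  own <- cross_score(events, sim$psi)
  expect_true(own$evaluable)
  expect_identical(own$n_events, length(events))
  expect_equal(own$scores, score_samples(sim$psi, events))
  # restricted module: 7 of 10 events present
  sub <- psi_subset(sim$psi, events = setdiff(event_ids(sim$psi), events[1:3]))
  part <- cross_score(events[1:10], sub)
  expect_identical(part$n_events, 7L)
  # empty intersection is a sentinel, not an error
  none <- cross_score(c("nope1", "nope2"), sim$psi)
  expect_false(none$evaluable)
  expect_null(none$scores)
})

test_that("type clustering groups identical profiles first", {
  m <- cbind(A = c(1, 0, 0.5), B = c(1, 0, 0.5), C = c(-1, 2, 0))
  hc <- cluster_types(m)
  merged_first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(merged_first, c("A", "B"))
  expect_equal(hc$height[1], 0)
  # single type: trivial tree
  tr <- cluster_types(m[, 1, drop = FALSE])
  expect_true(tr$trivial)
  # missing cells are mean-imputed per module before clustering
  m2 <- m; m2[2, 3] <- NA
  expect_s3_class(cluster_types(m2), "hclust")
})

test_that("two planted tissue archetypes are recovered by the 2-cluster cut", {
  set.seed(91)
  arch1 <- rnorm(10); arch2 <- rnorm(10, 2)
  profiles <- sapply(1:6, function(i) {
    base <- if (i <= 3) arch1 else arch2
    base + rnorm(10, 0, 0.1)
  })
  colnames(profiles) <- paste0("T", 1:6)
  hc <- cluster_types(profiles)
  cut2 <- stats::cutree(hc, k = 2)
  expect_equal(adjusted_rand_index(cut2, rep(1:2, each = 3)), 1)
})

test_that("a module shared across types is the only one flagged common", {
  base <- lapply(1:4, function(i) {
    synthetic_config(seed = 100 + i, n_events = 400, module_sizes = 40,
                     n_tumor = 25, n_normal = 10, missing_rate = 0)
  })
  names(base) <- paste0("TY", 1:4)
  sims <- generate_multitype(
    base, shared_modules = list(list(size = 40, delta = 2, beta = 0,
                                     types = "all")))
  # module sets from planted truth per type
  module_sets <- lapply(sims, function(sim) {
    truth <- sim$truth$module_assignment
    module_set(truth[truth > 0], names(truth)[truth > 0])
  })
  cohorts <- lapply(sims, function(sim) sim$psi)
  pc <- pancancer_summary(module_sets, cohorts)
  flagged <- names(pc$common)[pc$common]
  # the shared module is planted in all 4 types, so each type carries an
  # identical copy; exactly those copies are flagged, no private module is
  shared_events <- sims[[1]]$truth$shared_event_ids[[1]]
  is_copy <- vapply(rownames(pc$signs), function(full) {
    ty <- sub("_M\\d+$", "", full)
    loc <- sub("^.*_(M\\d+)$", "\\1", full)
    setequal(module_events(module_sets[[ty]], loc), shared_events)
  }, logical(1))
  expect_setequal(flagged, rownames(pc$signs)[is_copy])
  expect_identical(length(flagged), 4L)
  expect_true(all(pc$signs[flagged, ] == "+"))
  # shared module occupies the same events in every type
  ev <- lapply(sims, function(s) s$truth$shared_event_ids[[1]])
  expect_identical(length(unique(ev)), 1L)
})

test_that("multitype generation validates shared-module specs", {
  cfgs <- list(A = synthetic_config(seed = 1), B = synthetic_config(seed = 2))
  expect_error(generate_multitype(cfgs[1]), ">= 2")
  expect_error(generate_multitype(cfgs, shared_modules = list(list(size = 10))),
               "types")
})
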