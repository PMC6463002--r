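test_that("rank-sum test matches exact enumeration on small groups", {
  x <- c(0.9, 0.8, 0.7)
  y <- c(0.1, 0.2, 0.3)
  res <- wilcoxon_event_test(x, y)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, ranksum_exact_p(x, y))

  # a non-extreme configuration agrees with enumeration too
  x2 <- c(0.62, 0.41, 0.77, 0.5)
  y2 <- c(0.3, 0.55, 0.45)
  expect_equal(wilcoxon_event_test(x2, y2)$p, ranksum_exact_p(x2, y2))

  # identical multisets carry no signal
  same <- wilcoxon_event_test(c(0.1, 0.2, 0.3), c(0.3, 0.1, 0.2))
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 4.5)
})

test_that("paired signed-rank test matches sign-pattern enumeration", {
  d <- c(0.2, 0.3, 0.1, 0.25)
  base <- c(0.3, 0.3, 0.6, 0.5)
  res <- wilcoxon_event_test(base + d, base, mode = "signed_rank_paired")
  expect_equal(res$p, 1 / 8)
  expect_equal(res$p, signedrank_exact_p(d))
  expect_error(wilcoxon_event_test(1:4 / 10, 1:3 / 10,
                                   mode = "signed_rank_paired"),
               "equal-length")
})

test_that("degenerate all-identical input yields P = 1 with a flag", {
  res <- wilcoxon_event_test(rep(0.5, 5), rep(0.5, 6))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_equal(res$statistic, 15)  # null mean of U = n1*n2/2
})

test_that("delta PSI is the group summary difference with bounds attained", {
  expect_equal(delta_psi(c(0.7, 0.5), c(0.4, 0.5)), 0.15)
  expect_equal(delta_psi(c(0.3, 0.6), c(0.3, 0.6)), 0)
  expect_equal(delta_psi(rep(1, 3), rep(0, 3)), 1)
  expect_equal(delta_psi(c(0.1, 0.9, 0.9), c(0.4, 0.5, 0.6), stat = "median"),
               0.4)
  expect_error(delta_psi(numeric(0), 0.5), "nonempty")
})

test_that("BH adjustment agrees with the brute-force step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(123)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # BH monotonicity: q nondecreasing in sorted-p order
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("differential selection applies strict q and delta thresholds", {
  sim <- generate_cohort(synthetic_config(seed = 21, n_events = 400,
                                          missing_rate = 0))
  dt <- select_differential(sim$psi)
  expect_identical(dt$is_differential,
                   dt$q < 0.1 & abs(dt$delta_psi) > 0.1)
  # planted events dominate the flagged set
  truth <- sim$truth$module_assignment[dt$event_id]
  expect_gt(mean(truth[dt$is_differential] > 0), 0.9)
  # power: nearly all planted events found under the default conditions
  expect_gt(mean(dt$is_differential[truth > 0]), 0.85)
})

test_that("a null cohort yields uniform P-values and almost no discoveries", {
  null_cfg <- synthetic_config(seed = 77, n_events = 600, delta = 0,
                               loading_strength = 0, beta = 0,
                               missing_rate = 0)
  sim <- generate_cohort(null_cfg)
  dt <- suppressWarnings(select_differential(sim$psi))
  expect_lt(mean(dt$is_differential), 0.02)
  ks <- suppressWarnings(stats::ks.test(dt$p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("planted strong shifts are flagged with high power", {
  # direct construction: delta PSI 0.3 against sd 0.05 at 30+30
  set.seed(99)
  n <- 30
  vals <- rbind(
    t(replicate(40, c(pmin(1, pmax(0, rnorm(n, 0.7, 0.05))),
                      pmin(1, pmax(0, rnorm(n, 0.4, 0.05)))))),
    t(replicate(160, pmin(1, pmax(0, rnorm(2 * n, 0.5, 0.05)))))
  )
  m <- toy_psi(vals, groups = c(rep("tumor", n), rep("normal", n)))
  dt <- select_differential(m)
  expect_gte(mean(dt$is_differential[1:40]), 0.95)
})
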