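test_that("median split sends at-median samples to the low group", {
  expect_identical(unname(dichotomize(c(a = 1, b = 2, c = 3, d = 4))),
                   c("low", "low", "high", "high"))
  expect_identical(unname(dichotomize(c(1, 2, 2, 4))),
                   c("low", "low", "low", "high"))
  expect_error(dichotomize(rep(2, 6)), "identical")
  expect_error(dichotomize(c(1, 2, 3)), "at least 4")
})

test_that("Kaplan-Meier estimate equals the product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  km2 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # single subject with an event drops to 0
  km3 <- km_estimate(4, 1)
  expect_equal(km3$survival, 0)
  # with no censoring the estimate is the empirical survival function
  set.seed(2)
  tt <- sample(1:50, 20, replace = TRUE)
  km4 <- km_estimate(tt, rep(1, 20))
  emp <- vapply(km4$time, function(s) mean(tt > s), numeric(1))
  expect_equal(km4$survival, emp)
})

test_that("log-rank statistic matches the hand-worked example", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi_square, (2 - 5 / 6)^2 / (0.25 + 2 / 9), tolerance = 1e-6)
  expect_equal(lr$chi_square, 2.8824, tolerance = 1e-4)
  # identical data in both groups: no signal
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # label invariance
  lr_sw <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(lr_sw$chi_square, lr$chi_square)
  expect_warning(out <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0),
                                     c("A", "A", "B", "B")), "no events")
  expect_equal(out$p, 1)
})

test_that("Cox hazard ratio matches grid maximization of the partial likelihood", {
  # A events at 1 and 3, B at 2 and 4; explicit Breslow partial likelihood
  loglik <- function(b) 2 * b - log(2 * exp(b) + 2) - log(exp(b) + 2) -
    log(exp(b) + 1)
  grid <- seq(-3, 3, by = 1e-4)
  b_star <- grid[which.max(loglik(grid))]
  fit <- cox_hr(c(1, 3, 2, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(log(fit$hr), b_star, tolerance = 1e-3)
  expect_equal(fit$hr, 2.56, tolerance = 0.01)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  # duplicated outcomes in both groups: HR = 1
  fit1 <- cox_hr(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(fit1$hr, 1, tolerance = 1e-8)
  # flipping labels inverts the ratio
  fit_sw <- cox_hr(c(1, 3, 2, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(fit_sw$hr, 1 / fit$hr, tolerance = 1e-8)
})

test_that("complete separation is reported as a capped monotone fit", {
  expect_warning(
    fit <- cox_hr(c(1, 2, 3, 10, 11, 12), rep(1, 6),
                  rep(c("A", "B"), each = 3)),
    "monotone")
  expect_true(fit$separated)
  expect_true(is.finite(fit$hr))
})

test_that("module survival association and retention work end to end", {
  cfg <- synthetic_config(seed = 41, n_events = 300,
                          module_sizes = c(60, 60), n_tumor = 200,
                          n_normal = 20, loading_strength = 2, delta = 1.2,
                          beta = c(1.5, 0), missing_rate = 0)
  sim <- generate_cohort(cfg)
  truth <- sim$truth$module_assignment
  ms <- module_set(truth[truth > 0], names(truth)[truth > 0])
  scores <- score_modules(sim$psi, ms)
  assoc <- module_survival(scores, sim$clinical)
  expect_identical(nrow(assoc), 4L)  # 2 modules x 2 endpoints
  expect_true(all(assoc$ci_low <= assoc$hr & assoc$hr <= assoc$ci_high))
  expect_true(all(assoc$n_high + assoc$n_low == 200))
  # the hazard-linked module (M1 or M2 depends on size ties; both are 60,
  # tie-break by smallest event id puts the beta module first)
  ret <- retain_prognostic(assoc)
  expect_named(ret, c("module", "os_p", "pfi_p", "reason", "retained"))
})

test_that("retention logic reproduces the published module accounting", {
  assoc <- as_survival_association(tcga_module_prognosis())
  ret <- retain_prognostic(assoc)
  expect_identical(sum(ret$reason %in% c("OS", "both")), 10L)
  expect_identical(sum(ret$reason %in% c("PFI", "both")), 8L)
  expect_identical(sum(ret$reason == "both", na.rm = TRUE), 5L)
  expect_setequal(ret$module[which(ret$reason == "both")],
                  c("BLCA_M1", "BLCA_M2", "LUAD_M3", "PRAD_M1", "UCEC_M3"))
  expect_identical(sum(ret$retained & ret$reason != "near_OS"), 13L)
  expect_identical(sum(ret$retained), 15L)
  expect_setequal(ret$module[ret$reason == "near_OS"],
                  c("LUSC_M2", "LUSC_M3"))
  # without the near-significance window only 13 remain
  strict <- retain_prognostic(assoc, include_near = FALSE)
  expect_identical(sum(strict$retained), 13L)
})
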