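test_that("KS distance matches brute-force enumeration of ECDF jumps", {
  p <- p_biased()
  tr <- tibble::tibble(stimulus_class = "old",
                       response = c("old", "new", "old"),
                       rt = c(0.8, 0.7, 1.4))
  got <- ks_statistic(tr, list(old = p))
  x <- sort(ifelse(tr$response == "new", -tr$rt, tr$rt))
  expected_T <- brute_force_ks(x, function(q) wfpt_signed_cdf(q, p))
  expect_equal(got$statistic, expected_T, tolerance = 1e-12)
  expect_gte(got$p, 0)
  expect_lte(got$p, 1)
})

test_that("overall KS statistic is the max across classes and p the product", {
  pp <- two_class_params()
  sim <- simulate_condition(pp, c(old = 50L, new = 50L), seed = 7)
  got <- ks_statistic(sim, pp)
  expect_equal(got$statistic, max(got$classes$statistic))
  expect_equal(got$p, prod(got$classes$p), tolerance = 1e-12)
})

test_that("KS p-values are in [0,1] across random data and shrink for misfit", {
  p_fit <- p_unbiased()
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(20:200, 1))
    tr <- sample_trials(p_unbiased(), n, seed = seed)
    dat <- tibble::tibble(stimulus_class = "old",
                          response = ifelse(tr$boundary == "upper",
                                            "old", "new"),
                          rt = tr$rt)
    pv <- ks_statistic(dat, list(old = p_fit))$p
    expect_gte(pv, 0); expect_lte(pv, 1)
  }
  # data generated far from the candidate model are flagged
  tr <- sample_trials(diffusion_params(v = -0.2, a = 0.08, t0 = 1.2), 400,
                      seed = 2)
  dat <- tibble::tibble(stimulus_class = "old",
                        response = ifelse(tr$boundary == "upper",
                                          "old", "new"),
                        rt = tr$rt)
  expect_lt(ks_statistic(dat, list(old = p_fit))$p, 1e-4)
})

test_that("KS fitting recovers known parameters from large samples", {
  pp <- two_class_params(v_old = 0.06, v_new = -0.12, a = 0.13, zr = 0.6,
                         t0 = 0.5)
  sim <- simulate_condition(pp, c(old = 2500L, new = 2500L), seed = 9)
  fit <- ks_fit(sim)
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_lt(abs(est[["a"]] - 0.13) / 0.13, 0.05)
  expect_lt(abs(est[["zr"]] - 0.6) / 0.6, 0.05)
  expect_lt(abs(est[["t0"]] - 0.5) / 0.5, 0.05)
  expect_lt(abs(est[["v_old"]] - 0.06), 0.06 * 0.25)
  expect_lt(abs(est[["v_new"]] + 0.12), 0.12 * 0.15)
  expect_true(fit$converged)
  expect_false(fit$screened)
})

test_that("sharing parameters across identical conditions costs no fit quality", {
  pp <- two_class_params(v_old = 0.08, v_new = 0.08, a = 0.14, zr = 0.5,
                         t0 = 0.5)
  sim <- simulate_condition(pp, c(old = 400L, new = 400L), seed = 13)
  free <- ks_fit(sim, design = fit_design())
  shared <- ks_fit(sim, design = fit_design(drift_per_class = FALSE))
  # nested-model property: the free design can always match the shared one
  expect_lte(free$objective, shared$objective + 0.05)
})

test_that("degenerate single-boundary data do not crash the fitter", {
  tr <- tibble::tibble(stimulus_class = "old",
                       response = "old",
                       rt = withr::with_seed(1, runif(40, 0.4, 1)))
  fit <- ks_fit(tr)
  expect_s3_class(fit, "ddm_fit")
  expect_true(is.finite(fit$objective))
})

test_that("identical data give identical fits", {
  sim <- simulate_condition(two_class_params(), c(old = 80L, new = 80L),
                            seed = 15)
  f1 <- ks_fit(sim)
  f2 <- ks_fit(sim)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(glance(f1), glance(f2))
})
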