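test_that("X2 is zero when observed equals expected and matches hand summation", {
  # hand table: collapse-free, expected computed independently from the
  # predicted signed CDF at the same edges
  p <- p_biased()
  sim <- simulate_condition(list(old = p), c(old = 200L), seed = 20)
  got <- chisq_statistic(sim, list(old = p), n_free = 0)
  # independent recomputation of expected counts for the 'old' responses
  rts_old <- sort(sim$rt[sim$response == "old"])
  edges <- quantile(rts_old, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  Fv <- wfpt_signed_cdf(c(0, edges, Inf), p)
  exp_old <- diff(Fv) * 200
  got_old <- got$bins[got$bins$response == "old", ]
  if (nrow(got_old) == 6) {
    expect_equal(got_old$expected, exp_old, tolerance = 1e-8)
    x2_hand <- sum((got_old$observed - got_old$expected)^2 / got_old$expected)
    expect_equal(sum((got$bins$observed - got$bins$expected)^2 /
                       got$bins$expected), got$statistic)
    expect_gte(got$statistic, x2_hand)
  }
  # observed == expected gives exactly zero
  tb <- tibble::tibble(observed = c(10, 20, 30), expected = c(10, 20, 30))
  expect_equal(sum((tb$observed - tb$expected)^2 / tb$expected), 0)
})

test_that("sparse-bin collapsing keeps expected counts at or above 1", {
  # a tiny class with very few errors forces collapsing
  p <- diffusion_params(v = 0.35, a = 0.14, zr = 0.5, t0 = 0.4)
  sim <- simulate_condition(list(old = p), c(old = 60L), seed = 21)
  got <- chisq_statistic(sim, list(old = p), n_free = 0)
  by_resp <- split(got$bins, got$bins$response)
  for (tb in by_resp) {
    if (nrow(tb) > 1) expect_true(all(tb$expected >= 1))
  }
  expect_true(is.finite(got$statistic))
  expect_gte(got$p, 0); expect_lte(got$p, 1)
})

test_that("chi-square fitting recovers parameters and is deterministic", {
  pp <- two_class_params(v_old = 0.06, v_new = -0.12, a = 0.13, zr = 0.6,
                         t0 = 0.5)
  sim <- simulate_condition(pp, c(old = 1200L, new = 1200L), seed = 22)
  fit <- chisq_fit(sim)
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_lt(abs(est[["a"]] - 0.13) / 0.13, 0.08)
  expect_lt(abs(est[["zr"]] - 0.6) / 0.6, 0.08)
  expect_lt(abs(est[["t0"]] - 0.5) / 0.5, 0.08)
  fit2 <- chisq_fit(sim)
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("near-perfect accuracy warns but still returns estimates", {
  p_easy <- two_class_params(v_old = 0.45, v_new = -0.45, a = 0.14,
                             zr = 0.5, t0 = 0.45)
  sim <- simulate_condition(p_easy, c(old = 80L, new = 80L), seed = 23)
  expect_lt(sum(sim$response != sim$stimulus_class), 11)
  expect_warning(fit <- chisq_fit(sim), "Fewer than 11")
  expect_s3_class(fit, "ddm_fit")
  expect_true(all(is.finite(fit$estimates$estimate)))
})
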