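test_that("recovery reports satisfy their own invariants", {
  rec <- recovery_experiment(
    truth = list(v = c(old = 0.04, new = -0.14), a = 0.14, zr = 0.66,
                 t0 = 0.6),
    counts = c(old = 70L, new = 35L), n_participants = 4, method = "ks",
    seed = 70, maxit = 300)
  expect_s3_class(rec, "ddm_recovery")
  expect_true(all(rec$rmse >= abs(rec$bias) - 1e-12))
  expect_setequal(rec$parameter, c("v_old", "v_new", "a", "zr", "t0"))
  # deterministic given the seed
  rec2 <- recovery_experiment(
    truth = list(v = c(old = 0.04, new = -0.14), a = 0.14, zr = 0.66,
                 t0 = 0.6),
    counts = c(old = 70L, new = 35L), n_participants = 4, method = "ks",
    seed = 70, maxit = 300)
  expect_equal(tidy(rec), tidy(rec2))
})

test_that("estimators agree on large unbiased zero-variability data", {
  truth <- list(v = c(old = 0.1, new = -0.1), a = 0.14, zr = 0.5, t0 = 0.5)
  pp <- two_class_params(v_old = 0.1, v_new = -0.1, a = 0.14, zr = 0.5,
                         t0 = 0.5)
  sim <- simulate_condition(pp, c(old = 1500L, new = 1500L), seed = 71)
  ks_est <- tidy(ks_fit(sim))
  cs_est <- tidy(chisq_fit(sim))
  ez_p <- ez_fit(summarize_for_ez(sim))
  for (par in c("a", "t0")) {
    k <- ks_est$estimate[ks_est$parameter == par]
    c_ <- cs_est$estimate[cs_est$parameter == par]
    e <- ez_p[[par]]
    expect_lt(abs(k - c_) / abs(k), 0.1)
    expect_lt(abs(k - e) / abs(k), 0.1)
  }
  # drift magnitude: EZ reports a single accuracy-coded drift
  k_v <- mean(abs(ks_est$estimate[ks_est$parameter %in% c("v_old", "v_new")]))
  expect_lt(abs(k_v - abs(ez_p$v)) / k_v, 0.1)
})

test_that("recovery error shrinks with the number of trials", {
  truth_p <- two_class_params(v_old = 0.08, v_new = -0.12, a = 0.13,
                              zr = 0.58, t0 = 0.5)
  err_at_n <- function(n) {
    errs <- purrr::map_dbl(1:3, function(r) {
      sim <- simulate_condition(truth_p, c(old = n, new = n),
                                seed = 80 + r)
      est <- tidy(ks_fit(sim))
      est <- setNames(est$estimate, est$parameter)
      mean(c(abs(est[["a"]] - 0.13) / 0.13, abs(est[["zr"]] - 0.58) / 0.58,
             abs(est[["t0"]] - 0.5) / 0.5))
    })
    median(errs)
  }
  e250 <- err_at_n(125L)
  e1000 <- err_at_n(500L)
  e5000 <- err_at_n(2500L)
  expect_lt(e5000, e250)
  expect_lt(median(c(e1000, e5000)), e250 + 0.01)
})

test_that("swapping EZ for KS on an unbiased scenario moves estimates < 10%", {
  truth <- list(v = c(old = 0.12), a = 0.12, zr = 0.5, t0 = 0.5)
  rec_ez <- recovery_experiment(truth, c(old = 400L), 6, method = "ez",
                                seed = 81, absolute_v = TRUE)
  rec_ks <- recovery_experiment(truth, c(old = 400L), 6, method = "ks",
                                seed = 81, absolute_v = TRUE)
  for (par in c("a", "t0", "v")) {
    ez_m <- rec_ez$mean_recovered[rec_ez$parameter == par]
    ks_m <- rec_ks$mean_recovered[rec_ks$parameter == par]
    expect_lt(abs(ez_m - ks_m) / abs(ks_m), 0.1)
  }
})
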