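test_that("absorption probability matches limits and the closed form", {
  # zero drift: upper-boundary probability equals the relative start point
  expect_equal(wfpt_absorption(diffusion_params(v = 0, a = 0.11, zr = 0.37)),
               0.37)
  expect_equal(wfpt_absorption(diffusion_params(v = 0, a = 0.2, zr = 0.5)),
               0.5)
  # value cross-checked against a 2e5-trial Euler-Maruyama simulation
  # (dt = 1e-4) during development: simulated 0.7773 +/- 0.0028 (3 SE, with
  # the expected small upward discretization bias)
  expect_equal(wfpt_absorption(p_biased()), 0.7755508, tolerance = 1e-6)
  # continuity in v at 0
  p_eps <- diffusion_params(v = 1e-12, a = 0.14, zr = 0.37)
  expect_equal(wfpt_absorption(p_eps), 0.37, tolerance = 1e-6)
  # strong drift saturates without overflow
  expect_equal(wfpt_absorption(diffusion_params(v = 10, a = 0.14)), 1,
               tolerance = 1e-8)
  expect_equal(wfpt_absorption(diffusion_params(v = -10, a = 0.14)), 0,
               tolerance = 1e-8)
  expect_error(wfpt_absorption(p_biased(sv = 0.1)), "trial-level")
})

test_that("densities vanish at 0+, stay nonnegative, and integrate to the absorption probabilities", {
  for (p in random_param_grid(8)) {
    expect_lt(wfpt_density(1e-6, p, "lower"), 1e-12)
    ts <- seq(0.01, 5, length.out = 200)
    expect_true(all(wfpt_density(ts, p, "lower") >= 0))
    expect_true(all(wfpt_density(ts, p, "upper") >= 0))
    i_up <- integrate(function(x) wfpt_density(x, p, "upper"), 0, Inf,
                      rel.tol = 1e-9)$value
    i_lo <- integrate(function(x) wfpt_density(x, p, "lower"), 0, Inf,
                      rel.tol = 1e-9)$value
    expect_equal(i_up, wfpt_absorption(p, "upper"), tolerance = 1e-6)
    expect_equal(i_up + i_lo, 1, tolerance = 1e-6)
  }
  expect_error(wfpt_density(-0.1, p_biased(), "lower"), "positive")
})

test_that("CDF agrees with quadrature of the density and has the right limits", {
  p <- p_biased()
  expect_equal(wfpt_cdf(0, p, "lower"), 0)
  q <- integrate(function(x) wfpt_density(x, p, "lower"), 0, 0.8,
                 rel.tol = 1e-10)$value
  expect_equal(wfpt_cdf(0.8, p, "lower"), q, tolerance = 1e-6)
  # symmetry at zero drift
  p0 <- diffusion_params(v = 0, a = 0.14, zr = 0.5)
  expect_equal(wfpt_cdf(Inf, p0, "lower"), 0.5, tolerance = 1e-9)
  expect_equal(wfpt_cdf(Inf, p0, "upper"), 0.5, tolerance = 1e-9)
  # nondecreasing, consistent with density by differentiation
  ts <- seq(0.05, 4, length.out = 80)
  Fv <- wfpt_cdf(ts, p, "upper")
  expect_true(all(diff(Fv) >= -1e-12))
  h <- 1e-5
  mid <- c(0.4, 0.9, 1.6)
  deriv <- (wfpt_cdf(mid + h, p, "upper") - wfpt_cdf(mid - h, p, "upper")) /
    (2 * h)
  expect_equal(deriv, wfpt_density(mid, p, "upper"), tolerance = 1e-4)
})

test_that("signed CDF is a proper, monotone CDF that reduces to the defective CDFs", {
  p <- p_biased()
  qs <- seq(-6, 6, length.out = 1000)
  Fv <- wfpt_signed_cdf(qs, p)
  expect_true(all(diff(Fv) >= -1e-12))
  expect_equal(wfpt_signed_cdf(-100, p), 0)
  expect_equal(wfpt_signed_cdf(100, p), 1, tolerance = 1e-8)
  # degenerate mixture equals composition of the per-boundary CDFs
  expect_equal(wfpt_signed_cdf(1.3, p),
               wfpt_absorption(p, "lower") + wfpt_cdf(1.3 - p$t0, p, "upper"),
               tolerance = 1e-10)
  expect_equal(wfpt_signed_cdf(-0.9, p),
               wfpt_absorption(p, "lower") - wfpt_cdf(0.9 - p$t0, p, "lower"),
               tolerance = 1e-10)
  # plateau across the non-decision window
  expect_equal(wfpt_signed_cdf(0, p), wfpt_absorption(p, "lower"))
})

test_that("variability mixture matches a brute-force node-free average and simulation", {
  p <- diffusion_params(v = 0.1, a = 0.14, zr = 0.55, t0 = 0.45,
                        sv = 0.05, sz = 0.02, st = 0.12)
  qs <- c(-1.5, -0.8, 0.7, 1.1, 2)
  # dense Monte Carlo average over the mixing distributions as oracle
  mix <- withr::with_seed(99, {
    n_mc <- 3000
    v_i <- rnorm(n_mc, p$v, p$sv)
    zr_i <- p$zr + runif(n_mc, -0.5, 0.5) * p$sz / p$a
    t0_i <- p$t0 + runif(n_mc, -0.5, 0.5) * p$st
    acc <- numeric(length(qs))
    for (i in seq_len(n_mc)) {
      pp <- diffusion_params(v = v_i[i], a = p$a, zr = zr_i[i], t0 = t0_i[i])
      acc <- acc + wfpt_signed_cdf(qs, pp)
    }
    acc / n_mc
  })
  expect_equal(wfpt_signed_cdf(qs, p), mix, tolerance = 0.02)
  # and against a simulated ECDF with trial-level variability
  tr <- sample_trials(p, 4000, seed = 17)
  x <- ifelse(tr$boundary == "lower", -tr$rt, tr$rt)
  emp <- vapply(qs, function(qq) mean(x <= qq), numeric(1))
  expect_equal(wfpt_signed_cdf(qs, p), emp, tolerance = 0.03)
})
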