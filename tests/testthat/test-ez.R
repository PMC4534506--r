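test_that("EZ summary statistics are computed over correct trials only", {
  tr <- tibble::tibble(stimulus_class = c("old", "old", "old"),
                       response = c("old", "old", "new"),
                       rt = c(0.5, 0.7, 0.6))
  st <- summarize_for_ez(tr)
  expect_equal(st$pc, 2 / 3)
  expect_equal(st$mrt, 0.6)
  expect_equal(st$vrt, 0.02)
  expect_equal(st$n, 3)
  expect_error(summarize_for_ez(tr[3, , drop = FALSE]), "2 correct")
})

test_that("EZ summaries are invariant to a joint boundary/class relabeling", {
  sim <- simulate_condition(two_class_params(), c(old = 60L, new = 60L),
                            seed = 44)
  flip <- function(x) ifelse(x == "old", "new", "old")
  flipped <- dplyr::mutate(sim, stimulus_class = flip(stimulus_class),
                           response = flip(response))
  expect_equal(summarize_for_ez(sim), summarize_for_ez(flipped))
})

test_that("EZ inversion recovers parameters from analytic moments", {
  # forward moments from the independent closed forms (logistic accuracy,
  # tanh mean decision time), then inverted
  cases <- list(c(v = 0.1, a = 0.14, t0 = 0.4),
                c(v = 0.19, a = 0.12, t0 = 0.55),
                c(v = -0.13, a = 0.1, t0 = 0.3))
  for (cs in cases) {
    vv <- unname(cs["v"]); aa <- unname(cs["a"]); tt <- unname(cs["t0"])
    pc <- 1 / (1 + exp(-vv * aa / 0.01))
    mdt <- (aa / (2 * vv)) * tanh(vv * aa / 0.02)
    L <- qlogis(pc)
    vrt <- 1e-4 * L * (L * pc^2 - L * pc + pc - 0.5) / vv^4
    est <- ez_fit(list(pc = pc, mrt = tt + mdt, vrt = vrt, n = 1000))
    expect_equal(est$v, vv, tolerance = 1e-8)
    expect_equal(est$a, aa, tolerance = 1e-8)
    expect_equal(est$t0, tt, tolerance = 1e-8)
    expect_equal(est$zr, 0.5)
    expect_equal(est$sv + est$sz + est$st, 0)
  }
})

test_that("EZ round-trips through simulated data within Monte-Carlo error", {
  for (seed in 1:3) {
    truth <- withr::with_seed(seed, c(v = runif(1, 0.06, 0.2),
                                      a = runif(1, 0.1, 0.16),
                                      t0 = runif(1, 0.3, 0.6)))
    p <- diffusion_params(v = unname(truth["v"]), a = unname(truth["a"]),
                          zr = 0.5, t0 = unname(truth["t0"]))
    tr <- sample_trials(p, 2e5, seed = seed + 100)
    dat <- tibble::tibble(stimulus_class = "old",
                          response = ifelse(tr$boundary == "upper",
                                            "old", "new"),
                          rt = tr$rt)
    est <- ez_fit(summarize_for_ez(dat))
    expect_equal(est$v, unname(truth["v"]), tolerance = 0.02)
    expect_equal(est$a, unname(truth["a"]), tolerance = 0.02)
    expect_equal(est$t0, unname(truth["t0"]), tolerance = 0.01)
  }
})

test_that("EZ sign rule and degenerate accuracies behave as specified", {
  # below-chance accuracy gives negative drift
  est <- ez_fit(list(pc = 0.3, mrt = 0.8, vrt = 0.1, n = 100))
  expect_lt(est$v, 0)
  expect_error(ez_fit(list(pc = 1, mrt = 0.5, vrt = 0.05, n = 90)),
               "perfect accuracy")
  expect_error(ez_fit(list(pc = 0.5, mrt = 0.5, vrt = 0.05, n = 90)),
               "pc = 0.5")
  # edge correction replaces pc = 1 by 1 - 1/(2n)
  est1 <- ez_fit(list(pc = 1, mrt = 0.5, vrt = 0.05, n = 90),
                 edge_correction = TRUE)
  est2 <- ez_fit(list(pc = 1 - 1 / 180, mrt = 0.5, vrt = 0.05, n = 90))
  expect_equal(est1$v, est2$v)
})
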