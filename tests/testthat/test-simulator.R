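test_that("sampling is seeded, reproducible, and respects support bounds", {
  p <- p_biased(st = 0.1)
  a1 <- sample_trials(p, 200, seed = 3)
  a2 <- sample_trials(p, 200, seed = 3)
  expect_identical(a1, a2)
  expect_true(all(a1$rt >= p$t0 - p$st / 2))
  # extreme drift dominates the choice
  hi <- sample_trials(diffusion_params(v = 10, a = 0.14), 300, seed = 4)
  expect_true(all(hi$boundary == "upper"))
})

test_that("simulated choice proportions and moments match the model", {
  p <- p_biased()
  tr <- sample_trials(p, 1e5, seed = 8)
  p_up <- wfpt_absorption(p, "upper")
  se <- sqrt(p_up * (1 - p_up) / 1e5)
  expect_lt(abs(mean(tr$boundary == "upper") - p_up), 3 * se)
  # RT quantiles against the predicted signed CDF on a random grid of params
  for (pp in random_param_grid(6, seed = 5)) {
    trq <- sample_trials(pp, 2e4, seed = 6)
    x <- ifelse(trq$boundary == "lower", -trq$rt, trq$rt)
    qs <- c(-1.2, -0.6, 0.8, 1.5)
    emp <- vapply(qs, function(q) mean(x <= q), numeric(1))
    expect_equal(emp, wfpt_signed_cdf(qs, pp), tolerance = 0.015)
  }
})

test_that("condition simulation applies per-class drift, deadlines and labels", {
  pp <- two_class_params()
  sim <- simulate_condition(pp, c(old = 140L, new = 70L), seed = 10)
  expect_equal(nrow(sim), 210)
  expect_equal(sum(sim$stimulus_class == "old"), 140)
  expect_true(all(sim$response %in% c("old", "new")))
  expect_true(all(sim$censored == (sim$rt >= 4)))
  no_deadline <- simulate_condition(pp, c(old = 50L, new = 50L),
                                    deadline = Inf, seed = 10)
  expect_false(any(no_deadline$censored))
  expect_error(simulate_condition(pp, c(old = 140L)), "match")
})

test_that("equal-drift classes are exchangeable", {
  pp <- two_class_params(v_old = 0.06, v_new = 0.06)
  sim <- simulate_condition(pp, c(old = 4000L, new = 4000L), seed = 12)
  x_old <- with(sim[sim$stimulus_class == "old", ],
                ifelse(response == "new", -rt, rt))
  x_new <- with(sim[sim$stimulus_class == "new", ],
                ifelse(response == "new", -rt, rt))
  expect_gt(suppressWarnings(stats::ks.test(x_old, x_new)$p.value), 0.001)
})

test_that("full experiments are reproducible and follow their design", {
  d <- experiment_design("exp1", n_per_group = 3)
  dat1 <- generate_experiment(d, seed = 21)
  dat2 <- generate_experiment(d, seed = 21)
  expect_identical(dat1, dat2)
  expect_equal(length(unique(dat1$participant)), 6)
  counts <- dplyr::count(dat1, participant, stimulus_class)
  expect_true(all(counts$n %in% c(70, 140)))
  expect_setequal(unique(dat1$group), c("old_bias", "new_bias"))
  # zero between-participant SDs give identical truths: with a shared seed
  # offset the data still differ across participants via trial noise, but
  # the censoring property must hold
  expect_lt(mean(dat1$censored), 0.05)
})

test_that("between-participant heterogeneity is truncated to valid regions", {
  d <- experiment_design("exp3", n_per_group = 4)
  dat <- generate_experiment(d, seed = 31)
  expect_equal(length(unique(dat$participant)), 4)
  expect_setequal(unique(dat$condition), c("not_presented", "once", "twice"))
  counts <- dplyr::count(dat, participant, condition)
  expect_true(all(counts$n == 90))
})
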