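# Restricted multi-condition models: only the psychologically responsible
# parameter should be able to absorb a drift manipulation.

make_exp3_like <- function(v_by_cond = c(not_presented = -0.21, once = 0.05,
                                         twice = 0.14),
                           a = 0.12, zr = 0.5, t0 = 0.6, n = 90L, seed = 1) {
  classes <- c(not_presented = "new", once = "old", twice = "old")
  withr::with_seed(seed, {
    purrr::map_dfr(names(v_by_cond), function(cn) {
      p <- diffusion_params(v = unname(v_by_cond[cn]), a = a, zr = zr,
                            t0 = t0)
      cl <- if (cn %in% names(classes)) classes[[cn]] else "old"
      sim <- simulate_condition(setNames(list(p), cl), setNames(n, cl))
      dplyr::mutate(sim, condition = cn, .before = 1)
    })
  })
}

test_that("a free drift fits drift-manipulated data; a free t0 does not", {
  tr <- make_exp3_like(seed = 2)
  fit_v <- restricted_fit(tr, "v")
  fit_t0 <- restricted_fit(tr, "t0")
  expect_gt(fit_v$p, 0.05)
  expect_lt(fit_t0$p, 0.05)
  expect_lt(fit_v$objective, fit_t0$objective)
  # recovered per-condition drifts track the generating ordering
  v_est <- fit_v$estimates[fit_v$estimates$parameter == "v", ]
  v_by <- setNames(v_est$estimate, v_est$condition)
  expect_lt(v_by[["not_presented"]], 0)
  expect_gt(v_by[["twice"]], v_by[["once"]])
})

test_that("truly identical conditions are fit acceptably by any restriction", {
  tr <- make_exp3_like(v_by_cond = c(c1 = 0.1, c2 = 0.1, c3 = 0.1),
                       seed = 3)
  for (par in c("v", "a", "zr", "t0")) {
    fit <- restricted_fit(tr, par)
    expect_gt(fit$p, 0.01)
  }
})

test_that("restricting parameters can never beat the fully free fit", {
  tr <- make_exp3_like(seed = 4)
  restricted <- restricted_fit(tr, "v")
  free_obj <- sum(purrr::map_dbl(unique(tr$condition), function(cn) {
    ks_fit(tr[tr$condition == cn, ])$objective
  }))
  expect_gte(restricted$objective, free_obj - 0.05)
})

test_that("unknown parameter names are rejected", {
  tr <- make_exp3_like(seed = 5)
  expect_error(restricted_fit(tr, "sv"), "arg")
  expect_error(restricted_fit(tr[tr$condition == "once", ], "v"),
               "two conditions")
})
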