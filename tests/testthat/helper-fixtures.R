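# Shared fixtures, built in code.

p_unbiased <- function(...) diffusion_params(v = 0.1, a = 0.14, zr = 0.5,
                                             t0 = 0.4, ...)

p_biased <- function(...) diffusion_params(v = 0.04, a = 0.14, zr = 0.66,
                                           t0 = 0.6, ...)

# Two-class parameter list sharing everything but drift.
two_class_params <- function(v_old = 0.04, v_new = -0.14, a = 0.14,
                             zr = 0.66, t0 = 0.6, ...) {
  list(old = diffusion_params(v = v_old, a = a, zr = zr, t0 = t0, ...),
       new = diffusion_params(v = v_new, a = a, zr = zr, t0 = t0, ...))
}

# Random valid no-variability parameter sets for property loops.
random_param_grid <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      diffusion_params(v = runif(1, -0.3, 0.3),
                       a = runif(1, 0.08, 0.2),
                       zr = runif(1, 0.25, 0.75),
                       t0 = runif(1, 0.2, 0.8))
    })
  })
}

# Brute-force KS distance: enumerate every ECDF jump point.
brute_force_ks <- function(x_sorted, cdf_fun) {
  n <- length(x_sorted)
  Fv <- cdf_fun(x_sorted)
  max(vapply(seq_len(n), function(i)
    max(abs(Fv[i] - (i - 1) / n), abs(Fv[i] - i / n)), numeric(1)))
}
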