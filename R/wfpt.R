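# First-passage-time machinery for the two-boundary Wiener process.
#
# Internally everything is computed on the unit-diffusion scale: vn = v/s,
# an = a/s, w = zr. Lower-boundary quantities use the standard infinite-series
# expansions; upper-boundary quantities follow by the reflection
# v -> -v, w -> 1 - w. Densities and CDFs are "defective": the total mass at a
# boundary equals that boundary's absorption probability.

WFPT_EPS <- 1e-10   # absolute truncation tolerance for series terms
WFPT_KMAX <- 1000L  # hard cap on series length (see wfpt_cdf_lower_norm)

check_no_variability <- function(p, what) {
  if (p$sv > 0 || p$sz > 0 || p$st > 0)
    abort(paste0("`", what, "` is defined for trial-level parameters only; ",
                 "set sv = sz = st = 0 (use wfpt_signed_cdf() for mixtures)."))
}

#' Absorption probability at a boundary
#'
#' Probability that a Wiener diffusion with drift `v`, boundaries at 0 and
#' `a`, and start point `zr * a` is eventually absorbed at the given boundary.
#' For zero drift the upper-boundary probability equals `zr`. Variability
#' parameters must be zero (this is a trial-level quantity).
#'
#' @param p A [diffusion_params()] object with `sv = sz = st = 0`.
#' @param boundary `"upper"` or `"lower"`.
#' @return A probability in (0, 1).
#' @examples
#' wfpt_absorption(diffusion_params(v = 0.04, a = 0.14, zr = 0.66))
#' @export
wfpt_absorption <- function(p, boundary = c("upper", "lower")) {
  stopifnot(inherits(p, "diffusion_params"))
  boundary <- match.arg(boundary)
  check_no_variability(p, "wfpt_absorption")
  p_up <- absorption_upper_norm(p$v / p$s, p$a / p$s, p$zr)
  if (boundary == "upper") p_up else 1 - p_up
}

# P(absorb at upper) for unit diffusion; stable for large |drift|.
absorption_upper_norm <- function(vn, an, w) {
  x <- 2 * vn * an
  if (abs(x) < 1e-9) return(w)  # zero-drift limit
  if (-x > 700) {
    # strong negative drift: both expm1() terms explode; cancel analytically
    return(exp(x * (1 - w)) * (-expm1(x * w)) / (-expm1(x)))
  }
  expm1(-x * w) / expm1(-x)
}

#' First-passage-time density at a boundary
#'
#' Defective density (per second, as a function of decision time, excluding
#' `t0`) of absorption at the given boundary. Uses the small-time and
#' large-time series expansions, switching to whichever needs fewer terms.
#' Integrating the density for a boundary over all times gives that boundary's
#' absorption probability.
#'
#' @inheritParams wfpt_absorption
#' @param t Vector of decision times in seconds (> 0).
#' @return Density values, same length as `t`.
#' @export
wfpt_density <- function(t, p, boundary = c("upper", "lower")) {
  stopifnot(inherits(p, "diffusion_params"))
  boundary <- match.arg(boundary)
  check_no_variability(p, "wfpt_density")
  if (any(!is.finite(t)) || any(t <= 0))
    abort("`t` must be finite and strictly positive.")
  vn <- p$v / p$s; an <- p$a / p$s; w <- p$zr
  if (boundary == "upper") { vn <- -vn; w <- 1 - w }
  wfpt_density_lower_norm(t, vn, an, w)
}

# Lower-boundary defective density, unit diffusion.
wfpt_density_lower_norm <- function(t, vn, an, w, eps = WFPT_EPS) {
  tau <- t / an^2
  pref <- exp(-vn * an * w - vn^2 * t / 2) / an^2
  core <- vapply(tau, function(tt) {
    # term counts for the two expansions (absolute tolerance eps on the core)
    kl <- max(sqrt(-2 * log(pi * tt * eps) / (pi^2 * tt)), 1 / (pi * sqrt(tt)))
    ks <- max(2 + sqrt(-2 * tt * log(2 * eps * sqrt(2 * pi * tt))),
              sqrt(tt) + 1)
    if (!is.finite(kl)) kl <- Inf
    if (!is.finite(ks)) ks <- 2
    if (ks < kl) {
      K <- ceiling(ks)
      k <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
      sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tt))) / sqrt(2 * pi * tt^3)
    } else {
      K <- min(ceiling(kl), WFPT_KMAX)
      k <- seq_len(K)
      pi * sum(k * exp(-k^2 * pi^2 * tt / 2) * sin(k * pi * w))
    }
  }, numeric(1))
  pmax(pref * core, 0)
}

#' First-passage-time CDF at a boundary
#'
#' Defective cumulative distribution of decision time at the given boundary:
#' `F_b(t)` rises from 0 to the absorption probability of boundary `b`.
#' Computed from the exponentially convergent tail series of the large-time
#' expansion; for times so small that the series would need more than 1000
#' terms the absorbed mass is itself below machine precision and 0 is
#' returned.
#'
#' @inheritParams wfpt_absorption
#' @param t Vector of decision times in seconds (>= 0).
#' @return Cumulative probabilities, same length as `t`.
#' @export
wfpt_cdf <- function(t, p, boundary = c("upper", "lower")) {
  stopifnot(inherits(p, "diffusion_params"))
  boundary <- match.arg(boundary)
  check_no_variability(p, "wfpt_cdf")
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0))
    abort("`t` must be non-negative.")
  vn <- p$v / p$s; an <- p$a / p$s; w <- p$zr
  if (boundary == "upper") { vn <- -vn; w <- 1 - w }
  wfpt_cdf_lower_norm(t, vn, an, w)
}

# Lower-boundary defective CDF, unit diffusion, vectorized over t.
# F(t) = P_low - tail(t) with
# tail(t) = (pi/an^2) e^{-vn an w} sum_k k sin(k pi w) exp(-lam_k t) / lam_k,
# lam_k = (vn^2 + k^2 pi^2 / an^2) / 2.
wfpt_cdf_lower_norm <- function(t, vn, an, w, eps = 1e-12) {
  p_low <- 1 - absorption_upper_norm(vn, an, w)
  out <- numeric(length(t))
  pos <- which(t > 0 & is.finite(t))
  out[is.infinite(t)] <- p_low
  if (length(pos)) {
    tt <- t[pos]
    # terms needed so the k-th term magnitude falls below eps
    kreq <- ceiling(sqrt(pmax(2 * an^2 * (-log(eps)) / (pi^2 * tt), 1))) + 2
    usable <- kreq <= WFPT_KMAX
    # below the usable range the total absorbed mass is < 1e-300: return 0
    if (any(usable)) {
      K <- max(kreq[usable])
      k <- seq_len(K)
      lam <- (vn^2 + k^2 * pi^2 / an^2) / 2
      coef <- pi / an^2 * exp(-vn * an * w) * k * sin(k * pi * w) / lam
      E <- exp(-outer(lam, tt[usable]))  # K x n
      tails <- as.numeric(crossprod(E, coef))
      out[pos[usable]] <- pmin(pmax(p_low - tails, 0), p_low)
    }
  }
  out
}

#' Predicted CDF on the signed response-time axis
#'
#' Joint model prediction for both response types on a single axis: response
#' times of lower-boundary ("new") responses carry a negative sign, those of
#' upper-boundary ("old") responses a positive sign. The returned value is
#' `P(signed RT <= q)`, a proper (non-defective) CDF rising from 0 at
#' `-Inf` to 1 at `+Inf`, with a flat plateau around 0 spanning the
#' non-decision time. Trial-to-trial variability in drift (normal), start
#' point (uniform) and non-decision time (uniform) is integrated out by
#' deterministic quadrature: Gauss-Hermite over drift and Gauss-Legendre over
#' the two uniform ranges.
#'
#' @param q Vector of signed response times in seconds.
#' @param p A [diffusion_params()] object (variability allowed).
#' @param gh_order Gauss-Hermite order for the drift mixture (default 12).
#' @param gl_order Gauss-Legendre order for the start-point and non-decision
#'   mixtures (default 8).
#' @return Cumulative probabilities, same length as `q`.
#' @examples
#' p <- diffusion_params(v = 0.04, a = 0.14, zr = 0.66, t0 = 0.6)
#' wfpt_signed_cdf(c(-1, 0, 1), p)
#' @export
wfpt_signed_cdf <- function(q, p, gh_order = 12, gl_order = 8) {
  stopifnot(inherits(p, "diffusion_params"))
  if (p$sv == 0 && p$sz == 0 && p$st == 0) {
    out <- signed_cdf_fixed(q, p$v, p$a, p$zr, p$t0, p$s)
    return(pmin(pmax(out, 0), 1))
  }
  nodes <- mixing_nodes(p, gh_order, gl_order)
  out <- numeric(length(q))
  for (i in seq_len(nrow(nodes))) {
    out <- out + nodes$wt[i] *
      signed_cdf_fixed(q, nodes$v[i], p$a, nodes$zr[i], nodes$t0[i], p$s)
  }
  pmin(pmax(out, 0), 1)
}

# Signed-axis CDF for a single (no-variability) parameter point.
signed_cdf_fixed <- function(q, v, a, zr, t0, s) {
  vn <- v / s; an <- a / s; w <- zr
  p_low <- 1 - absorption_upper_norm(vn, an, w)
  out <- numeric(length(q))
  neg <- q < 0
  dt_neg <- -q[neg] - t0
  out[neg] <- p_low - wfpt_cdf_lower_norm(pmax(dt_neg, 0), vn, an, w)
  dt_pos <- q[!neg] - t0
  out[!neg] <- p_low +
    wfpt_cdf_lower_norm(pmax(dt_pos, 0), -vn, an, 1 - w)
  out
}

# Quadrature nodes and weights for the (v, zr, t0) variability mixture.
# Returns a data.frame with columns v, zr, t0, wt summing to 1.
mixing_nodes <- function(p, gh_order = 12, gl_order = 8) {
  if (p$sv > 0) {
    gh <- pracma::gaussHermite(gh_order)
    v_nodes <- p$v + sqrt(2) * p$sv * gh$x
    v_wts <- gh$w / sqrt(pi)
  } else {
    v_nodes <- p$v; v_wts <- 1
  }
  if (p$sz > 0) {
    gl <- pracma::gaussLegendre(gl_order, -0.5, 0.5)
    zr_nodes <- p$zr + (p$sz / p$a) * gl$x
    zr_wts <- gl$w
  } else {
    zr_nodes <- p$zr; zr_wts <- 1
  }
  if (p$st > 0) {
    gl <- pracma::gaussLegendre(gl_order, -0.5, 0.5)
    t0_nodes <- p$t0 + p$st * gl$x
    t0_wts <- gl$w
  } else {
    t0_nodes <- p$t0; t0_wts <- 1
  }
  grid <- expand.grid(iv = seq_along(v_nodes), iz = seq_along(zr_nodes),
                      it = seq_along(t0_nodes))
  data.frame(v = v_nodes[grid$iv], zr = zr_nodes[grid$iz],
             t0 = t0_nodes[grid$it],
             wt = v_wts[grid$iv] * zr_wts[grid$iz] * t0_wts[grid$it])
}
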