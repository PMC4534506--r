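# Design-matrix layer: which diffusion parameters are free, which are fixed,
# and how free parameters map to an unconstrained optimization space.

PARAM_NAMES <- c("v", "a", "zr", "t0", "sv", "sz", "st")

#' Specify free and fixed parameters for distribution fitting
#'
#' Builds the constraint structure used by [ks_fit()] and [chisq_fit()]:
#' each of the seven diffusion parameters is either free or fixed. When
#' `drift_per_class = TRUE` (the default), a free drift rate is estimated
#' separately for every stimulus class (e.g. one for old items, one for new
#' items) while all other parameters are shared across classes.
#'
#' Parameters named in neither `free` nor `fixed` receive fixed defaults:
#' `zr = 0.5` and `sv = sz = st = 0`. `v`, `a` and `t0` must be free or fixed
#' explicitly.
#'
#' @param free Character vector of free parameter names (subset of
#'   `v, a, zr, t0, sv, sz, st`).
#' @param fixed Named list of fixed values for non-free parameters.
#' @param drift_per_class Estimate one drift rate per stimulus class.
#' @return A list of class `ddm_fit_design`.
#' @examples
#' fit_design()                               # v (per class), a, zr, t0 free
#' fit_design(free = c("v", "a", "zr", "t0", "sv", "sz", "st"))  # all free
#' @export
fit_design <- function(free = c("v", "a", "zr", "t0"), fixed = list(),
                       drift_per_class = TRUE) {
  bad <- setdiff(c(free, names(fixed)), PARAM_NAMES)
  if (length(bad))
    abort(paste0("Unknown parameter name(s): ", paste(bad, collapse = ", ")))
  if (length(free) == 0) abort("At least one parameter must be free.")
  overlap <- intersect(free, names(fixed))
  if (length(overlap))
    abort(paste0("Parameter(s) both free and fixed: ",
                 paste(overlap, collapse = ", ")))
  defaults <- list(zr = 0.5, sv = 0, sz = 0, st = 0)
  for (nm in setdiff(PARAM_NAMES, c(free, names(fixed)))) {
    if (is.null(defaults[[nm]]))
      abort(paste0("Parameter `", nm, "` must be either free or fixed."))
    fixed[[nm]] <- defaults[[nm]]
  }
  structure(list(free = free, fixed = fixed,
                 drift_per_class = isTRUE(drift_per_class)),
            class = "ddm_fit_design")
}

# --- transformed parameter space -------------------------------------------
# v: identity; a, t0: log; zr: logit; sz, st: logit of the fraction of their
# maximal admissible range (which depends on a, zr, t0, so decoding is
# order-dependent); sv: log.

theta_names <- function(design, classes) {
  nm <- character(0)
  for (par in design$free) {
    if (par == "v" && design$drift_per_class) {
      nm <- c(nm, paste0("v_", classes))
    } else nm <- c(nm, par)
  }
  nm
}

encode_theta <- function(values, design, classes) {
  # values: named list with v as named-per-class vector, others scalars
  out <- numeric(0)
  for (par in design$free) {
    x <- switch(par,
      v = if (design$drift_per_class) unname(values$v[classes]) else
        unname(values$v[1]),
      a = log(values$a),
      zr = qlogis(values$zr),
      t0 = log(max(values$t0, 1e-3)),
      sv = log(max(values$sv, 1e-3)),
      sz = qlogis(min(max(values$sz_frac %||% 0.3, 1e-3), 1 - 1e-3)),
      st = qlogis(min(max(values$st_frac %||% 0.3, 1e-3), 1 - 1e-3)))
    out <- c(out, x)
  }
  setNames(out, theta_names(design, classes))
}

decode_theta <- function(theta, design, classes, s) {
  i <- 1L
  vals <- design$fixed
  v_by_class <- NULL
  for (par in design$free) {
    if (par == "v" && design$drift_per_class) {
      v_by_class <- setNames(theta[i:(i + length(classes) - 1L)], classes)
      i <- i + length(classes)
    } else {
      vals[[par]] <- theta[i]
      i <- i + 1L
    }
  }
  a <- if ("a" %in% design$free) exp(vals$a) else vals$a
  zr <- if ("zr" %in% design$free) plogis(vals$zr) else vals$zr
  t0 <- if ("t0" %in% design$free) exp(vals$t0) else vals$t0
  sv <- if ("sv" %in% design$free) exp(vals$sv) else vals$sv
  sz <- if ("sz" %in% design$free)
    plogis(vals$sz) * 2 * a * min(zr, 1 - zr) * 0.999 else vals$sz
  st <- if ("st" %in% design$free) plogis(vals$st) * 2 * t0 * 0.999 else vals$st
  if (is.null(v_by_class)) {
    v0 <- if ("v" %in% design$free) vals$v else vals$v
    v_by_class <- setNames(rep(v0, length(classes)), classes)
  }
  lapply(setNames(classes, classes), function(cl) {
    diffusion_params(v = unname(v_by_class[cl]), a = a, zr = zr, t0 = t0,
                     sv = sv, sz = sz, st = st, s = s)
  })
}

# EZ-based starting values on accuracy-coded data, with fallbacks when the
# closed form is unavailable (extreme accuracy, too few errors).
starting_values <- function(trials, classes, s) {
  est <- tryCatch({
    st <- summarize_for_ez(trials)
    ez_fit(st, s = s, edge_correction = TRUE)
  }, error = function(e) NULL)
  if (is.null(est)) {
    est <- list(v = 0.5 * s, a = 1.2 * s,
                t0 = max(0.9 * min(trials$rt), 0.1))
  }
  v_mag <- max(abs(est$v), 0.1 * s)
  v <- setNames(ifelse(classes == "new", -v_mag, v_mag), classes)
  list(v = v, a = est$a, zr = 0.5, t0 = max(min(est$t0, min(trials$rt) * 0.95), 0.05),
       sv = 0.05 * s / 0.1, sz_frac = 0.3, st_frac = 0.3)
}

# Deterministic multi-start Nelder-Mead driver. `starts` is a list of theta
# vectors; after the multistart phase the search is restarted from the best
# point until the objective stops improving, which guards against premature
# simplex collapse. Identical data always yield identical fits.
run_simplex <- function(starts, objective, maxit = 800, reltol = 1e-6,
                        polish_tol = 1e-4, max_polish = 2) {
  if (!is.list(starts)) starts <- list(starts)
  best <- NULL
  n_eval <- 0L
  for (start in starts) {
    fit <- tryCatch(
      optim(start, objective, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_eval <- n_eval + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(par = starts[[1]], value = Inf, converged = FALSE,
                n_eval = n_eval))
  for (k in seq_len(max_polish)) {
    fit <- tryCatch(
      optim(best$par, objective, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) break
    n_eval <- n_eval + fit$counts[["function"]]
    improved <- best$value - fit$value
    if (fit$value < best$value) best <- fit
    if (improved < polish_tol) break
  }
  list(par = best$par, value = best$value,
       converged = best$convergence == 0 && is.finite(best$value),
       n_eval = n_eval)
}

# Multistart set: the EZ-derived start plus variants exploring the start
# point, for which EZ provides no information (it assumes zr = 0.5).
build_starts <- function(theta0, design, classes, n_starts = 3) {
  starts <- list(theta0)
  nm <- theta_names(design, classes)
  if (n_starts >= 2 && "zr" %in% nm) {
    for (z in c(0.3, 0.7)) {
      th <- theta0
      th[which(nm == "zr")] <- qlogis(z)
      starts <- c(starts, list(th))
    }
    starts <- starts[seq_len(min(n_starts, length(starts)))]
  } else if (n_starts >= 2) {
    starts <- c(starts, list(theta0 + 0.25, theta0 - 0.2))
    starts <- starts[seq_len(min(n_starts, length(starts)))]
  }
  starts
}
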