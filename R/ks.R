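# Kolmogorov-Smirnov estimation on the signed response-time axis, in the
# style of minimum-distance diffusion fitting: RTs of lower-boundary ("new")
# responses are negated, both response types share one empirical distribution
# per stimulus class, and the parameters minimize the distance between the
# empirical and predicted signed CDFs (equivalently, maximize the product of
# per-class KS p-values).

#' Signed response times for one stimulus class
#'
#' @noRd
signed_rts <- function(trials) {
  ifelse(trials$response == "new", -trials$rt, trials$rt)
}

#' Kolmogorov-Smirnov fit statistic for a candidate parameter set
#'
#' For each stimulus class, computes the supremum distance `T` between the
#' empirical CDF of the signed RTs and the model's predicted signed CDF, and
#' the corresponding p-value from the asymptotic Kolmogorov distribution at
#' that class's trial count. The overall statistic is the maximum `T` across
#' classes; the overall p-value is the product of the per-class p-values.
#'
#' @param trials A tibble with columns `stimulus_class`, `response`, `rt`.
#' @param params_by_class Named list of [diffusion_params()], one per
#'   stimulus class present in `trials`.
#' @return A list with `statistic`, `p` and a per-class tibble `classes`.
#' @export
ks_statistic <- function(trials, params_by_class) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  classes <- sort(unique(trials$stimulus_class))
  miss <- setdiff(classes, names(params_by_class))
  if (length(miss))
    abort(paste0("No parameters supplied for class(es): ",
                 paste(miss, collapse = ", ")))
  per <- purrr::map_dfr(classes, function(cl) {
    tr <- trials[trials$stimulus_class == cl, ]
    if (nrow(tr) == 0) abort(paste0("Empty stimulus class: ", cl))
    x <- sort(signed_rts(tr))
    Fx <- wfpt_signed_cdf(x, params_by_class[[cl]])
    n <- length(x)
    Ti <- max(pmax(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n)))
    tibble(stimulus_class = cl, n = n, statistic = Ti,
           log_p = kolmogorov_log_p(sqrt(n) * Ti))
  })
  list(statistic = max(per$statistic), p = exp(sum(per$log_p)),
       classes = dplyr::mutate(per, p = exp(.data$log_p)))
}

# log of the asymptotic Kolmogorov survival function Q(lambda).
kolmogorov_log_p <- function(lambda) {
  if (!is.finite(lambda) || lambda <= 0) return(0)
  if (lambda < 1) {
    # small-lambda (theta-function) representation
    k <- seq_len(20)
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
    p <- 1 - sqrt(2 * pi) / lambda * s
    return(log(max(min(p, 1), 1e-300)))
  }
  e <- 2 * lambda^2
  if (e > 690) return(log(2) - e)  # one-term asymptotics before underflow
  k <- seq_len(20)
  s <- sum((-1)^(k - 1) * exp(-k^2 * e))
  log(max(min(2 * s, 1), 1e-300))
}

# Objective: minus the sum of per-class log KS p-values.
ks_objective <- function(trials_by_class, signed_by_class, design, classes, s) {
  function(theta) {
    params <- tryCatch(decode_theta(theta, design, classes, s),
                       error = function(e) NULL)
    if (is.null(params)) return(1e10)
    total <- 0
    for (cl in classes) {
      x <- signed_by_class[[cl]]
      Fx <- tryCatch(wfpt_signed_cdf(x, params[[cl]]),
                     error = function(e) NULL)
      if (is.null(Fx) || any(!is.finite(Fx))) return(1e10)
      n <- length(x)
      Ti <- max(pmax(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n)))
      total <- total - kolmogorov_log_p(sqrt(n) * Ti)
    }
    if (!is.finite(total)) 1e10 else total
  }
}

#' Fit diffusion parameters by Kolmogorov-Smirnov minimization
#'
#' Estimates the free parameters of `design` by minimizing the KS distance
#' between empirical and predicted signed-RT distributions (jointly across
#' stimulus classes, as minus the summed log per-class KS p-values), using
#' Nelder-Mead simplex search from EZ-derived starting values with
#' deterministic restarts. The fitted model is screened as misfitting when
#' its overall KS p-value is at or below `alpha`.
#'
#' @param trials A tibble with columns `stimulus_class`, `response`, `rt`
#'   (trimmed of outliers and censored trials).
#' @param design A [fit_design()] specifying free and fixed parameters.
#' @param s Diffusion constant of the reported estimates (default 0.1).
#' @param init Optional named list of starting values (as
#'   [starting_values()] would produce); defaults to EZ-derived starts.
#' @param n_starts Number of deterministic simplex starts (default 3).
#' @param alpha Screening level for the goodness-of-fit p-value.
#' @param maxit,reltol Simplex iteration cap and convergence tolerance on the
#'   objective.
#' @return A `ddm_fit` object; see [tidy.ddm_fit()].
#' @examples
#' \donttest{
#' p <- list(old = diffusion_params(v = 0.1, a = 0.14, t0 = 0.4),
#'           new = diffusion_params(v = -0.1, a = 0.14, t0 = 0.4))
#' tr <- simulate_condition(p, c(old = 100, new = 100), seed = 1)
#' ks_fit(tr)
#' }
#' @export
ks_fit <- function(trials, design = fit_design(), s = 0.1, init = NULL,
                   n_starts = 3, alpha = 0.05, maxit = 800, reltol = 1e-6) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  if (nrow(trials) < 2) abort("Too few trials to fit.")
  classes <- sort(unique(trials$stimulus_class))
  start_vals <- init %||% starting_values(trials, classes, s)
  theta0 <- encode_theta(start_vals, design, classes)
  signed_by_class <- lapply(setNames(classes, classes), function(cl)
    sort(signed_rts(trials[trials$stimulus_class == cl, ])))
  obj <- ks_objective(NULL, signed_by_class, design, classes, s)
  res <- run_simplex(build_starts(theta0, design, classes, n_starts), obj,
                     maxit = maxit, reltol = reltol)
  params <- decode_theta(res$par, design, classes, s)
  gof <- ks_statistic(trials, params)
  new_ddm_fit(method = "ks", params = params, design = design,
              objective = res$value, statistic = gof$statistic, df = NA_real_,
              p = gof$p, converged = res$converged, n_eval = res$n_eval,
              n = nrow(trials), alpha = alpha, s = s,
              extra = list(class_fit = gof$classes))
}

# Shared FitResult container -------------------------------------------------

new_ddm_fit <- function(method, params, design, objective, statistic, df, p,
                        converged, n_eval, n, alpha, s, extra = list(),
                        estimates = NULL) {
  if (is.null(estimates)) estimates <- params_to_estimates(params)
  structure(
    c(list(method = method, params = params, design = design,
           estimates = estimates, objective = objective,
           statistic = statistic, df = df, p = p, converged = converged,
           n_eval = n_eval, n = n, alpha = alpha, s = s,
           screened = is.finite(p) && p <= alpha),
      extra),
    class = "ddm_fit")
}

# Long tibble of estimates from a per-class parameter list: per-class drifts
# (v_<class>) plus the shared parameters.
params_to_estimates <- function(params) {
  classes <- names(params)
  shared <- params[[1]]
  drift <- tibble(parameter = paste0("v_", classes),
                  estimate = vapply(params, function(p) p$v, numeric(1)))
  if (length(classes) == 1) drift$parameter <- "v"
  rest <- tibble(parameter = c("a", "zr", "t0", "sv", "sz", "st"),
                 estimate = c(shared$a, shared$zr, shared$t0, shared$sv,
                              shared$sz, shared$st))
  dplyr::bind_rows(drift, rest)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> method:", x$method,
      " n:", x$n,
      " converged:", x$converged, "\n")
  if (is.finite(x$statistic))
    cat("  fit statistic:", signif(x$statistic, 4),
        " p:", signif(x$p, 3),
        if (x$screened) " [screened: misfit]" else "", "\n")
  print(as.data.frame(x$estimates), row.names = FALSE)
  invisible(x)
}
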