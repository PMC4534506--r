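# broom-style tidiers for fitted objects and reports.

#' Tidy a fitted diffusion model
#'
#' @param x A `ddm_fit` from [ks_fit()], [chisq_fit()] or [restricted_fit()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter.
#' @exportS3Method generics::tidy
tidy.ddm_fit <- function(x, ...) {
  x$estimates
}

#' One-row fit summary of a fitted diffusion model
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return A tibble with the objective name, fit statistic, p-value,
#'   convergence and screening flags, evaluation count and trial count.
#' @exportS3Method generics::glance
glance.ddm_fit <- function(x, ...) {
  tibble(method = x$method, objective = x$objective,
         statistic = x$statistic, df = x$df, p = x$p,
         converged = x$converged, screened = x$screened,
         n_eval = x$n_eval, n = x$n)
}

#' Tidy a recovery report
#'
#' @param x A `ddm_recovery` from [recovery_experiment()].
#' @param ... Unused.
#' @return The underlying tibble (parameter, truth, recovered summaries).
#' @exportS3Method generics::tidy
tidy.ddm_recovery <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a recovery report
#'
#' @param x A `ddm_recovery`.
#' @param ... Unused.
#' @return A tibble with the estimator, cohort size, screening count, seed
#'   and worst-case absolute bias.
#' @exportS3Method generics::glance
glance.ddm_recovery <- function(x, ...) {
  tibble(method = attr(x, "method"),
         n_participants = attr(x, "n_participants"),
         n_screened = attr(x, "n_screened"),
         all_screened = attr(x, "all_screened"),
         seed = attr(x, "seed"),
         max_abs_bias = max(abs(x$bias)))
}

#' Tidy a validation report
#'
#' @param x A `ddm_validation` from [run_validation()].
#' @param ... Unused.
#' @return The group-inference test table.
#' @exportS3Method generics::tidy
tidy.ddm_validation <- function(x, ...) {
  x$tests
}

#' One-row summary of a validation report
#'
#' @param x A `ddm_validation`.
#' @param ... Unused.
#' @return A tibble with the design, method, targeted parameter, and whether
#'   the target showed the largest standardized effect.
#' @exportS3Method generics::glance
glance.ddm_validation <- function(x, ...) {
  tibble(design_id = x$design_id, method = x$method, target = x$target,
         target_is_largest = x$target_is_largest, seed = x$seed)
}
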