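# EZ estimation: closed-form inversion of accuracy, mean RT and RT variance
# of correct responses into (v, a, t0), under the simplifying assumptions of
# an unbiased start point (zr = 0.5) and no trial-to-trial variability.

#' Summary statistics for EZ estimation
#'
#' Computes proportion correct and the mean and variance of correct-response
#' RTs. "Correct" is defined by the accuracy coding rule: a response is
#' correct when it matches the stimulus class ("old" response to an old item,
#' "new" to a new item).
#'
#' @param trials A tibble with columns `stimulus_class`, `response`, `rt`.
#' @return A one-row tibble with `pc`, `mrt` (s), `vrt` (s^2) and `n`.
#' @examples
#' tr <- tibble::tibble(stimulus_class = c("old", "old", "old"),
#'                      response = c("old", "old", "new"),
#'                      rt = c(0.5, 0.7, 0.6))
#' summarize_for_ez(tr)
#' @export
summarize_for_ez <- function(trials) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  correct <- trials$response == trials$stimulus_class
  rt_c <- trials$rt[correct]
  if (length(rt_c) < 2)
    abort("EZ summaries need at least 2 correct trials (variance undefined).")
  tibble(pc = mean(correct), mrt = mean(rt_c), vrt = var(rt_c),
         n = nrow(trials))
}

#' EZ closed-form parameter estimates
#'
#' Inverts `(pc, mrt, vrt)` into drift rate, boundary separation and
#' non-decision time. With `L = logit(pc)`:
#' \deqn{v = sign(pc - 1/2)\, s\, [L (L pc^2 - L pc + pc - 1/2)/vrt]^{1/4},}
#' \deqn{a = s^2 L / v,} and `t0 = mrt - mdt` where the mean decision time is
#' `mdt = (a / 2v) (1 - e^y)/(1 + e^y)` with `y = -v a / s^2`. The estimates
#' assume an unbiased start point (`zr = 0.5`) and no trial-to-trial
#' variability; the returned parameter set fixes those accordingly.
#'
#' `pc` of exactly 0, 0.5 or 1 leaves the estimates undefined and raises an
#' error by default; `edge_correction = TRUE` instead replaces `pc = 1` by
#' `1 - 1/(2n)` and `pc = 0` by `1/(2n)` (`pc = 0.5` remains undefined).
#'
#' @param stats A one-row tibble from [summarize_for_ez()] (or any list with
#'   `pc`, `mrt`, `vrt`, `n`).
#' @param s Diffusion constant (default 0.1).
#' @param edge_correction Apply the `1/(2n)` correction at `pc` of 0 or 1.
#' @return A [diffusion_params()] object with `zr = 0.5` and zero
#'   variability.
#' @export
ez_fit <- function(stats, s = 0.1, edge_correction = FALSE) {
  pc <- stats$pc; mrt <- stats$mrt; vrt <- stats$vrt
  if (!is.finite(pc) || !is.finite(mrt) || !is.finite(vrt) || vrt <= 0)
    abort("EZ requires finite summaries with positive RT variance.")
  if (pc %in% c(0, 1)) {
    if (!edge_correction)
      abort("EZ estimates are undefined at pc of 0 or 1 (perfect accuracy).")
    n <- stats$n %||% abort("Edge correction needs the trial count `n`.")
    pc <- if (pc == 1) 1 - 1 / (2 * n) else 1 / (2 * n)
  }
  if (pc == 0.5)
    abort("EZ estimates are undefined at pc = 0.5 (zero drift).")
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  t0 <- mrt - mdt
  if (t0 < 0) t0 <- 0
  diffusion_params(v = v, a = a, zr = 0.5, t0 = t0, s = s)
}

# Forward EZ moments for a no-variability, unbiased-start parameter set.
# Used as an independent closed form in tests and for simulator checks.
ez_forward_moments <- function(v, a, t0, s = 0.1) {
  pc <- 1 / (1 + exp(-v * a / s^2))
  mdt <- (a / (2 * v)) * tanh(v * a / (2 * s^2))
  L <- qlogis(pc)
  vrt <- s^4 * L * (L * pc^2 - L * pc + pc - 0.5) / v^4
  tibble(pc = pc, mrt = t0 + mdt, vrt = vrt)
}

check_trial_cols <- function(trials, cols) {
  miss <- setdiff(cols, names(trials))
  if (length(miss))
    abort(paste0("Trial data is missing column(s): ",
                 paste(miss, collapse = ", ")))
  invisible(trials)
}
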