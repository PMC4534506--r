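# Named recovery scenarios keyed to the three synthetic studies: the
# generating truths are the published group-mean estimates of the
# corresponding recognition-memory conditions, with between-participant
# dispersion fixed at zero so that recovery bias is attributable to the
# estimator alone.

#' Ready-made parameter-recovery scenarios
#'
#' Returns the full specification of one standard recovery run: generating
#' truths (group-mean parameters of the corresponding study condition),
#' per-class trial counts, cohort size and estimator. Passing the result to
#' [recovery_experiment()] via `do.call` (plus a seed) reproduces the
#' standard validation runs.
#'
#' Scenario ids: `exp1-old-bias`, `exp1-new-bias` (KS; start-point truths
#' 0.66 / 0.49), `exp2-speed`, `exp2-accuracy` (KS; boundary truths
#' 0.09 / 0.17, non-decision 0.54 / 0.67 s), `exp3-ez-twice`,
#' `exp3-ez-not-presented` (EZ; drift magnitudes 0.13 / 0.19 under EZ's
#' assumptions: unbiased start, no variability).
#'
#' @param id Scenario name, see above.
#' @return A list of arguments for [recovery_experiment()].
#' @examples
#' sc <- recovery_scenario("exp3-ez-twice")
#' rec <- do.call(recovery_experiment, c(sc, list(seed = 1)))
#' @export
recovery_scenario <- function(id = c("exp1-old-bias", "exp1-new-bias",
                                     "exp2-speed", "exp2-accuracy",
                                     "exp3-ez-twice",
                                     "exp3-ez-not-presented")) {
  id <- match.arg(id)
  switch(id,
    "exp1-old-bias" = list(
      truth = list(v = c(old = 0.04, new = -0.14), a = 0.14, zr = 0.66,
                   t0 = 0.60),
      counts = c(old = 140L, new = 70L), n_participants = 30L,
      method = "ks"),
    "exp1-new-bias" = list(
      truth = list(v = c(old = 0.05, new = -0.14), a = 0.13, zr = 0.49,
                   t0 = 0.60),
      counts = c(old = 70L, new = 140L), n_participants = 30L,
      method = "ks"),
    "exp2-speed" = list(
      truth = list(v = c(old = 0.04, new = -0.17), a = 0.09, zr = 0.55,
                   t0 = 0.54),
      counts = c(old = 140L, new = 140L), n_participants = 30L,
      method = "ks"),
    "exp2-accuracy" = list(
      truth = list(v = c(old = 0.05, new = -0.09), a = 0.17, zr = 0.55,
                   t0 = 0.67),
      counts = c(old = 140L, new = 140L), n_participants = 30L,
      method = "ks"),
    "exp3-ez-twice" = list(
      truth = list(v = c(old = 0.13), a = 0.12, zr = 0.5, t0 = 0.55),
      counts = c(old = 90L), n_participants = 26L, method = "ez",
      absolute_v = TRUE),
    "exp3-ez-not-presented" = list(
      truth = list(v = c(new = -0.19), a = 0.12, zr = 0.5, t0 = 0.55),
      counts = c(new = 90L), n_participants = 26L, method = "ez",
      absolute_v = TRUE))
}
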