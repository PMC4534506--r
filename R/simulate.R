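# Seeded trial-level simulator. Trials are drawn by inverse-CDF sampling on a
# cached signed-RT grid built from the first-passage machinery, so simulated
# data converge to the model's predicted distributions by construction.

#' Sample choice-RT trials from a diffusion parameter set
#'
#' Draws `n` trials from the joint (choice, RT) distribution implied by `p`.
#' Without trial-to-trial variability, a signed-RT grid of the predicted CDF
#' is built once and inverted; with variability, each trial first receives its
#' own drift (normal), start point (uniform) and non-decision time (uniform),
#' and the conditional trial is then drawn the same way. RTs include the
#' non-decision time.
#'
#' @param p A [diffusion_params()] object.
#' @param n Number of trials.
#' @param seed Optional integer seed. If supplied, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param n_grid Number of grid points per boundary for CDF inversion.
#' @return A tibble with columns `boundary` (`"upper"`/`"lower"`) and `rt`
#'   (seconds).
#' @examples
#' sample_trials(diffusion_params(v = 0.1, a = 0.14), 5, seed = 1)
#' @export
sample_trials <- function(p, n, seed = NULL, n_grid = 4096) {
  stopifnot(inherits(p, "diffusion_params"))
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive count.")
  n <- as.integer(n)
  draw <- function() {
    if (p$sv == 0 && p$sz == 0 && p$st == 0) {
      sample_trials_fixed(p$v, p$a, p$zr, p$t0, p$s, n, n_grid)
    } else {
      v_i <- rnorm(n, p$v, p$sv)
      zr_i <- p$zr + runif(n, -0.5, 0.5) * (p$sz / p$a)
      t0_i <- p$t0 + runif(n, -0.5, 0.5) * p$st
      out_b <- character(n); out_rt <- numeric(n)
      for (i in seq_len(n)) {
        one <- sample_trials_fixed(v_i[i], p$a, zr_i[i], t0_i[i], p$s,
                                   1L, 256L)
        out_b[i] <- one$boundary; out_rt[i] <- one$rt
      }
      tibble(boundary = out_b, rt = out_rt)
    }
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

# Inverse-CDF sampling for a fixed (no-variability) parameter point.
sample_trials_fixed <- function(v, a, zr, t0, s, n, n_grid) {
  vn <- v / s; an <- a / s; w <- zr
  p_low <- 1 - absorption_upper_norm(vn, an, w)
  tmax <- fpt_horizon(vn, an)
  tg <- seq(0, tmax, length.out = n_grid)
  F_low <- wfpt_cdf_lower_norm(tg, vn, an, w)
  F_up <- wfpt_cdf_lower_norm(tg, -vn, an, 1 - w)
  u <- runif(n)
  lower <- u < p_low
  rt <- numeric(n)
  # invert each boundary's branch separately so no draw can land inside the
  # non-decision window between the branches
  if (any(lower)) {
    Fs <- p_low - rev(F_low); ts <- t0 + rev(tg)
    keep <- !duplicated(Fs)
    rt[lower] <- approx(Fs[keep], ts[keep], xout = u[lower], rule = 2)$y
  }
  if (any(!lower)) {
    Fs <- p_low + F_up; ts <- t0 + tg
    keep <- !duplicated(Fs)
    rt[!lower] <- approx(Fs[keep], ts[keep], xout = u[!lower], rule = 2)$y
  }
  tibble(boundary = ifelse(lower, "lower", "upper"), rt = rt)
}

# Decision-time horizon beyond which the remaining FPT mass is < ~1e-9.
fpt_horizon <- function(vn, an) {
  lam1 <- (vn^2 + pi^2 / an^2) / 2
  min(max(22 / lam1, 2), 60)
}

#' Simulate one condition's test phase
#'
#' Simulates all trials of one condition for one participant: every stimulus
#' class uses its own drift rate while all other parameters are shared.
#' Trials slower than the response deadline are flagged `censored`, not
#' discarded.
#'
#' @param params_by_class Named list of [diffusion_params()] objects, one per
#'   stimulus class (e.g. `list(old = ..., new = ...)`), identical except for
#'   drift.
#' @param counts Named integer vector of trial counts per stimulus class,
#'   names matching `params_by_class`.
#' @param deadline Response deadline in seconds (default 4); `Inf` disables
#'   censoring.
#' @param seed Optional integer seed.
#' @return A tibble with columns `stimulus_class`, `response` (`"old"`/
#'   `"new"`), `rt` (seconds) and `censored` (logical).
#' @export
simulate_condition <- function(params_by_class, counts, deadline = 4,
                               seed = NULL) {
  if (is.null(names(counts)) || !setequal(names(counts), names(params_by_class)))
    abort("`counts` must be named and match `params_by_class`.")
  if (any(counts < 1)) abort("All class counts must be >= 1.")
  run <- function() {
    purrr::map_dfr(names(counts), function(cl) {
      tr <- sample_trials(params_by_class[[cl]], counts[[cl]])
      tibble(stimulus_class = cl,
             response = unname(boundary_to_response(tr$boundary)),
             rt = tr$rt,
             censored = tr$rt >= deadline)
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Ready-made designs for the three synthetic recognition experiments
#'
#' Returns the full specification of one of three synthetic recognition-memory
#' studies: group/condition structure, trial counts per stimulus class, a
#' 4-second response deadline, group-mean diffusion parameters and
#' between-participant standard deviations.
#'
#' * `exp1` - response-bias manipulation: two groups of 30 participants see
#'   140:70 vs 70:140 old:new test items; the start point `zr` differs
#'   (0.66 old-bias vs 0.49 new-bias).
#' * `exp2` - speed-accuracy manipulation: two groups of 30, 140 + 140 trials;
#'   boundary separation (0.09 vs 0.17) and non-decision time (0.54 vs 0.67 s)
#'   differ.
#' * `exp3` - encoding-strength manipulation, within-subject: 28 participants,
#'   90 trials in each of three conditions (not presented / presented once /
#'   presented twice); only the drift rate differs across conditions.
#'
#' Group means follow the printed group-level estimates of the corresponding
#' recognition experiments; parameters those experiments do not report
#' (e.g. `t0` in `exp1`) use documented plausible defaults and can be
#' overridden via `modify`.
#'
#' @param design_id One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param n_per_group Participants per group (default: the study sizes,
#'   30/30/28).
#' @param seed Integer seed stored with the design and used by
#'   [generate_experiment()].
#' @param modify Optional function applied to the design list before return,
#'   for overriding individual entries.
#' @return A list of class `ddm_design`.
#' @export
experiment_design <- function(design_id = c("exp1", "exp2", "exp3"),
                              n_per_group = NULL, seed = 1L, modify = NULL) {
  design_id <- match.arg(design_id)
  d <- switch(design_id,
    exp1 = list(
      design_id = "exp1", type = "between", deadline = 4,
      groups = list(
        old_bias = list(
          n = n_per_group %||% 30L,
          conditions = list(test = list(
            counts = c(old = 140L, new = 70L),
            mean = list(v = c(old = 0.04, new = -0.14), a = 0.14, zr = 0.66,
                        t0 = 0.60, sv = 0, sz = 0, st = 0),
            sd = list(v = c(old = 0.05, new = 0.07), a = 0.02, zr = 0.09,
                      t0 = 0.08)))),
        new_bias = list(
          n = n_per_group %||% 30L,
          conditions = list(test = list(
            counts = c(old = 70L, new = 140L),
            mean = list(v = c(old = 0.05, new = -0.14), a = 0.13, zr = 0.49,
                        t0 = 0.60, sv = 0, sz = 0, st = 0),
            sd = list(v = c(old = 0.08, new = 0.06), a = 0.02, zr = 0.10,
                      t0 = 0.08))))
      )),
    exp2 = list(
      design_id = "exp2", type = "between", deadline = 4,
      groups = list(
        speed = list(
          n = n_per_group %||% 30L,
          conditions = list(test = list(
            counts = c(old = 140L, new = 140L),
            mean = list(v = c(old = 0.04, new = -0.17), a = 0.09, zr = 0.55,
                        t0 = 0.54, sv = 0, sz = 0, st = 0),
            sd = list(v = c(old = 0.08, new = 0.11), a = 0.02, zr = 0.10,
                      t0 = 0.08)))),
        accuracy = list(
          n = n_per_group %||% 30L,
          conditions = list(test = list(
            counts = c(old = 140L, new = 140L),
            mean = list(v = c(old = 0.05, new = -0.09), a = 0.17, zr = 0.55,
                        t0 = 0.67, sv = 0, sz = 0, st = 0),
            sd = list(v = c(old = 0.06, new = 0.08), a = 0.06, zr = 0.10,
                      t0 = 0.12))))
      )),
    exp3 = list(
      design_id = "exp3", type = "within", deadline = 4,
      groups = list(
        within = list(
          n = n_per_group %||% 28L,
          shared_sd = list(a = 0.03, zr = 0.10, t0 = 0.07),
          conditions = list(
            not_presented = list(
              counts = c(new = 90L),
              mean = list(v = c(new = -0.21), a = 0.12, zr = 0.50, t0 = 0.60,
                          sv = 0, sz = 0, st = 0),
              sd = list(v = c(new = 0.09), a = 0.03, zr = 0.10, t0 = 0.07)),
            once = list(
              counts = c(old = 90L),
              mean = list(v = c(old = 0.05), a = 0.12, zr = 0.50, t0 = 0.60,
                          sv = 0, sz = 0, st = 0),
              sd = list(v = c(old = 0.08), a = 0.03, zr = 0.10, t0 = 0.07)),
            twice = list(
              counts = c(old = 90L),
              mean = list(v = c(old = 0.14), a = 0.12, zr = 0.50, t0 = 0.60,
                          sv = 0, sz = 0, st = 0),
              sd = list(v = c(old = 0.12), a = 0.03, zr = 0.10, t0 = 0.07)))
        ))))
  d$seed <- as.integer(seed)
  if (!is.null(modify)) d <- modify(d)
  structure(d, class = "ddm_design")
}

# Draw one participant's true parameters: shared (a, zr, t0) plus a drift per
# condition x class, each Normal(group mean, between-participant SD) truncated
# to the valid region by rejection.
draw_participant_params <- function(group, max_tries = 1000) {
  conds <- group$conditions
  first <- conds[[1]]
  shared_names <- c("a", "zr", "t0")
  for (try in seq_len(max_tries)) {
    shared <- lapply(shared_names, function(nm) {
      m <- first$mean[[nm]]; s_ <- first$sd[[nm]] %||% 0
      if (s_ > 0) rnorm(1, m, s_) else m
    })
    names(shared) <- shared_names
    ok <- shared$a > 0 && shared$zr > 0.02 && shared$zr < 0.98 &&
      shared$t0 > 0.05
    if (ok) break
    if (try == max_tries) abort("Truncation region appears empty for this design.")
  }
  out <- lapply(conds, function(cond) {
    v <- vapply(names(cond$mean$v), function(cl) {
      m <- cond$mean$v[[cl]]; s_ <- (cond$sd$v %||% c())[cl]
      if (!is.na(s_) && !is.null(s_) && s_ > 0) rnorm(1, m, s_) else m
    }, numeric(1))
    base <- cond$mean
    lapply(setNames(names(v), names(v)), function(cl) {
      diffusion_params(v = unname(v[cl]), a = shared$a, zr = shared$zr,
                       t0 = shared$t0, sv = base$sv %||% 0,
                       sz = base$sz %||% 0, st = base$st %||% 0)
    })
  })
  out
}

#' Generate a full synthetic study
#'
#' Simulates every participant of a study design: each participant's true
#' parameters are drawn from Normal(group mean, between-participant SD),
#' truncated to the valid parameter region, with `a`, `zr`, `t0` shared across
#' conditions and a drift rate per condition and stimulus class. All trials
#' are then simulated per condition. Fully reproducible from the design's
#' seed.
#'
#' @param design A `ddm_design` from [experiment_design()].
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A tibble of trial records (`participant`, `group`, `condition`,
#'   `stimulus_class`, `response`, `rt`, `censored`) with attributes
#'   `design_id` and `seed`.
#' @examples
#' d <- experiment_design("exp1", n_per_group = 2)
#' generate_experiment(d, seed = 7)
#' @export
generate_experiment <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "ddm_design"))
  run <- function() {
    pid <- 0L
    rows <- purrr::map_dfr(names(design$groups), function(gname) {
      g <- design$groups[[gname]]
      purrr::map_dfr(seq_len(g$n), function(i) {
        pid <<- pid + 1L
        truth <- draw_participant_params(g)
        purrr::map_dfr(names(g$conditions), function(cname) {
          cond <- g$conditions[[cname]]
          sim <- simulate_condition(truth[[cname]], cond$counts,
                                    deadline = design$deadline)
          dplyr::mutate(sim,
                        participant = sprintf("p%03d", pid),
                        group = gname, condition = cname,
                        .before = 1)
        })
      })
    })
    rows
  }
  out <- withr::with_seed(as.integer(seed), run())
  attr(out, "design_id") <- design$design_id
  attr(out, "seed") <- as.integer(seed)
  out
}
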