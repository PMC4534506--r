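# Quantile-bin chi-square estimation: observed RTs of each response type are
# binned at the 0.1/0.3/0.5/0.7/0.9 quantiles (six bins per response, twelve
# per stimulus class) and Pearson's X^2 between observed and model-expected
# bin counts is minimized.

CHISQ_PROBS <- c(0.1, 0.3, 0.5, 0.7, 0.9)

# Bin table for one stimulus class: observed counts and model-expected counts
# per response type, with adjacent bins collapsed until every expected count
# is at least 1 (keeps X^2 defined for participants with very few errors).
class_bin_table <- function(tr, params, probs = CHISQ_PROBS) {
  n_class <- nrow(tr)
  purrr::map_dfr(c("old", "new"), function(resp) {
    rts <- tr$rt[tr$response == resp]
    edges <- if (length(rts) >= 2) unique(quantile(rts, probs, names = FALSE))
             else numeric(0)
    lo <- c(0, edges); hi <- c(edges, Inf)
    obs <- vapply(seq_along(lo), function(i)
      sum(rts > lo[i] & rts <= hi[i]) + (i == 1) * sum(rts <= lo[1]),
      numeric(1))
    # expected mass from the signed-axis CDF
    if (resp == "old") {
      Fhi <- wfpt_signed_cdf(hi, params); Flo <- wfpt_signed_cdf(lo, params)
      ex <- (Fhi - Flo) * n_class
    } else {
      Fhi <- wfpt_signed_cdf(-lo, params); Flo <- wfpt_signed_cdf(-hi, params)
      ex <- (Fhi - Flo) * n_class
    }
    tb <- tibble(response = resp, observed = obs, expected = pmax(ex, 0))
    collapse_bins(tb)
  })
}

# Merge each sparse bin (expected < 1) into its neighbour, right-to-left.
collapse_bins <- function(tb, min_expected = 1) {
  while (nrow(tb) > 1 && any(tb$expected < min_expected)) {
    i <- which(tb$expected < min_expected)[1]
    j <- if (i == nrow(tb)) i - 1L else i + 1L
    tb$observed[j] <- tb$observed[j] + tb$observed[i]
    tb$expected[j] <- tb$expected[j] + tb$expected[i]
    tb <- tb[-i, ]
  }
  tb
}

#' Chi-square fit statistic for a candidate parameter set
#'
#' Pearson's `X^2 = sum (O - E)^2 / E` over quantile-based RT bins of both
#' response types in every stimulus class (six bins per response at the
#' 0.1/0.3/0.5/0.7/0.9 observed-RT quantiles; sparse bins with expected count
#' below 1 are collapsed into a neighbour). Degrees of freedom are the number
#' of bins minus one constraint per stimulus class (bin counts sum to the
#' class total) minus the number of free parameters.
#'
#' @inheritParams ks_statistic
#' @param n_free Number of free parameters used when computing `df`.
#' @return A list with `statistic`, `df`, `p` and the bin table `bins`.
#' @export
chisq_statistic <- function(trials, params_by_class, n_free = 0) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  classes <- sort(unique(trials$stimulus_class))
  bins <- purrr::map_dfr(classes, function(cl) {
    tr <- trials[trials$stimulus_class == cl, ]
    if (nrow(tr) == 0) abort(paste0("Empty stimulus class: ", cl))
    dplyr::mutate(class_bin_table(tr, params_by_class[[cl]]),
                  stimulus_class = cl, .before = 1)
  })
  if (any(bins$expected <= 0))
    abort("Zero expected count in a non-collapsible bin.")
  x2 <- sum((bins$observed - bins$expected)^2 / bins$expected)
  df <- max(nrow(bins) - length(classes) - n_free, 1)
  list(statistic = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE),
       bins = bins)
}

# Precomputed bin structure for one class: per response, the signed-axis bin
# edges (from observed quantiles) and observed counts. Edges are data-driven
# and never change during optimization.
class_bin_spec <- function(tr, probs = CHISQ_PROBS) {
  n_class <- nrow(tr)
  lapply(setNames(c("old", "new"), c("old", "new")), function(resp) {
    rts <- tr$rt[tr$response == resp]
    edges <- if (length(rts) >= 2) unique(quantile(rts, probs, names = FALSE))
             else numeric(0)
    lo <- c(0, edges); hi <- c(edges, Inf)
    obs <- vapply(seq_along(lo), function(i) sum(rts > lo[i] & rts <= hi[i]),
                  numeric(1))
    # signed-axis evaluation points: old responses positive, new negated
    pts <- if (resp == "old") c(lo, Inf) else -c(lo, Inf)
    list(obs = obs, pts = pts, n_class = n_class, sign = if (resp == "old") 1 else -1)
  })
}

# Expected counts for one response's bin spec under candidate params.
spec_expected <- function(spec, params) {
  Fv <- wfpt_signed_cdf(spec$pts, params)
  k <- length(spec$obs)
  if (spec$sign > 0) {
    ex <- Fv[c(2:k, k + 1)] - Fv[1:k]
  } else {
    ex <- Fv[1:k] - Fv[c(2:k, k + 1)]
  }
  ex * spec$n_class
}

# During optimization, expected counts are floored (not collapsed): a model
# that puts no mass where data sit is penalized, never rewarded.
chisq_objective <- function(bin_specs, design, classes, s) {
  function(theta) {
    params <- tryCatch(decode_theta(theta, design, classes, s),
                       error = function(e) NULL)
    if (is.null(params)) return(1e10)
    total <- 0
    for (cl in classes) {
      for (spec in bin_specs[[cl]]) {
        ex <- tryCatch(spec_expected(spec, params[[cl]]),
                       error = function(e) NULL)
        if (is.null(ex) || any(!is.finite(ex))) return(1e10)
        ex <- pmax(ex, 1e-10)
        total <- total + sum((spec$obs - ex)^2 / ex)
      }
    }
    if (!is.finite(total)) 1e10 else total
  }
}

#' Fit diffusion parameters by chi-square minimization
#'
#' Estimates the free parameters of `design` by minimizing the quantile-bin
#' `X^2` of [chisq_statistic()] via Nelder-Mead from EZ-derived starting
#' values. A warning (not an error) is emitted when any response type in a
#' stimulus class has fewer than 11 trials, where observed quantile edges
#' become unstable -- typical for near-perfect participants. Screening uses
#' the chi-square goodness-of-fit p-value at level `alpha`.
#'
#' @inheritParams ks_fit
#' @return A `ddm_fit` object.
#' @export
chisq_fit <- function(trials, design = fit_design(), s = 0.1, init = NULL,
                      n_starts = 3, alpha = 0.05, maxit = 800,
                      reltol = 1e-6) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  classes <- sort(unique(trials$stimulus_class))
  counts <- dplyr::count(trials, .data$stimulus_class, .data$response)
  full <- tidyr::complete(counts, stimulus_class = classes,
                          response = c("old", "new"),
                          fill = list(n = 0L))
  if (any(full$n < 11))
    warn("Fewer than 11 trials for some response type; quantile bin edges may be unstable.")
  start_vals <- init %||% starting_values(trials, classes, s)
  theta0 <- encode_theta(start_vals, design, classes)
  bin_specs <- lapply(setNames(classes, classes), function(cl)
    class_bin_spec(trials[trials$stimulus_class == cl, ]))
  obj <- chisq_objective(bin_specs, design, classes, s)
  res <- run_simplex(build_starts(theta0, design, classes, n_starts), obj,
                     maxit = maxit, reltol = reltol)
  params <- decode_theta(res$par, design, classes, s)
  n_free <- length(theta_names(design, classes))
  gof <- chisq_statistic(trials, params, n_free = n_free)
  new_ddm_fit(method = "chisq", params = params, design = design,
              objective = res$value, statistic = gof$statistic, df = gof$df,
              p = gof$p, converged = res$converged, n_eval = res$n_eval,
              n = nrow(trials), alpha = alpha, s = s,
              extra = list(bins = gof$bins))
}
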