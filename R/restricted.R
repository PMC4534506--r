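# Restricted multi-condition models: all diffusion parameters shared across
# conditions except one, which varies freely per condition. Used to ask which
# single parameter best explains a within-subject manipulation.

#' Fit a restricted multi-condition model
#'
#' Fits all of a participant's conditions jointly with every parameter
#' (`v`, `a`, `zr`, `t0`; variability fixed at zero) shared across
#' conditions, except `free_param`, which receives one value per condition.
#' With the KS back-end the objective is minus the summed log per-condition
#' KS p-values (overall statistic: maximum `T`; overall p: product); with the
#' chi-square back-end it is the summed `X^2`.
#'
#' @param trials A tibble with columns `condition`, `stimulus_class`,
#'   `response`, `rt`, covering at least two conditions.
#' @param free_param One of `"v"`, `"a"`, `"zr"`, `"t0"`.
#' @param method `"ks"` or `"chisq"`.
#' @inheritParams ks_fit
#' @return A `ddm_fit` with one estimate per condition for `free_param` and
#'   shared estimates for the rest.
#' @export
restricted_fit <- function(trials, free_param = c("v", "a", "zr", "t0"),
                           method = c("ks", "chisq"), s = 0.1, n_starts = 3,
                           alpha = 0.05, maxit = 1000, reltol = 1e-6) {
  free_param <- match.arg(free_param)
  method <- match.arg(method)
  check_trial_cols(trials, c("condition", "stimulus_class", "response", "rt"))
  conds <- unique(trials$condition)
  if (length(conds) < 2) abort("Restricted fits need at least two conditions.")
  trials_by_cond <- lapply(setNames(conds, conds), function(cn)
    trials[trials$condition == cn, ])
  shared_names <- setdiff(c("v", "a", "zr", "t0"), free_param)

  # theta layout: shared params first (transformed), then one free_param
  # value per condition.
  sv0 <- starting_values(trials, classes = "all", s = s)
  enc1 <- function(nm, val) switch(nm, v = val, a = log(val),
                                   zr = qlogis(val), t0 = log(max(val, 1e-3)))
  dec1 <- function(nm, x) switch(nm, v = x, a = exp(x), zr = plogis(x),
                                 t0 = exp(x))
  start_shared <- vapply(shared_names, function(nm)
    enc1(nm, switch(nm, v = unname(sv0$v[1]), a = sv0$a, zr = 0.5,
                    t0 = sv0$t0)), numeric(1))
  start_free <- vapply(conds, function(cn) {
    val <- switch(free_param, v = {
      cls <- trials_by_cond[[cn]]$stimulus_class[1]
      if (cls == "new") -abs(sv0$v[1]) else abs(sv0$v[1])
    }, a = sv0$a, zr = 0.5, t0 = sv0$t0)
    enc1(free_param, val)
  }, numeric(1))
  theta0 <- c(start_shared, start_free)

  decode <- function(theta) {
    shared <- lapply(setNames(seq_along(shared_names), shared_names),
                     function(i) dec1(shared_names[i], theta[i]))
    free_vals <- vapply(seq_along(conds), function(j)
      dec1(free_param, theta[length(shared_names) + j]), numeric(1))
    lapply(setNames(seq_along(conds), conds), function(j) {
      vals <- shared
      vals[[free_param]] <- free_vals[j]
      diffusion_params(v = vals$v, a = vals$a, zr = vals$zr, t0 = vals$t0,
                       s = s)
    })
  }

  signed_by_cond <- lapply(trials_by_cond, function(tr) sort(signed_rts(tr)))
  specs_by_cond <- lapply(trials_by_cond, class_bin_spec)
  objective <- function(theta) {
    params <- tryCatch(decode(theta), error = function(e) NULL)
    if (is.null(params)) return(1e10)
    total <- 0
    for (cn in conds) {
      if (method == "ks") {
        x <- signed_by_cond[[cn]]
        Fx <- tryCatch(wfpt_signed_cdf(x, params[[cn]]),
                       error = function(e) NULL)
        if (is.null(Fx) || any(!is.finite(Fx))) return(1e10)
        n <- length(x)
        Ti <- max(pmax(abs(Fx - (seq_len(n) - 1) / n),
                       abs(Fx - seq_len(n) / n)))
        total <- total - kolmogorov_log_p(sqrt(n) * Ti)
      } else {
        for (spec in specs_by_cond[[cn]]) {
          ex <- tryCatch(spec_expected(spec, params[[cn]]),
                         error = function(e) NULL)
          if (is.null(ex) || any(!is.finite(ex))) return(1e10)
          ex <- pmax(ex, 1e-10)
          total <- total + sum((spec$obs - ex)^2 / ex)
        }
      }
    }
    if (!is.finite(total)) 1e10 else total
  }

  starts <- list(theta0, theta0 + 0.25, theta0 - 0.2)[seq_len(max(1L, n_starts))]
  res <- run_simplex(starts, objective, maxit = maxit, reltol = reltol)
  params <- decode(res$par)
  n_free <- length(theta0)
  if (method == "ks") {
    per <- purrr::map_dfr(conds, function(cn) {
      tr <- trials_by_cond[[cn]]
      g <- ks_statistic(tr, setNames(list(params[[cn]]),
                                     tr$stimulus_class[1]))
      tibble(condition = cn, statistic = g$statistic, p = g$p)
    })
    statistic <- max(per$statistic); p <- prod(per$p); df <- NA_real_
  } else {
    per <- purrr::map_dfr(conds, function(cn) {
      tr <- trials_by_cond[[cn]]
      g <- chisq_statistic(tr, setNames(list(params[[cn]]),
                                        tr$stimulus_class[1]), n_free = 0)
      tibble(condition = cn, statistic = g$statistic, df = g$df, p = g$p)
    })
    statistic <- sum(per$statistic)
    df <- max(sum(per$df) - n_free + 0, 1)
    p <- pchisq(statistic, df, lower.tail = FALSE)
  }
  estimates <- dplyr::bind_rows(
    tibble(parameter = free_param, condition = conds,
           estimate = vapply(params, function(pp) pp[[free_param]],
                             numeric(1))),
    purrr::map_dfr(shared_names, function(nm)
      tibble(parameter = nm, condition = "shared",
             estimate = params[[1]][[nm]])))
  new_ddm_fit(method = paste0("restricted_", method), params = params,
              design = NULL, objective = res$value, statistic = statistic,
              df = df, p = p, converged = res$converged, n_eval = res$n_eval,
              n = nrow(trials), alpha = alpha, s = s,
              estimates = estimates,
              extra = list(free_param = free_param, per_condition = per))
}
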