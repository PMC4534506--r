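# ggplot2 visualization helpers.

#' Plot a fitted model against the empirical signed-RT distribution
#'
#' Overlays the empirical CDF of signed RTs (lower-boundary responses
#' negated) with the fitted model's predicted signed CDF, per stimulus class.
#'
#' @param object A `ddm_fit` from [ks_fit()] or [chisq_fit()].
#' @param trials The trial tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ddm_fit <- function(object, trials, ...) {
  check_trial_cols(trials, c("stimulus_class", "response", "rt"))
  classes <- names(object$params)
  emp <- purrr::map_dfr(classes, function(cl) {
    x <- sort(signed_rts(trials[trials$stimulus_class == cl, ]))
    tibble(stimulus_class = cl, q = x, cdf = seq_along(x) / length(x),
           which = "empirical")
  })
  grid <- purrr::map_dfr(classes, function(cl) {
    q <- seq(min(emp$q) - 0.2, max(emp$q) + 0.2, length.out = 301)
    tibble(stimulus_class = cl, q = q,
           cdf = wfpt_signed_cdf(q, object$params[[cl]]), which = "model")
  })
  ggplot2::ggplot(dplyr::bind_rows(emp, grid),
                  ggplot2::aes(.data$q, .data$cdf, colour = .data$which)) +
    ggplot2::geom_step(data = function(d) d[d$which == "empirical", ]) +
    ggplot2::geom_line(data = function(d) d[d$which == "model", ]) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus_class)) +
    ggplot2::labs(x = "signed RT (s; new responses negative)",
                  y = "cumulative probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery report
#'
#' Recovered group means (with +/- 1 SD error bars) against the generating
#' truths, one facet row.
#'
#' @param object A `ddm_recovery` from [recovery_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ddm_recovery <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$mean_recovered)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_recovered - .data$sd_recovered,
                   ymax = .data$mean_recovered + .data$sd_recovered),
      width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$truth), colour = "red",
                        shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "recovered (bars) vs truth (x)") +
    ggplot2::theme_minimal()
}

#' Bar plot of group-mean parameter estimates
#'
#' Mirrors the conventional summary figure of diffusion-model studies: mean
#' parameter estimate per group or condition with SD error bars.
#'
#' @param estimates Tidy estimates from [fit_study()].
#' @param by Grouping column, `"group"` or `"condition"`.
#' @return A ggplot object.
#' @export
plot_group_estimates <- function(estimates, by = "group") {
  d <- estimates |>
    dplyr::filter(!.data$screened, is.na(.data$error)) |>
    dplyr::group_by(.data$parameter, .data[[by]]) |>
    dplyr::summarise(m = mean(.data$estimate), s = sd(.data$estimate),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$m,
                                  fill = .data[[by]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$s, ymax = .data$m + .data$s),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean estimate (error bars: SD)") +
    ggplot2::theme_minimal()
}
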