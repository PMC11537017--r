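#' Funnel plot of per-instrument estimates
#'
#' Precision (`1 / ratio_se`) against the per-instrument Wald ratio, with
#' a reference line at the IVW estimate; asymmetry suggests directional
#' pleiotropy.
#'
#' @param h A `harmonized_set` (or a funnel tibble from [funnel_data()]).
#' @return A ggplot object.
#' @export
plot_funnel <- function(h) {
  dat <- if (inherits(h, "harmonized_set")) funnel_data(h) else as_tibble(h)
  ref <- if (inherits(h, "harmonized_set")) mr_ivw(h)$beta else
    weighted.mean(dat$ratio, dat$precision^2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = "Wald ratio (per-instrument causal estimate)",
                  y = "Precision (1 / SE)") +
    ggplot2::theme_minimal()
}

#' Forest plot of estimator results
#'
#' Odds ratios with 95% confidence intervals for each estimator, as
#' produced by [mr_estimate()] or stored in an `mr_report`.
#'
#' @param estimates A tidy estimates tibble (or an `mr_report`).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates) {
  dat <- if (inherits(estimates, "mr_report")) estimates$estimates else
    as_tibble(estimates)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or.conf.low, xmax = .data$or.conf.high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out influence plot
#'
#' Re-estimated IVW effect (with 95% CI) after omitting each instrument,
#' against the all-instrument estimate.
#'
#' @param loo A `loo_result` from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  dat <- as_tibble(loo)
  z <- z_crit()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$variant_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - z * .data$std.error,
                   xmax = .data$estimate + z * .data$std.error),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = attr(loo, "full_beta"),
                        linetype = "dashed") +
    ggplot2::labs(x = "IVW estimate omitting the variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot harmonized_set
#' @export
autoplot.harmonized_set <- function(object, ...) plot_funnel(object)

#' @method autoplot loo_result
#' @export
autoplot.loo_result <- function(object, ...) plot_leave_one_out(object)

#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, ...) plot_forest(object)
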