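#' Scatter plots of brain outcomes vs gestational age with growth fits
#'
#' One facet per outcome, points colored by cohort, with the per-cohort
#' [growth_fit()] curve overlaid (exponential for volumes, linear for folding
#' features) - the curves are drawn from the same fit the tables report.
#'
#' @param data Scan table with `ga_mri_weeks` and `cohort` (0/1).
#' @param outcomes Outcome column names to facet over.
#' @param form "exponential" or "linear".
#' @return A ggplot object.
#' @export
plot_growth <- function(data, outcomes, form = c("exponential", "linear")) {
  form <- match.arg(form)
  long <- tidyr::pivot_longer(
    data[, c("ga_mri_weeks", "cohort", intersect(outcomes, names(data)))],
    cols = -c("ga_mri_weeks", "cohort"),
    names_to = "outcome", values_to = "value"
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  long$cohort_lab <- factor(long$cohort, levels = c(0, 1),
                            labels = c("pre-pandemic", "pandemic"))

  curves <- dplyr::group_modify(
    dplyr::group_by(long, .data$outcome, .data$cohort_lab),
    function(df, key) {
      if (nrow(df) < 3) return(tibble::tibble())
      fit <- growth_fit(df$ga_mri_weeks, df$value, form = form)
      ga <- seq(min(df$ga_mri_weeks), max(df$ga_mri_weeks), length.out = 80)
      tibble::tibble(ga_mri_weeks = ga, value = fit$fitted(ga))
    }
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ga_mri_weeks, y = .data$value,
                                     color = .data$cohort_lab)) +
    ggplot2::geom_point(alpha = 0.45, size = 0.8) +
    ggplot2::geom_line(data = dplyr::ungroup(curves), linewidth = 0.8) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "gestational age at MRI (weeks)", color = "cohort") +
    ggplot2::theme_minimal()
}

#' Forest plot of a fitted model battery
#'
#' Coefficient of interest with a robust 95% Wald interval per outcome,
#' FDR-passing models highlighted.
#'
#' @param object A [run_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gee_battery <- function(object, ...) {
  df <- object[!is.na(object$estimate), , drop = FALSE]
  df$lo <- df$estimate - 1.96 * df$std.error
  df$hi <- df$estimate + 1.96 * df$std.error
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                   color = .data$sig_q)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::facet_wrap(~stratum + rhs, scales = "free_x") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                name = "q < 0.05") +
    ggplot2::labs(x = "cohort coefficient (robust 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a growth fit over its data
#'
#' @param object A [growth_fit()].
#' @param ga,y The data the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, ga, y, ...) {
  gg <- seq(min(ga), max(ga), length.out = 100)
  ggplot2::ggplot(tibble::tibble(ga = ga, y = y), ggplot2::aes(.data$ga, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = tibble::tibble(ga = gg, y = object$fitted(gg)),
                       color = "steelblue", linewidth = 0.9) +
    ggplot2::labs(x = "gestational age (weeks)", y = "outcome") +
    ggplot2::theme_minimal()
}
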