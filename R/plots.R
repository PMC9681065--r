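#' Plot the lnRR inflation curve
#'
#' Effect-size magnitude against the (log-scaled) control value, one line
#' per treatment mean: the visual form of the argument that replacement
#' constants below 1 on a percentage scale explode |lnRR|.
#'
#' @param curve A tibble from [inflation_curve()].
#' @return A ggplot object.
#' @export
plot_inflation_curve <- function(curve) {
  stopifnot(all(c("treatment", "control", "lnrr") %in% names(curve)))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$control, y = .data$lnrr,
                                      colour = factor(.data$treatment))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Control value (%) used in the denominator",
                  y = "lnRR = ln(treatment / control)",
                  colour = "Treatment (%)") +
    ggplot2::theme_minimal()
}

#' Plot yearly variance-weighted mean effect sizes
#'
#' @param yearly A tibble from [yearly_weighted_means()].
#' @return A ggplot object.
#' @export
plot_yearly_means <- function(yearly) {
  stopifnot(all(c("year", "pooled_mean", "ci_low", "ci_high") %in% names(yearly)))
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$pooled_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Publication year", y = "Pooled effect size (lnRR)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lnrr_trend <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8,
                       colour = "#2166ac") +
    ggplot2::geom_point(
      data = object$yearly,
      ggplot2::aes(x = .data$year, y = .data$pooled_mean),
      inherit.aes = FALSE, colour = "grey30"
    ) +
    ggplot2::labs(x = "Publication year",
                  y = sprintf("Effect size (%s lnRR)", object$params$response)) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$curve$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, fill = "#2166ac"
    )
  }
  p
}

#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  yearly <- purrr::imap_dfr(object$cells, function(cell, nm) {
    if (is.null(cell$yearly)) return(NULL)
    d <- cell$yearly
    d$cell <- nm
    d$policy <- cell$policy
    d$ruleset <- cell$ruleset
    d
  })
  if (!nrow(yearly)) abort("All grid cells are degenerate; nothing to plot.")
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$pooled_mean,
                                       colour = .data$policy)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5),
                             size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ruleset)) +
    ggplot2::labs(x = "Publication year", y = "Pooled effect size (lnRR)",
                  colour = "Replacement policy") +
    ggplot2::theme_minimal()
}
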