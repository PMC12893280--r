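#' Plot a trend posterior
#'
#' Density of the per-draw trend with median and 50/80/95% interval bars,
#' on the log or percent-per-year scale.
#'
#' @param object A `trend_posterior`.
#' @param scale `"log"` (default) or `"percent"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_posterior
#' @export
autoplot.trend_posterior <- function(object, scale = c("log", "percent"),
                                     ...) {
  scale <- match.arg(scale)
  x <- if (scale == "percent") 100 * (exp(object$draws) - 1) else
    object$draws
  s <- trend_intervals(x)
  df <- tibble::tibble(trend = x)
  xlab <- if (scale == "percent") "trend (% per year)" else
    expression(Delta * log(abundance) / Delta * year)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trend)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::annotate("segment", x = s["lower_95"], xend = s["upper_95"],
                      y = 0, yend = 0, linewidth = 0.5) +
    ggplot2::annotate("segment", x = s["lower_80"], xend = s["upper_80"],
                      y = 0, yend = 0, linewidth = 1.2) +
    ggplot2::annotate("segment", x = s["lower_50"], xend = s["upper_50"],
                      y = 0, yend = 0, linewidth = 2.2) +
    ggplot2::annotate("point", x = s["median"], y = 0, size = 2.5) +
    ggplot2::labs(x = xlab, y = "posterior density",
                  title = object$context) +
    ggplot2::theme_minimal()
}

#' Plot interaction verdicts
#'
#' Median and credible interval of each interaction's differenced trend
#' posterior (interactive minus additive), coloured by verdict.
#'
#' @param object Tibble from [classify_all_interactions()] (or a single
#'   verdict).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_verdict
#' @export
autoplot.interaction_verdict <- function(object, ...) {
  plot_verdicts(object)
}

#' @rdname autoplot.interaction_verdict
#' @param verdicts Verdict tibble.
#' @export
plot_verdicts <- function(verdicts) {
  pal <- c(additive = "#5e4fa2", antagonistic = "#f46d43",
           synergistic = "#9e0142")
  ggplot2::ggplot(verdicts,
                  ggplot2::aes(x = .data$median,
                               y = stats::reorder(.data$combo,
                                                  .data$median),
                               colour = .data$verdict)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "interactive - additive trend", y = NULL,
                  colour = "verdict") +
    ggplot2::theme_minimal()
}

#' Plot a counterfactual scenario grid
#'
#' Box plots of the pooled population-trend distribution under each
#' removal scenario, with the baseline median as a dashed reference.
#'
#' @param object A `counterfactual_grid` from [scenario_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot counterfactual_grid
#' @export
autoplot.counterfactual_grid <- function(object, ...) {
  scen <- attr(object, "scenarios")
  df <- dplyr::bind_rows(purrr::map2(scen, object$removal_set,
    function(s, lbl) {
      tibble::tibble(removal = lbl, trend = s$counterfactual)
    }))
  baseline <- scen[[1]]$baseline_summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trend,
                                   y = stats::reorder(.data$removal,
                                                      .data$trend,
                                                      FUN = median))) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = baseline, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.6) +
    ggplot2::labs(x = "predicted population trend (log scale)",
                  y = "threat(s) removed") +
    ggplot2::theme_minimal()
}

#' Caterpillar plot of threat year-slope coefficients
#'
#' @param fit An `mtfit`.
#' @param conf_level Interval level, default 0.90.
#' @return A ggplot object.
#' @export
plot_threat_effects <- function(fit, conf_level = 0.90) {
  td <- tidy(fit, pars = "^beta\\[.*:year\\]|^beta\\[year\\]",
             conf_level = conf_level, diagnostics = FALSE)
  td$term <- sub("^beta\\[(.*)\\]$", "\\1", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "year-slope coefficient (log abundance per year)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
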