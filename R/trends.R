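#' Predicted log abundance for a threat context
#'
#' Per-draw conditional predictions of (centred) log abundance over a year
#' grid for a population exposed to a given threat set, using the fitted
#' fixed effects and optionally random-effect identities.
#'
#' @param fit An `mtfit`.
#' @param threats Character vector of threat categories (possibly empty).
#' @param years Year grid (centred internally); default a unit-spaced grid
#'   of 25 years.
#' @param include_random `"none"` (default, conditional predictions with
#'   random effects set to zero) or a named list
#'   `list(species=, population=, site=)` of identities whose fitted random
#'   slopes are added.
#' @param design Optional design template carrying toggle state (defaults
#'   to the fit's design).
#' @param ndraws Optional number of (evenly subsampled) posterior draws.
#' @return Matrix of predictions, draws x years, with the (centred) year
#'   grid in attribute `"years"`.
#' @export
predict_log_abundance <- function(fit, threats = character(0),
                                  years = NULL, include_random = "none",
                                  design = NULL, ndraws = NULL) {
  if (length(threats) > 0) assert_threats(threats)
  years <- years %||% seq(-12, 12)
  template <- design %||% fit$design
  cd <- context_design(template, threats, years)
  B <- beta_draws(fit)[draw_subsample(fit, ndraws), , drop = FALSE]
  pred <- B %*% t(cd$matrix)
  if (!identical(include_random, "none")) {
    if (!is.list(include_random)) {
      abort("include_random must be \"none\" or a list of identities")
    }
    cy <- cd$centered_year
    slope <- slope_random_part(fit, include_random)
    slope <- slope[draw_subsample(fit, ndraws)]
    pred <- pred + outer(slope, cy)
  }
  attr(pred, "years") <- years
  pred
}

# per-draw random slope contribution for a set of identities
slope_random_part <- function(fit, ids) {
  md <- fit$model_data
  total <- 0
  if (!is.null(ids$species)) {
    i <- match(ids$species, md$species_levels)
    if (anyNA(i)) abort(sprintf("unknown species: %s", ids$species))
    total <- total + random_slope_draws(fit, "species")[, i]
  }
  if (!is.null(ids$population)) {
    i <- match(ids$population, md$population_levels)
    if (anyNA(i)) abort(sprintf("unknown population: %s", ids$population))
    total <- total + random_slope_draws(fit, "population")[, i]
  }
  if (!is.null(ids$site)) {
    i <- match(ids$site, md$site_levels)
    if (anyNA(i)) abort(sprintf("unknown site: %s", ids$site))
    total <- total + random_slope_draws(fit, "site")[, i]
  }
  if (identical(total, 0)) total <- numeric(nrow(draw_matrix(fit)))
  total
}

#' Trend as the mean derivative of predicted log abundance
#'
#' Per draw, the unweighted mean of successive difference quotients
#' `(x[t] - x[t-1]) / (year[t] - year[t-1])` over the year grid — the
#' "mean derivative" trend estimand. For noiseless linear series this is
#' exactly the slope.
#'
#' @param predicted Draws-by-years matrix (e.g. from
#'   [predict_log_abundance()]) or a numeric vector for a single draw.
#' @param years Strictly increasing year grid (defaults to the matrix's
#'   `"years"` attribute).
#' @param context Label describing the threat combination / scenario.
#' @return A `trend_posterior` object: per-draw trend in
#'   `Delta log(abundance) / Delta year`, with percent-per-year transform
#'   available via [to_percent_per_year()] and summaries via [tidy()].
#' @export
trend_derivative <- function(predicted, years = NULL, context = "trend") {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  years <- years %||% attr(predicted, "years")
  if (is.null(years)) abort("`years` must be supplied")
  if (length(years) < 2) abort("at least two years are required")
  if (any(diff(years) <= 0)) {
    abort("years must be strictly increasing (no duplicates)")
  }
  dy <- diff(years)
  slopes <- t(apply(predicted, 1, function(x) diff(x) / dy))
  if (length(dy) == 1) slopes <- matrix(slopes, ncol = 1)
  new_trend_posterior(rowMeans(slopes), context)
}

new_trend_posterior <- function(draws, context = "trend") {
  structure(list(draws = as.numeric(draws), context = context),
            class = "trend_posterior")
}

#' Convert a log-scale trend to percent per year
#'
#' `100 * (exp(trend) - 1)`, the multiplicative-change scale a log-linear
#' model implies. A linear approximation (`100 * trend`) is available via
#' `method = "linear"`.
#'
#' @param trend A `trend_posterior` or numeric vector of log-scale trends.
#' @param method `"exponential"` (default) or `"linear"`.
#' @return Same shape as the input, on the percent scale.
#' @export
to_percent_per_year <- function(trend, method = c("exponential", "linear")) {
  method <- match.arg(method)
  x <- if (inherits(trend, "trend_posterior")) trend$draws else trend
  if (any(!is.finite(x))) abort("non-finite trend values")
  out <- switch(method, exponential = 100 * (exp(x) - 1),
                linear = 100 * x)
  if (inherits(trend, "trend_posterior")) {
    new_trend_posterior(out, paste0(trend$context, " (%/yr)"))
  } else {
    out
  }
}

#' Trend posterior for a threat combination
#'
#' Convenience wrapper: conditional predictions for the given threat set on
#' a unit-spaced year grid, converted to a trend posterior via the mean
#' derivative. `interactions = "off"` turns off all interaction columns
#' among the given threats (the additive prediction).
#'
#' @inheritParams predict_log_abundance
#' @param interactions `"on"` (default) or `"off"` (additive null).
#' @return A `trend_posterior`.
#' @export
trend_posterior <- function(fit, threats = character(0),
                            interactions = c("on", "off"),
                            include_random = "none", years = NULL,
                            ndraws = NULL) {
  interactions <- match.arg(interactions)
  template <- fit$design
  if (interactions == "off" && length(threats) >= 2) {
    subs <- enumerate_combinations(list(sort(threats)))
    for (lab in subs[combo_order(subs) >= 2]) {
      if (lab %in% template$labels) {
        template <- switch_interactions(template, lab, "off")
      }
    }
  }
  pred <- predict_log_abundance(fit, threats, years = years,
                                include_random = include_random,
                                design = template, ndraws = ndraws)
  ctx <- if (length(threats)) combo_label(threats) else "none"
  if (interactions == "off" && length(threats) >= 2) {
    ctx <- paste0(ctx, " [additive]")
  }
  trend_derivative(pred, context = ctx)
}

#' Decompose trend contributions into random and threat components
#'
#' Rebuilds the comparison of spatial/temporal random variation against
#' threat fixed effects: a null trend posterior (all threats removed,
#' random effects zero), a random-effect posterior (null threat matrix plus
#' all fitted random identities, averaged across series into a marginal
#' posterior), and a fixed-effect posterior (all threat columns set to 1,
#' conditional). The two difference distributions (random minus null, fixed
#' minus null) measure each component's contribution to trend direction —
#' zero difference means no contribution.
#'
#' @param fit An `mtfit` from [fit_model()].
#' @param ndraws Posterior draws to use (evenly subsampled), default 1000.
#' @return List of class `mt_influence` with `null`, `random`, `fixed`
#'   trend posteriors and `random_contribution`, `fixed_contribution`
#'   difference posteriors. `tidy()` gives a summary table.
#' @export
influence_decomposition <- function(fit, ndraws = 1000) {
  md <- fit$model_data
  rows <- draw_subsample(fit, ndraws)
  B <- beta_draws(fit)[rows, , drop = FALSE]

  # trends are linear in year, so read slopes off the year columns
  null_tr <- B[, "year"]

  # random: null threat matrix + every series' random identities,
  # averaged across series per draw
  if (fit$method == "hmc") {
    rS <- random_slope_draws(fit, "species")[rows, , drop = FALSE]
    rP <- random_slope_draws(fit, "population")[rows, , drop = FALSE]
    rL <- random_slope_draws(fit, "site")[rows, , drop = FALSE]
    meta <- md$pop_meta
    isp <- match(meta$species_id, md$species_levels)
    ipop <- match(meta$population_id, md$population_levels)
    isite <- match(meta$site_id, md$site_levels)
    series_slopes <- null_tr +
      rS[, isp, drop = FALSE] + rP[, ipop, drop = FALSE] +
      rL[, isite, drop = FALSE]
    random_tr <- rowMeans(series_slopes)
  } else {
    random_tr <- null_tr
  }

  year_cols <- paste0(md$design$labels, ":year")
  fixed_tr <- null_tr + rowSums(B[, year_cols, drop = FALSE])

  structure(list(
    null = new_trend_posterior(null_tr, "null"),
    random = new_trend_posterior(random_tr, "random"),
    fixed = new_trend_posterior(fixed_tr, "fixed"),
    random_contribution = new_trend_posterior(random_tr - null_tr,
                                              "random - null"),
    fixed_contribution = new_trend_posterior(fixed_tr - null_tr,
                                             "fixed - null")
  ), class = "mt_influence")
}

trend_intervals <- function(draws, levels = c(0.5, 0.8, 0.95)) {
  out <- purrr::map(levels, function(l) {
    q <- quantile(draws, c((1 - l) / 2, 1 - (1 - l) / 2), names = FALSE)
    setNames(q, sprintf(c("lower_%d", "upper_%d"), round(100 * l)))
  })
  c(median = median(draws), unlist(out))
}

#' @export
print.trend_posterior <- function(x, ...) {
  s <- trend_intervals(x$draws)
  cat(sprintf("<trend_posterior> %s: median %.4f [80%%: %.4f, %.4f] (%d draws)\n",
              x$context, s["median"], s["lower_80"], s["upper_80"],
              length(x$draws)))
  invisible(x)
}
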