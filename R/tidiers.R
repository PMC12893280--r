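#' Tidy a fitted threat-trend model
#'
#' One row per selected parameter with posterior mean, median, standard
#' deviation, equal-tailed interval bounds and convergence diagnostics.
#'
#' @param x An `mtfit`.
#' @param pars Regular expression selecting parameters (default fixed
#'   effects plus scale/correlation parameters).
#' @param conf_level Interval level, default 0.90.
#' @param diagnostics Attach split-Rhat and ESS columns (default `TRUE`
#'   when more than one chain is available).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mtfit
#' @export
tidy.mtfit <- function(x, pars = NULL, conf_level = 0.90,
                       diagnostics = NULL, ...) {
  if (is.null(pars)) pars <- "^beta\\[|^log_sigma|^rho$"
  diagnostics <- diagnostics %||% (length(x$draws) > 1)
  sel <- grep(pars, x$param_names, value = TRUE)
  M <- draw_matrix(x)
  a <- (1 - conf_level) / 2
  out <- dplyr::bind_rows(purrr::map(sel, function(pn) {
    d <- M[, pn]
    tibble::tibble(
      term = pn, estimate = median(d), mean = mean(d), std.error = sd(d),
      conf.low = quantile(d, a, names = FALSE),
      conf.high = quantile(d, 1 - a, names = FALSE)
    )
  }))
  if (diagnostics) {
    dg <- suppressWarnings(diagnostics(x, pars = pars))
    out <- dplyr::left_join(out, dplyr::rename(dg, term = "parameter"),
                            by = "term")
    out$flagged <- NULL
  }
  out
}

#' Glance at a fitted threat-trend model
#'
#' @param x An `mtfit`.
#' @param ... Unused.
#' @return One-row tibble: sizes, sampler settings, mean acceptance rate,
#'   divergence count, and the worst Rhat / smallest ESS over the fixed
#'   effects (when multiple chains are available).
#' @method glance mtfit
#' @export
glance.mtfit <- function(x, ...) {
  md <- x$model_data
  base <- tibble::tibble(
    n_obs = length(md$y),
    n_populations = md$n_pop,
    n_species = md$n_species,
    n_sites = md$n_site,
    n_fixed_effects = ncol(md$X),
    chains = x$spec$chains,
    draws = sum(purrr::map_int(x$draws, nrow)),
    method = x$method,
    accept_rate = mean(x$sampler$accept_rate),
    divergences = sum(x$sampler$divergences)
  )
  if (length(x$draws) > 1) {
    dg <- diagnostics(x)
    base$max_rhat <- max(dg$rhat, na.rm = TRUE)
    base$min_ess <- min(dg$ess, na.rm = TRUE)
  }
  base
}

#' Tidy a trend posterior
#'
#' @param x A `trend_posterior`.
#' @param levels Interval levels, default 50/80/95% to match the standard
#'   reporting convention.
#' @param percent Also report the percent-per-year scale (default `TRUE`).
#' @param ... Unused.
#' @return One-row tibble: context, median and interval bounds on the log
#'   scale and (optionally) percent scale.
#' @method tidy trend_posterior
#' @export
tidy.trend_posterior <- function(x, levels = c(0.5, 0.8, 0.95),
                                 percent = TRUE, ...) {
  s <- trend_intervals(x$draws, levels)
  out <- tibble::as_tibble(as.list(s))
  out <- dplyr::bind_cols(tibble::tibble(context = x$context), out)
  if (percent) {
    sp <- trend_intervals(100 * (exp(x$draws) - 1), levels)
    names(sp) <- paste0("pct_", names(sp))
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(sp)))
  }
  out
}

#' Tidy an influence decomposition
#'
#' @param x An `mt_influence` from [influence_decomposition()].
#' @param ... Passed to [tidy.trend_posterior()].
#' @return Tibble with one row per component (null, random, fixed, and the
#'   two contribution differences).
#' @method tidy mt_influence
#' @export
tidy.mt_influence <- function(x, ...) {
  dplyr::bind_rows(purrr::map(
    x[c("null", "random", "fixed", "random_contribution",
        "fixed_contribution")],
    tidy, ...))
}

#' Tidy a counterfactual scenario
#'
#' @param x A `counterfactual_scenario`.
#' @param ... Unused.
#' @return One-row tibble (same columns as a [scenario_grid()] row).
#' @method tidy counterfactual_scenario
#' @export
tidy.counterfactual_scenario <- function(x, ...) {
  tidy_scenario_row(x)
}
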