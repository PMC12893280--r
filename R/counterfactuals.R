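#' Counterfactual threat-removal scenario
#'
#' Predicts what the trends of the threatened populations would have been
#' had one or more threats been removed, following the three-step
#' procedure: (1) drop unthreatened populations; (2) zero every design
#' column involving a removed threat (single columns and all interactions
#' containing it); (3) re-estimate each remaining population's trend under
#' the modified matrix and pool into a population-trend distribution.
#' Baseline and counterfactual use the same posterior draws, so Monte Carlo
#' noise cancels in the comparison.
#'
#' @param fit An `mtfit`.
#' @param removal_set Character vector of threats to remove (possibly
#'   empty, possibly all six).
#' @param ndraws Posterior draws to use (evenly subsampled), default 1000.
#' @param include_random Add each population's fitted random slopes to its
#'   trend (default `TRUE` for full fits; forced `FALSE` for conjugate
#'   fits).
#' @param pooling `"population"` (default: the scenario distribution is one
#'   per-population trend median) or `"draw"` (all population x draw trend
#'   values).
#' @param summary `"median"` (default) or `"mean"` summary of the pooled
#'   distribution.
#' @return An object of class `counterfactual_scenario`: removal set,
#'   baseline and counterfactual pooled distributions and summaries, and
#'   the relative change in percent (`NA` with an `absolute_change` fall
#'   back if the baseline summary is zero). `tidy()` gives a one-row table.
#' @export
run_counterfactual <- function(fit, removal_set = character(0),
                               ndraws = 1000, include_random = NULL,
                               pooling = c("population", "draw"),
                               summary = c("median", "mean")) {
  pooling <- match.arg(pooling)
  summary <- match.arg(summary)
  if (length(removal_set) > 0) assert_threats(removal_set, "removal")
  include_random <- include_random %||% (fit$method == "hmc")
  if (fit$method != "hmc") include_random <- FALSE

  md <- fit$model_data
  meta <- md$pop_meta
  threatened <- lengths(meta$threats) > 0
  if (!any(threatened)) abort("no threatened populations in the dataset")
  meta <- meta[threatened, , drop = FALSE]

  rows <- draw_subsample(fit, ndraws)
  B <- beta_draws(fit)[rows, , drop = FALSE]
  labels <- fit$design$labels
  year_cols <- c("year", paste0(labels, ":year"))
  Byear <- B[, year_cols, drop = FALSE]

  # indicator weights per population x year column, baseline and removed
  weights_for <- function(removed) {
    W <- matrix(0, nrow(meta), length(year_cols),
                dimnames = list(meta$population_id, year_cols))
    W[, "year"] <- 1
    for (j in seq_along(labels)) {
      toks <- combo_tokens(labels[j])
      if (labels[j] %in% fit$design$forced_off) next
      active <- purrr::map_lgl(meta$threats, function(s) {
        all(toks %in% setdiff(s, removed))
      })
      W[active, j + 1L] <- 1
    }
    W
  }

  rand_part <- if (include_random) {
    rS <- random_slope_draws(fit, "species")[rows, , drop = FALSE]
    rP <- random_slope_draws(fit, "population")[rows, , drop = FALSE]
    rL <- random_slope_draws(fit, "site")[rows, , drop = FALSE]
    t(rS[, match(meta$species_id, md$species_levels), drop = FALSE] +
        rP[, match(meta$population_id, md$population_levels),
           drop = FALSE] +
        rL[, match(meta$site_id, md$site_levels), drop = FALSE])
  } else {
    matrix(0, nrow(meta), length(rows))
  }

  trend_mat <- function(removed) {
    weights_for(union(fit$design$removed, removed)) %*% t(Byear) + rand_part
  }

  base_mat <- trend_mat(character(0)) # populations x draws
  cf_mat <- trend_mat(removal_set)

  pool <- function(m) {
    if (pooling == "population") apply(m, 1, median) else as.numeric(m)
  }
  base_dist <- pool(base_mat)
  cf_dist <- pool(cf_mat)
  sfun <- if (summary == "median") median else mean
  base_sum <- sfun(base_dist)
  cf_sum <- sfun(cf_dist)
  rc <- relative_change(base_sum, cf_sum)

  structure(list(
    removal_set = sort(removal_set),
    baseline = base_dist, counterfactual = cf_dist,
    baseline_matrix = base_mat, counterfactual_matrix = cf_mat,
    baseline_summary = base_sum, counterfactual_summary = cf_sum,
    relative_change_percent = rc,
    absolute_change = cf_sum - base_sum,
    n_populations = nrow(meta), pooling = pooling, summary = summary
  ), class = "counterfactual_scenario")
}

#' Relative change between baseline and counterfactual trend summaries
#'
#' `100 * (counterfactual - baseline) / |baseline|`. A zero baseline makes
#' the ratio undefined: `NA` is returned with attribute
#' `"absolute_change"` carrying the raw difference and a warning.
#'
#' @param baseline,counterfactual Scalar trend summaries (e.g. medians).
#' @return Percent change (scalar).
#' @export
relative_change <- function(baseline, counterfactual) {
  if (baseline == 0) {
    warn("baseline trend is zero; relative change undefined, reporting NA")
    return(structure(NA_real_,
                     absolute_change = counterfactual - baseline))
  }
  100 * (counterfactual - baseline) / abs(baseline)
}

#' Run a grid of counterfactual scenarios
#'
#' @inheritParams run_counterfactual
#' @param removal_sets List of removal sets (character vectors); e.g. the
#'   six singletons plus the all-threat removal.
#' @return Tibble of class `counterfactual_grid`: one row per scenario
#'   (`removal_set` label, baseline/counterfactual summaries, relative
#'   change, 80% interval of the counterfactual distribution), with the
#'   scenario objects in attribute `"scenarios"`. Sortable by
#'   `relative_change_percent`.
#' @export
scenario_grid <- function(fit, removal_sets = NULL, ndraws = 1000,
                          include_random = NULL,
                          pooling = c("population", "draw"),
                          summary = c("median", "mean")) {
  removal_sets <- removal_sets %||% c(
    purrr::map(threat_categories(), identity),
    list(threat_categories())
  )
  scen <- purrr::map(removal_sets, function(rs) {
    run_counterfactual(fit, rs, ndraws = ndraws,
                       include_random = include_random,
                       pooling = pooling, summary = summary)
  })
  out <- dplyr::bind_rows(purrr::map(scen, tidy_scenario_row))
  attr(out, "scenarios") <- scen
  class(out) <- c("counterfactual_grid", class(out))
  out
}

tidy_scenario_row <- function(s) {
  ci <- quantile(s$counterfactual, c(0.1, 0.9), names = FALSE)
  tibble::tibble(
    removal_set = if (length(s$removal_set)) {
      paste(s$removal_set, collapse = "+")
    } else {
      "(none)"
    },
    n_removed = length(s$removal_set),
    baseline = s$baseline_summary,
    counterfactual = s$counterfactual_summary,
    relative_change_percent = as.numeric(s$relative_change_percent),
    absolute_change = s$absolute_change,
    lower_80 = ci[1], upper_80 = ci[2],
    n_populations = s$n_populations
  )
}

#' @export
print.counterfactual_scenario <- function(x, ...) {
  lbl <- if (length(x$removal_set)) paste(x$removal_set, collapse = "+")
         else "(none)"
  cat(sprintf(
    "<counterfactual_scenario> remove %s: baseline %s %.4f -> %.4f (%+.1f%%), %d populations\n",
    lbl, x$summary, x$baseline_summary, x$counterfactual_summary,
    as.numeric(x$relative_change_percent), x$n_populations))
  invisible(x)
}
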