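#' Classify a threat interaction as additive, antagonistic or synergistic
#'
#' Differences the interactive trend posterior (interaction columns on)
#' from the additive trend posterior (interaction columns off) for a
#' multi-threat combination, draw by draw, and classifies the combination
#' from the equal-tailed credible interval of the difference: interval
#' containing zero — additive; entirely negative — synergistic (the
#' interaction worsens the trend beyond the sum of single effects);
#' entirely positive — antagonistic.
#'
#' @param fit An `mtfit`.
#' @param combo An interaction label present in the design (e.g.
#'   `"disease.exploitation"`; token order is irrelevant).
#' @param ci_level Credible level for the equal-tailed interval, default
#'   0.80.
#' @param ndraws Posterior draws to use (evenly subsampled), default all.
#' @return A one-row tibble of class `interaction_verdict`: `combo`,
#'   `median`, `lower`, `upper`, `ci_level`, `verdict`, `p_negative`,
#'   `p_positive`; the difference draws are in attribute `"draws"`.
#' @export
classify_interaction <- function(fit, combo, ci_level = 0.8,
                                 ndraws = NULL) {
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)")
  tokens <- sort(combo_tokens(combo))
  assert_threats(tokens)
  combo <- combo_label(tokens)
  if (length(tokens) < 2) {
    abort(sprintf("'%s' is not an interaction (needs >= 2 categories)",
                  combo))
  }
  if (!combo %in% fit$design$labels) {
    abort(sprintf("interaction '%s' is not in the fitted design", combo))
  }
  ti <- trend_posterior(fit, tokens, interactions = "on", ndraws = ndraws)
  ta <- trend_posterior(fit, tokens, interactions = "off", ndraws = ndraws)
  diff_draws <- ti$draws - ta$draws
  ci <- quantile(diff_draws, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                 names = FALSE)
  verdict <- if (ci[1] > 0) "antagonistic"
             else if (ci[2] < 0) "synergistic"
             else "additive"
  out <- tibble::tibble(
    combo = combo,
    median = median(diff_draws),
    lower = ci[1], upper = ci[2],
    ci_level = ci_level,
    verdict = verdict,
    p_negative = mean(diff_draws < 0),
    p_positive = mean(diff_draws > 0)
  )
  attr(out, "draws") <- diff_draws
  class(out) <- c("interaction_verdict", class(out))
  out
}

#' Classify every interaction in a fitted design
#'
#' @inheritParams classify_interaction
#' @return Tibble with one [classify_interaction()] row per interaction
#'   label (order >= 2) in the design.
#' @export
classify_all_interactions <- function(fit, ci_level = 0.8, ndraws = NULL) {
  combos <- fit$design$labels[combo_order(fit$design$labels) >= 2]
  if (length(combos) == 0) {
    warn("design contains no interaction labels")
    return(tibble::tibble())
  }
  dplyr::bind_rows(purrr::map(combos, function(cb) {
    v <- classify_interaction(fit, cb, ci_level = ci_level,
                              ndraws = ndraws)
    attr(v, "draws") <- NULL
    v
  }))
}

#' Verdict sensitivity to the credible level
#'
#' Reclassifies an interaction at several credible levels. Because the
#' equal-tailed intervals are nested, a combination that is non-additive at
#' a level stays non-additive at every smaller level.
#'
#' @inheritParams classify_interaction
#' @param ci_levels Numeric vector of levels in (0, 1).
#' @return Tibble of verdicts, one row per level.
#' @export
sensitivity_scan <- function(fit, combo, ci_levels = c(0.5, 0.8, 0.95),
                             ndraws = NULL) {
  if (any(ci_levels <= 0 | ci_levels >= 1)) {
    abort("ci_levels must be in (0, 1)")
  }
  dplyr::bind_rows(purrr::map(ci_levels, function(l) {
    v <- classify_interaction(fit, combo, ci_level = l, ndraws = ndraws)
    attr(v, "draws") <- NULL
    v
  }))
}

#' Per-threat shares of interaction classes
#'
#' For each single threat, the share of additive / antagonistic /
#' synergistic classifications among the interactions involving it.
#' `weighting = "combo"` (default) gives each combination one vote;
#' `weighting = "draw"` weights a non-additive combination by the posterior
#' mass supporting its direction (`p_negative` for synergistic,
#' `p_positive` for antagonistic), attributing the remainder to additive —
#' a draw-level aggregation yielding fractional percentages.
#'
#' @param verdicts Tibble from [classify_all_interactions()].
#' @param weighting `"combo"` or `"draw"`.
#' @return Tibble: `threat`, `class`, `share` (proportions in \[0, 1\]
#'   summing to 1 within threat), `n_combos`. Threats with no interactions
#'   are omitted.
#' @export
summarize_classes <- function(verdicts, weighting = c("combo", "draw")) {
  weighting <- match.arg(weighting)
  if (nrow(verdicts) == 0) return(tibble::tibble())
  classes <- c("additive", "antagonistic", "synergistic")
  rows <- purrr::map(threat_categories(), function(th) {
    v <- verdicts[purrr::map_lgl(verdicts$combo,
                                 ~ th %in% combo_tokens(.x)), ]
    if (nrow(v) == 0) return(NULL)
    w <- matrix(0, nrow(v), 3, dimnames = list(NULL, classes))
    for (i in seq_len(nrow(v))) {
      if (weighting == "combo") {
        w[i, v$verdict[i]] <- 1
      } else {
        if (v$verdict[i] == "synergistic") {
          w[i, "synergistic"] <- v$p_negative[i]
          w[i, "additive"] <- 1 - v$p_negative[i]
        } else if (v$verdict[i] == "antagonistic") {
          w[i, "antagonistic"] <- v$p_positive[i]
          w[i, "additive"] <- 1 - v$p_positive[i]
        } else {
          w[i, "additive"] <- 1
        }
      }
    }
    tibble::tibble(threat = th, class = classes,
                   share = unname(colSums(w)) / nrow(v),
                   n_combos = nrow(v))
  })
  dplyr::bind_rows(rows)
}
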