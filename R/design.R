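#' Enumerate threat-combination labels
#'
#' Builds the canonical ordered list of threat-combination labels used to
#' index the fixed-effect design. A label joins its category tokens
#' alphabetically with `"."` (e.g. `"disease.exploitation"`). Labels are
#' ordered by interaction order, then alphabetically.
#'
#' @param threat_sets List of character vectors (observed threat sets; empty
#'   sets are ignored).
#' @param max_order Maximum combination order, default 3 (higher-order
#'   exposure is rare in the source data and unsupported).
#' @param observed_only If `TRUE` (default), return only combinations
#'   observed in the data plus all sub-combinations of observed multi-threat
#'   sets; if `FALSE`, all combinations of the six categories up to
#'   `max_order` (41 for order 3).
#' @return Character vector of combination labels.
#' @export
enumerate_combinations <- function(threat_sets, max_order = 3,
                                   observed_only = TRUE) {
  threat_sets <- purrr::map(threat_sets, function(s) sort(unique(s)))
  purrr::walk(threat_sets, assert_threats)
  too_big <- purrr::map_int(threat_sets, length) > max_order
  if (any(too_big)) {
    abort(sprintf("threat set exceeds max_order = %d: {%s}", max_order,
                  paste(threat_sets[[which(too_big)[1]]], collapse = ", ")))
  }
  subsets_of <- function(s) {
    unlist(purrr::map(seq_len(min(length(s), max_order)), function(k) {
      utils::combn(s, k, combo_label)
    }))
  }
  labels <- if (observed_only) {
    unique(unlist(purrr::map(threat_sets[lengths(threat_sets) > 0],
                             subsets_of)))
  } else {
    subsets_of(threat_categories())
  }
  if (is.null(labels)) return(character(0))
  labels[order(combo_order(labels), labels)]
}

#' Number of fixed-effect coefficients implied by a label set
#'
#' Each combination label contributes an indicator column and a year
#' interaction; a global intercept and year slope complete the matrix, so
#' `p = 2 + 2 * n_labels`, multiplied by the number of levels of any fully
#' crossed grouping factor (e.g. a 5-level taxon factor).
#'
#' @param labels Character vector of combination labels (or an integer
#'   count).
#' @param crossing_levels Levels of a fully crossed factor, default 1.
#' @return Integer coefficient count.
#' @export
#' @examples
#' count_fixed_effects(36)     # 74
#' count_fixed_effects(36, 5)  # 370
count_fixed_effects <- function(labels, crossing_levels = 1) {
  if (crossing_levels < 1) abort("crossing_levels must be >= 1")
  n <- if (is.numeric(labels)) as.integer(labels) else length(labels)
  as.integer((2L + 2L * n) * crossing_levels)
}

design_colnames <- function(labels) {
  if (length(labels) == 0) return(c("intercept", "year"))
  c("intercept", "year",
    as.vector(rbind(labels, paste0(labels, ":year"))))
}

# rebuild the matrix from the design's row state (threat sets, centered
# year) and its toggle state (removed threats, forced-off combos)
design_rebuild <- function(d) {
  n <- length(d$centered_year)
  labels <- d$labels
  X <- matrix(0, n, 2 + 2 * length(labels),
              dimnames = list(NULL, design_colnames(labels)))
  X[, "intercept"] <- 1
  X[, "year"] <- d$centered_year
  eff <- purrr::map(d$threats, function(s) setdiff(s, d$removed))
  for (lab in labels) {
    if (lab %in% d$forced_off) next
    toks <- combo_tokens(lab)
    ind <- purrr::map_dbl(eff, function(s) as.numeric(all(toks %in% s)))
    X[, lab] <- ind
    X[, paste0(lab, ":year")] <- ind * d$centered_year
  }
  d$matrix <- X
  d
}

#' Build the binary threat-combination design matrix
#'
#' One row per observation; columns are a global intercept, the centred
#' year, and for every combination label an indicator (1 when all the
#' label's categories are in the row's threat set) plus its year interaction
#' (indicator times centred year). A population exposed to exploitation and
#' disease therefore gets `exploitation = 1`, `disease = 1`,
#' `disease.exploitation = 1` and zeros elsewhere.
#'
#' @param prepared Long observation tibble from [prepare_series()] (needs
#'   `threats` and `centered_year`), or any tibble with those columns.
#' @param labels Combination labels; defaults to
#'   [enumerate_combinations()] on the observed threat sets.
#' @return An object of class `threat_design` holding the matrix, the
#'   labels, and the per-row threat/toggle state used by
#'   [switch_interactions()] and [remove_threat()].
#' @export
build_design <- function(prepared, labels = NULL) {
  if (!all(c("threats", "centered_year") %in% names(prepared))) {
    abort("`prepared` must contain threats and centered_year columns")
  }
  threats <- purrr::map(prepared$threats, function(s) sort(unique(s)))
  if (is.null(labels)) {
    labels <- enumerate_combinations(unique(threats))
  }
  observed <- unique(threats[lengths(threats) > 0])
  covered <- purrr::map_lgl(observed, function(s) combo_label(s) %in% labels)
  if (any(!covered)) {
    abort(sprintf("threat set {%s} has no covering label",
                  paste(observed[[which(!covered)[1]]], collapse = ", ")))
  }
  d <- structure(
    list(labels = labels, threats = threats,
         centered_year = prepared$centered_year,
         removed = character(0), forced_off = character(0), matrix = NULL),
    class = "threat_design"
  )
  design_rebuild(d)
}

#' Toggle an interaction column on or off
#'
#' Turning an interaction "off" zeroes its indicator column and year twin
#' (the additive prediction); turning it back "on" restores the product
#' rule. All other columns are untouched.
#'
#' @param design A `threat_design`.
#' @param combo An interaction label present in the design (two or more
#'   categories).
#' @param state `"on"` or `"off"`.
#' @return The modified `threat_design`.
#' @export
switch_interactions <- function(design, combo, state = c("on", "off")) {
  state <- match.arg(state)
  if (!combo %in% design$labels) {
    abort(sprintf("unknown combination label: %s", combo))
  }
  if (length(combo_tokens(combo)) < 2) {
    abort(sprintf("'%s' is not an interaction label", combo))
  }
  design$forced_off <- if (state == "off") {
    union(design$forced_off, combo)
  } else {
    setdiff(design$forced_off, combo)
  }
  design_rebuild(design)
}

#' Remove a threat from the design (counterfactual semantics)
#'
#' Zeroes every indicator column (and its year twin) whose label contains
#' the threat, including all interactions involving it: removing
#' exploitation from a population with exploitation and disease leaves
#' `disease = 1` but zeroes `exploitation` and `disease.exploitation`.
#' Idempotent; removals commute.
#'
#' @param design A `threat_design`.
#' @param threat One of the six categories.
#' @return The modified `threat_design`.
#' @export
remove_threat <- function(design, threat) {
  assert_threats(threat)
  design$removed <- union(design$removed, threat)
  design_rebuild(design)
}

#' @export
print.threat_design <- function(x, ...) {
  cat(sprintf("<threat_design> %d rows x %d columns (%d combination labels)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$labels)))
  if (length(x$removed)) {
    cat("  removed threats:", paste(x$removed, collapse = ", "), "\n")
  }
  if (length(x$forced_off)) {
    cat("  interactions off:", paste(x$forced_off, collapse = ", "), "\n")
  }
  invisible(x)
}

# design for a single pseudo-series context (one threat set over a year
# grid), sharing labels/toggles with a template design
context_design <- function(template, threats, years) {
  d <- structure(
    list(labels = template$labels,
         threats = rep(list(sort(unique(threats))), length(years)),
         centered_year = years - mean(years),
         removed = template$removed, forced_off = template$forced_off,
         matrix = NULL),
    class = "threat_design"
  )
  design_rebuild(d)
}
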