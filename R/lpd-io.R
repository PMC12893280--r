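#' Read a wide Living-Planet-style population table
#'
#' Reads the wide "LPD dialect": one row per population, metadata columns
#' followed by one column per calendar year (header is the year integer).
#' Blank or sentinel ("NA", "NULL") year cells become missing observations.
#'
#' Expected metadata columns: `population_id`, `species_id`, `latitude`,
#' `longitude`, `system`, `taxon`, one 0/1 column per threat category
#' (see [threat_categories()]) and optionally `threats_known` (0/1; assumed
#' known when absent).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per population: identifier and metadata
#'   columns, a `threats` list-column of category tokens, a logical
#'   `threat_status_known`, and a `data` list-column of `(year, abundance)`
#'   tibbles ordered by year.
#' @export
read_lpd <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("population_id", "species_id", "latitude", "longitude",
                 "system", "taxon", threat_categories())
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  year_cols <- names(raw)[grepl("^[0-9]{4}$", names(raw))]
  if (length(year_cols) == 0) abort("no year columns found")
  years <- as.integer(year_cols)

  sentinel <- function(x) is.na(x) | x == "" | x %in% c("NA", "NULL")

  parse_row <- function(i) {
    cells <- as.character(raw[i, year_cols])
    keep <- !sentinel(cells)
    ab <- suppressWarnings(as.numeric(cells[keep]))
    if (anyNA(ab)) {
      abort(sprintf("unparseable abundance in row '%s' (year %s)",
                    raw$population_id[i], years[keep][which(is.na(ab))[1]]))
    }
    ord <- order(years[keep])
    tibble::tibble(year = years[keep][ord], abundance = ab[ord])
  }

  threats <- purrr::map(seq_len(nrow(raw)), function(i) {
    flags <- suppressWarnings(as.numeric(raw[i, threat_categories()]))
    flags[is.na(flags)] <- 0
    set <- threat_categories()[flags > 0]
    if (length(set) > 3) {
      abort(sprintf("row '%s' has %d threats; at most 3 are supported",
                    raw$population_id[i], length(set)))
    }
    set
  })

  known <- if ("threats_known" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$threats_known)) > 0
  } else {
    rep(TRUE, nrow(raw))
  }
  known[is.na(known)] <- FALSE

  out <- tibble::tibble(
    population_id = raw$population_id,
    species_id = raw$species_id,
    latitude = as.numeric(raw$latitude),
    longitude = as.numeric(raw$longitude),
    system = raw$system,
    taxon = raw$taxon,
    threats = threats,
    threat_status_known = known,
    data = purrr::map(seq_len(nrow(raw)), parse_row)
  )
  if (any(abs(out$latitude) > 90, na.rm = TRUE) ||
      any(abs(out$longitude) > 180, na.rm = TRUE)) {
    abort("coordinates outside [-90, 90] x [-180, 180]")
  }
  out
}

#' Write populations back to the wide LPD dialect
#'
#' Inverse of [read_lpd()]; used for round-trip tests and data exchange.
#'
#' @param populations Tibble as returned by [read_lpd()] or
#'   [simulate_populations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lpd <- function(populations, path) {
  all_years <- sort(unique(unlist(purrr::map(populations$data, "year"))))
  meta <- dplyr::select(populations, -"threats", -"data",
                        -"threat_status_known")
  flags <- purrr::map(populations$threats, function(s) {
    setNames(as.integer(threat_categories() %in% s), threat_categories())
  })
  flags <- dplyr::bind_rows(flags)
  wide <- matrix(NA_real_, nrow(populations), length(all_years),
                 dimnames = list(NULL, as.character(all_years)))
  for (i in seq_len(nrow(populations))) {
    d <- populations$data[[i]]
    wide[i, as.character(d$year)] <- d$abundance
  }
  out <- dplyr::bind_cols(
    meta,
    tibble::tibble(threats_known = as.integer(populations$threat_status_known)),
    flags,
    tibble::as_tibble(wide)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Apply the study inclusion filters
#'
#' Retains populations monitored over an inclusive calendar span of at least
#' `min_span_years` years with at least `min_points` data points, and (by
#' default) a known threat status. Filtering preserves order and is
#' idempotent.
#'
#' @param populations Tibble as returned by [read_lpd()].
#' @param min_span_years Minimum inclusive calendar span
#'   (`last - first + 1`), default 10.
#' @param min_points Minimum number of non-missing observations, default 5.
#' @param require_threat_status Drop populations whose threat status is
#'   unknown (default `TRUE`).
#' @return Filtered tibble (possibly empty), same columns as the input.
#' @export
filter_series <- function(populations, min_span_years = 10, min_points = 5,
                          require_threat_status = TRUE) {
  span <- purrr::map_dbl(populations$data, function(d) {
    if (nrow(d) == 0) return(0)
    diff(range(d$year)) + 1
  })
  npts <- purrr::map_int(populations$data, nrow)
  keep <- span >= min_span_years & npts >= min_points
  if (require_threat_status) keep <- keep & populations$threat_status_known
  populations[keep, , drop = FALSE]
}

#' Centre series for modelling
#'
#' Converts populations to a long observation table with per-series centred
#' year and centred log abundance, the response/covariate pair the trend
#' model is fit to. The log transform is applied first and the log values
#' are then centred by their series mean (the default; see `center`). Series
#' containing zero abundances receive a constant offset before the log.
#'
#' @param populations Tibble as returned by [read_lpd()] /
#'   [filter_series()].
#' @param zero_policy How to handle zero abundances: `"mean_fraction"`
#'   (default; add `zero_fraction` of the series mean abundance to every
#'   observation of a series containing zeros), `"add_one"` (add 1), or
#'   `"error"`.
#' @param zero_fraction Fraction of the series mean used by
#'   `"mean_fraction"`, default 0.01.
#' @param center `"log_mean"` (default) subtracts the mean of the log
#'   values, giving exactly mean-zero series; `"abundance_mean"` subtracts
#'   the log of the mean abundance instead (centring on the abundance scale
#'   before the log; only approximately mean-zero).
#' @return A long tibble, one row per observation: population metadata,
#'   `site_id` (from integer-rounded coordinates), `year`, `abundance`,
#'   `centered_year`, `centered_log_abundance`, `offset_applied`.
#' @export
prepare_series <- function(populations,
                           zero_policy = c("mean_fraction", "add_one",
                                           "error"),
                           zero_fraction = 0.01,
                           center = c("log_mean", "abundance_mean")) {
  zero_policy <- match.arg(zero_policy)
  center <- match.arg(center)

  rows <- purrr::map(seq_len(nrow(populations)), function(i) {
    p <- populations[i, ]
    d <- p$data[[1]]
    if (nrow(d) < 2) {
      abort(sprintf("population '%s' has fewer than 2 observations",
                    p$population_id))
    }
    if (any(!is.finite(d$abundance))) {
      abort(sprintf("non-finite abundance in population '%s'",
                    p$population_id))
    }
    if (any(d$abundance < 0)) {
      abort(sprintf("negative abundance in population '%s'",
                    p$population_id))
    }
    offset <- 0
    if (any(d$abundance == 0)) {
      if (all(d$abundance == 0)) {
        abort(sprintf("population '%s' has all-zero abundances",
                      p$population_id))
      }
      offset <- switch(zero_policy,
        mean_fraction = zero_fraction * mean(d$abundance),
        add_one = 1,
        error = abort(sprintf("zero abundance in population '%s'",
                              p$population_id))
      )
    }
    la <- log(d$abundance + offset)
    cla <- switch(center,
      log_mean = la - mean(la),
      abundance_mean = la - log(mean(d$abundance + offset))
    )
    rc <- round_coordinates(p$latitude, p$longitude)
    tibble::tibble(
      population_id = p$population_id,
      species_id = p$species_id,
      site_id = sprintf("s%+04d%+05d", rc$latitude, rc$longitude),
      latitude = p$latitude,
      longitude = p$longitude,
      system = p$system,
      taxon = p$taxon,
      threats = list(p$threats[[1]]),
      year = d$year,
      abundance = d$abundance,
      centered_year = d$year - mean(d$year),
      centered_log_abundance = cla,
      offset_applied = offset
    )
  })
  dplyr::bind_rows(rows)
}
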