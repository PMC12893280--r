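#' Generator configuration
#'
#' Settings for the synthetic Living-Planet-style generator. Defaults state
#' the emulated world: series spanning 10–65 calendar years with a median
#' around 25; five taxa and three systems in the source data's proportions;
#' marginal threat prevalences (share of population-threat assignment
#' tokens, "none" included) of 20.00% none, 3.04% disease, 5.69% invasive,
#' 6.07% climate change, 7.16% pollution, 27.20% habitat loss and 30.60%
#' exploitation; at most three threats per population; no-threat trend of
#' about +1.7%/yr with single-threat year-slope moderations matching the
#' reported single-threat trends; interaction effects zero (an additive
#' world) unless overridden via `true_beta`.
#'
#' @param n_species,populations_per_species,n_sites Structure sizes.
#' @param span_range Calendar span limits (inclusive), default `c(10, 65)`.
#' @param missingness Probability that an interior year is unobserved,
#'   default 0.2 (first/last year always kept; at least `min_points`
#'   observations retained).
#' @param min_points Minimum observations per series, default 5.
#' @param threat_prevalence Named probabilities over `"none"` plus the six
#'   categories (need not sum exactly to 1; renormalised).
#' @param extra_threat_prob Probability of drawing each additional threat
#'   token after the first, default 0.5.
#' @param max_threats Maximum threats per population, default 3.
#' @param true_beta Named numeric vector of design-column effects
#'   overriding the defaults (e.g.
#'   `c("disease.exploitation:year" = -0.08)`); names follow the design
#'   grammar (`"year"`, combination labels, `"<label>:year"`).
#' @param true_sigma_obs AR(1) innovation standard deviation of log
#'   abundance, default 0.3.
#' @param true_sigma_species,true_sigma_population,true_sigma_site Random
#'   year-slope scales, defaults 0.02 / 0.02 / 0.01.
#' @param true_rho AR(1) residual correlation, default 0.3.
#' @param zero_rate Corruption option: probability of zeroing an
#'   observation (exercises the zero-offset path), default 0.
#' @param taxa_shares,system_shares Assignment probabilities (defaults
#'   match the source data's composition).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_species = 60, populations_per_species = 2,
                             n_sites = 60, span_range = c(10, 65),
                             missingness = 0.2, min_points = 5,
                             threat_prevalence = c(
                               none = 0.2000, disease = 0.0304,
                               invasive = 0.0569, climate_change = 0.0607,
                               pollution = 0.0716, habitat_loss = 0.2720,
                               exploitation = 0.3060),
                             extra_threat_prob = 0.5, max_threats = 3,
                             true_beta = NULL, true_sigma_obs = 0.3,
                             true_sigma_species = 0.02,
                             true_sigma_population = 0.02,
                             true_sigma_site = 0.01, true_rho = 0.3,
                             zero_rate = 0,
                             taxa_shares = c(amphibian = 83, bird = 1195,
                                             fish = 947, mammal = 698,
                                             reptile = 206) / 3129,
                             system_shares = c(freshwater = 616,
                                               marine = 1271,
                                               terrestrial = 1242) / 3129,
                             seed = 1) {
  if (any(threat_prevalence < 0)) abort("prevalences must be nonnegative")
  if (max_threats > 3) abort("max_threats cannot exceed 3")
  if (span_range[1] < 10 || span_range[2] > 65) {
    abort("span_range must lie within [10, 65]")
  }
  structure(as.list(environment()), class = "generator_config")
}

# default year-slope moderations: single-threat trends (percent/yr
# converted to log scale) relative to the no-threat trend; interactions 0
default_true_beta <- function() {
  pct <- c(none = 1.70, climate_change = -3.14, disease = -4.63,
           exploitation = -0.85, habitat_loss = -0.42, invasive = -6.01,
           pollution = -1.79)
  slope <- log(1 + pct / 100)
  out <- c(year = unname(slope["none"]))
  for (th in threat_categories()) {
    out[paste0(th, ":year")] <- slope[th] - slope["none"]
  }
  out
}

#' Simulate LPD-like multi-threat population time series
#'
#' Simulates forward from the trend model itself: sites on the globe with
#' proximity-correlated site slopes (through the Cholesky factor of the
#' Haversine proximity matrix), independent species and population slopes,
#' threat tokens drawn i.i.d. from the prevalence distribution (capped at
#' `max_threats` per population), and log abundance built from the
#' design-implied slope plus an AR(1) residual process with innovation
#' scale `true_sigma_obs` (abundances are exponentiated, hence positive by
#' construction). Every emitted series satisfies the inclusion envelope
#' (span >= 10 calendar years, >= `min_points` points, <= 3 threats).
#'
#' @param config A [generator_config()].
#' @return A list with `populations` (tibble in the [read_lpd()] shape) and
#'   `truth` (a `synthetic_truth` list: realised `beta` per design column,
#'   scales, `rho`, per-group random slopes, threat sets and raw prevalence
#'   tokens, and the config). Same seed, same output.
#' @export
simulate_populations <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    abort("config must be a generator_config()")
  }
  set.seed(config$seed)
  n_pop <- config$n_species * config$populations_per_species

  # sites roughly area-uniform on the globe, clipped to inhabited latitudes
  lat <- pmax(-65, pmin(75, asin(runif(config$n_sites, -1, 1)) * 180 / pi))
  lon <- runif(config$n_sites, -180, 180)
  sites <- tibble::tibble(
    site_id = sprintf("site%03d", seq_len(config$n_sites)),
    latitude = lat, longitude = lon
  )
  prox <- build_site_proximity(sites)

  species <- sprintf("sp%03d", seq_len(config$n_species))
  taxa <- sample(names(config$taxa_shares), config$n_species, TRUE,
                 config$taxa_shares)
  systems <- sample(names(config$system_shares), config$n_species, TRUE,
                    config$system_shares)
  pop_species <- rep(seq_len(config$n_species),
                     each = config$populations_per_species)
  pop_site <- sample(config$n_sites, n_pop, replace = TRUE)

  # threat tokens: first token from the full prevalence distribution
  # ("none" ends assignment); extra tokens drawn with prob
  # extra_threat_prob, a "none" extra also ending assignment. All drawn
  # tokens are i.i.d. from the prevalence distribution, so token shares
  # reproduce the configured marginal prevalences exactly in expectation.
  prev <- config$threat_prevalence / sum(config$threat_prevalence)
  draw_tokens <- function() {
    tokens <- character(0)
    repeat {
      tok <- sample(names(prev), 1, prob = prev)
      tokens <- c(tokens, tok)
      if (tok == "none") break
      if (sum(tokens != "none") >= config$max_threats) break
      if (runif(1) >= config$extra_threat_prob) break
    }
    tokens
  }
  token_list <- purrr::map(seq_len(n_pop), ~ draw_tokens())
  threat_sets <- purrr::map(token_list,
                            function(t) sort(unique(setdiff(t, "none"))))

  # random year slopes (noncentered construction)
  zS <- rnorm(config$n_species)
  zP <- rnorm(n_pop)
  zL <- rnorm(config$n_sites)
  rS <- noncentered_transform(zS, config$true_sigma_species)
  rP <- noncentered_transform(zP, config$true_sigma_population)
  rL <- noncentered_transform(zL, config$true_sigma_site, prox$chol)

  # true fixed effects over the design implied by the realised threat sets
  labels <- enumerate_combinations(unique(threat_sets))
  beta <- setNames(numeric(length(design_colnames(labels))),
                   design_colnames(labels))
  defaults <- default_true_beta()
  shared <- intersect(names(defaults), names(beta))
  beta[shared] <- defaults[shared]
  if (!is.null(config$true_beta)) {
    extra <- setdiff(names(config$true_beta), names(beta))
    if (length(extra) > 0) {
      abort(sprintf("true_beta names not in the implied design: %s",
                    paste(extra, collapse = ", ")))
    }
    beta[names(config$true_beta)] <- config$true_beta
  }

  slope_for <- function(s) {
    if (length(s) == 0) return(unname(beta["year"]))
    subs <- enumerate_combinations(list(s))
    unname(beta["year"]) + sum(beta[paste0(subs, ":year")])
  }

  rc <- round_coordinates(sites$latitude, sites$longitude)
  site_key <- sprintf("s%+04d%+05d", rc$latitude, rc$longitude)

  pops <- purrr::map(seq_len(n_pop), function(j) {
    span <- 0
    while (span < config$span_range[1] || span > config$span_range[2]) {
      span <- 10 + round(rgamma(1, shape = 2, scale = 9))
    }
    start <- sample(1950:(2019 - span + 1), 1)
    years <- start:(start + span - 1)
    keep <- rep(TRUE, span)
    interior <- 2:(span - 1)
    keep[interior] <- runif(length(interior)) >= config$missingness
    if (sum(keep) < config$min_points) {
      need <- config$min_points - sum(keep)
      keep[sample(which(!keep), need)] <- TRUE
    }
    years <- years[keep]
    cy <- years - mean(years)

    s <- threat_sets[[j]]
    sl <- slope_for(s) + rS[pop_species[j]] + rP[j] + rL[pop_site[j]]
    level <- rnorm(1, 5, 0.7)
    n <- length(years)
    eps <- numeric(n)
    eps[1] <- rnorm(1, 0, config$true_sigma_obs)
    if (n > 1) {
      for (t in 2:n) {
        eps[t] <- config$true_rho * eps[t - 1] +
          rnorm(1, 0, config$true_sigma_obs)
      }
    }
    log_ab <- level + sl * cy + eps
    abundance <- exp(log_ab)
    if (config$zero_rate > 0) {
      z <- runif(n) < config$zero_rate
      if (all(z)) z[1] <- FALSE # keep at least one positive value
      abundance[z] <- 0
    }
    list(
      data = tibble::tibble(year = years, abundance = abundance),
      frame = tibble::tibble(
        population_id = sprintf("pop%04d", j),
        species_id = species[pop_species[j]],
        site_id = site_key[pop_site[j]],
        latitude = sites$latitude[pop_site[j]],
        longitude = sites$longitude[pop_site[j]],
        threats = rep(list(s), n),
        year = years,
        centered_year = cy,
        centered_log_abundance = sl * cy + eps
      )
    )
  })
  model_frame <- dplyr::bind_rows(purrr::map(pops, "frame"))
  pops <- purrr::map(pops, "data")

  populations <- tibble::tibble(
    population_id = sprintf("pop%04d", seq_len(n_pop)),
    species_id = species[pop_species],
    latitude = sites$latitude[pop_site],
    longitude = sites$longitude[pop_site],
    system = systems[pop_species],
    taxon = taxa[pop_species],
    threats = threat_sets,
    threat_status_known = TRUE,
    data = pops
  )

  truth <- structure(list(
    beta = beta,
    sigma_obs = config$true_sigma_obs,
    rho = config$true_rho,
    sigma_species = config$true_sigma_species,
    sigma_population = config$true_sigma_population,
    sigma_site = config$true_sigma_site,
    species_slopes = setNames(rS, species),
    population_slopes = setNames(rP, populations$population_id),
    site_slopes = setNames(rL, sites$site_id),
    population_sites = setNames(sites$site_id[pop_site],
                                populations$population_id),
    threat_sets = setNames(threat_sets, populations$population_id),
    threat_tokens = setNames(token_list, populations$population_id),
    sites = sites,
    labels = labels,
    model_frame = model_frame,
    config = config
  ), class = "synthetic_truth")

  list(populations = populations, truth = truth)
}

#' Parameter-recovery report against generator truth
#'
#' Compares posterior medians and credible intervals from a fit to the
#' generating truth, parameter by parameter: fixed effects (matched by
#' design column), the AR(1) correlation and the observation/random-slope
#' scales.
#'
#' @param truth A `synthetic_truth` from [simulate_populations()].
#' @param fit An `mtfit` fitted to the generator's output.
#' @param level Credible level for coverage, default 0.90.
#' @return Tibble: `parameter`, `truth`, `median`, `lower`, `upper`,
#'   `bias`, `covered`; aggregate coverage in attribute `"coverage"`.
#'   Errors if truth names cannot be matched to fitted parameters.
#' @export
recovery_report <- function(truth, fit, level = 0.90) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("truth must be a synthetic_truth object")
  }
  M <- draw_matrix(fit)
  want <- c(paste0("beta[", names(truth$beta), "]"),
            if (!is.null(fit$param_index$rho)) "rho",
            "log_sigma",
            if (!is.null(fit$param_index$log_sigma_S)) {
              c("log_sigma_S", "log_sigma_P", "log_sigma_L")
            })
  missing_par <- setdiff(want, colnames(M))
  if (length(missing_par) > 0) {
    abort(sprintf("truth parameters not found in fit: %s",
                  paste(missing_par, collapse = ", ")))
  }
  tv <- c(truth$beta,
          if (!is.null(fit$param_index$rho)) c(rho = truth$rho),
          log_sigma = log(truth$sigma_obs),
          if (!is.null(fit$param_index$log_sigma_S)) {
            c(log_sigma_S = log(truth$sigma_species),
              log_sigma_P = log(truth$sigma_population),
              log_sigma_L = log(truth$sigma_site))
          })
  a <- (1 - level) / 2
  rows <- purrr::map(seq_along(want), function(i) {
    d <- M[, want[i]]
    q <- quantile(d, c(a, 0.5, 1 - a), names = FALSE)
    tibble::tibble(parameter = want[i], truth = unname(tv[i]),
                   median = q[2], lower = q[1], upper = q[3],
                   bias = q[2] - unname(tv[i]),
                   covered = tv[i] >= q[1] & tv[i] <= q[3])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "coverage") <- mean(out$covered)
  out
}
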