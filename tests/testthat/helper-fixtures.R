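# Shared fixtures: all built in code at test time.

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# toy wide-format CSV (3 populations, gappy years)
toy_lpd_csv <- function(path = tempfile(fileext = ".csv")) {
  header <- paste(c("population_id", "species_id", "latitude", "longitude",
                    "system", "taxon", "threats_known", threat_categories(),
                    2000:2010), collapse = ",")
  rows <- c(
    paste(c("p1", "spA", "10.65", "-3.2", "terrestrial", "bird", "1",
            "0", "1", "1", "0", "0", "0",
            "12", "", "14", "15", "", "17", "18", "19", "20", "21", "22"),
          collapse = ","),
    paste(c("p2", "spB", "-0.4", "100.5", "freshwater", "fish", "1",
            "0", "0", "0", "0", "0", "0",
            "5", "", "", "4", "", "3", "", "", "", "", "2"),
          collapse = ","),
    paste(c("p3", "spC", "45.0", "7.0", "marine", "mammal", "0",
            "0", "0", "0", "1", "0", "0",
            "100", "", "", "90", "", "80", "", "", "", "", "70"),
          collapse = ",")
  )
  writeLines(c(header, rows), path)
  path
}

# small synthetic world + HMC fit, reused across downstream tests
small_sim <- function() {
  cache_get("small_sim", function() {
    cfg <- generator_config(
      n_species = 12, populations_per_species = 2, n_sites = 10,
      threat_prevalence = c(none = 0.25, exploitation = 0.30,
                            disease = 0.25, habitat_loss = 0.20),
      seed = 7
    )
    simulate_populations(cfg)
  })
}

small_fit <- function() {
  cache_get("small_fit", function() {
    sim <- small_sim()
    prep <- prepare_series(filter_series(sim$populations))
    fit_model(prep, chains = 2, iter = 500, warmup = 250, seed = 7)
  })
}

# minimal mtfit around fabricated fixed-effect draws, for deterministic
# checks of the trend / classification / counterfactual layers
make_beta_fit <- function(threat_sets, beta_draws_matrix) {
  prep <- dplyr::bind_rows(lapply(seq_along(threat_sets), function(i) {
    yrs <- 2000:2004
    tibble::tibble(
      population_id = sprintf("p%02d", i),
      species_id = sprintf("sp%02d", i),
      site_id = "s+000+0000", latitude = 0.1 * i, longitude = 0.1 * i,
      threats = list(sort(threat_sets[[i]])),
      year = yrs, centered_year = yrs - mean(yrs),
      centered_log_abundance = 0, abundance = 1
    )
  }))
  md <- threatrends:::make_model_data(prep, ar1 = FALSE)
  p <- ncol(md$X)
  B <- matrix(0, nrow(beta_draws_matrix), p,
              dimnames = list(NULL, paste0("beta[", colnames(md$X), "]")))
  shared <- intersect(colnames(md$X), colnames(beta_draws_matrix))
  B[, paste0("beta[", shared, "]")] <- beta_draws_matrix[, shared]
  draws <- cbind(B, log_sigma = 0)
  structure(
    list(draws = list(draws), param_names = colnames(draws),
         param_index = list(beta = seq_len(p), log_sigma = p + 1L),
         model_data = md, design = md$design, proximity = md$proximity,
         spec = list(chains = 1, iter = nrow(draws), warmup = 0, seed = 1,
                     ar1 = FALSE),
         method = "conjugate",
         sampler = list(accept_rate = 1, stepsize = NA_real_,
                        divergences = 0L)),
    class = "mtfit"
  )
}

# fixed-effect Gaussian world with a two-threat interaction, used by the
# classifier calibration / detection experiments
make_interaction_world <- function(beta_int, seed, n_affected = 60,
                                   n_single = 30, n_none = 30, points = 15,
                                   sigma = 0.3) {
  set.seed(seed)
  sets <- c(rep(list(c("disease", "exploitation")), n_affected),
            rep(list("disease"), n_single),
            rep(list("exploitation"), n_single),
            rep(list(character(0)), n_none))
  slope1 <- c(year = 0.017, disease = -0.064, exploitation = -0.025)
  dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    yrs <- 2000:(2000 + points - 1)
    cy <- yrs - mean(yrs)
    s <- sets[[i]]
    sl <- slope1[["year"]] + sum(slope1[s]) +
      if (length(s) == 2) beta_int else 0
    tibble::tibble(
      population_id = sprintf("p%03d", i),
      species_id = sprintf("sp%03d", i),
      site_id = "s+000+0000", latitude = 0, longitude = 0,
      threats = list(s), year = yrs, centered_year = cy,
      centered_log_abundance = sl * cy + rnorm(points, 0, sigma)
    )
  }))
}
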