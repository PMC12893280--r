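# 5-series toy world shared by the density/gradient checks
toy_prepared <- function(seed = 5) {
  set.seed(seed)
  sets <- list(character(0), "exploitation", "disease",
               c("disease", "exploitation"), "exploitation")
  dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    yrs <- 2000:(2000 + 5 + i)
    tibble::tibble(
      population_id = sprintf("p%02d", i),
      species_id = sprintf("sp%02d", (i + 1) %/% 2),
      site_id = c("s1", "s2", "s3")[1 + i %% 3],
      latitude = c(0, 30, -45)[1 + i %% 3],
      longitude = c(10, 60, -120)[1 + i %% 3],
      threats = list(sets[[i]]), year = yrs,
      centered_year = yrs - mean(yrs),
      centered_log_abundance = rnorm(length(yrs))
    )
  }))
}

toy_params <- function(md, seed = 9) {
  set.seed(seed)
  list(beta = rnorm(ncol(md$X), 0, 0.2), sigma = 0.4, rho = 0.35,
       sigma_S = 0.05, sigma_P = 0.03, sigma_L = 0.02,
       zS = rnorm(md$n_species), zP = rnorm(md$n_pop),
       zL = rnorm(md$n_site))
}

test_that("model log density matches a brute-force evaluation", {
  prep <- toy_prepared()
  md <- threatrends:::make_model_data(prep)
  par <- toy_params(md)

  # brute force: walk each series in year order, assembling mu by hand
  rS <- par$sigma_S * par$zS
  rP <- par$sigma_P * par$zP
  rL <- par$sigma_L * drop(md$proximity$chol %*% par$zL)
  pd <- md$prepared
  X <- md$design$matrix
  ll <- 0
  for (pid in unique(pd$population_id)) {
    rows <- which(pd$population_id == pid)
    rows <- rows[order(pd$year[rows])]
    eps_prev <- 0
    for (r in rows) {
      eta <- sum(X[r, ] * par$beta) + pd$centered_year[r] *
        (rS[match(pd$species_id[r], md$species_levels)] +
           rP[match(pd$population_id[r], md$population_levels)] +
           rL[match(pd$site_id[r], md$site_levels)])
      mu <- eta + par$rho * eps_prev
      ll <- ll + dnorm(pd$centered_log_abundance[r], mu, par$sigma,
                       log = TRUE)
      eps_prev <- pd$centered_log_abundance[r] - eta
    }
  }
  expect_equal(model_log_density(md, par), ll, tolerance = 1e-8)

  # prior block adds the standard log densities
  lp <- model_log_density(md, par, include_prior = TRUE)
  prior <- sum(dnorm(par$beta, log = TRUE)) +
    sum(dnorm(c(par$zS, par$zP, par$zL), log = TRUE)) +
    sum(dexp(c(par$sigma, par$sigma_S, par$sigma_P, par$sigma_L),
             log = TRUE)) +
    dnorm(par$rho, 0, 0.25, log = TRUE)
  expect_equal(lp, ll + prior, tolerance = 1e-8)
})

test_that("the analytic gradient matches finite differences", {
  prep <- toy_prepared()
  md <- threatrends:::make_model_data(prep)
  pt <- threatrends:::param_template(md)
  set.seed(2)
  theta <- rnorm(pt$n, 0, 0.4)
  lg <- threatrends:::log_posterior_grad(theta, md, pt)
  h <- 1e-6
  num <- vapply(seq_len(pt$n), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (threatrends:::log_posterior_grad(tp, md, pt, grad = FALSE)$lp -
       threatrends:::log_posterior_grad(tm, md, pt, grad = FALSE)$lp) /
      (2 * h)
  }, numeric(1))
  expect_equal(lg$grad, num, tolerance = 1e-4)
})

test_that("the log density is invariant to input row order", {
  prep <- toy_prepared()
  md1 <- threatrends:::make_model_data(prep)
  par <- toy_params(md1)
  set.seed(77)
  shuffled <- prep[sample(nrow(prep)), ]
  md2 <- threatrends:::make_model_data(shuffled)
  expect_equal(model_log_density(md2, par), model_log_density(md1, par),
               tolerance = 1e-10)
})

test_that("noncentered_transform maps z-scores to slopes", {
  expect_equal(noncentered_transform(rep(0, 4), 2.5), rep(0, 4))
  expect_equal(noncentered_transform(c(1, -2), 0), c(0, 0))
  expect_equal(noncentered_transform(1.5, 2), 3.0)
  L <- t(chol(matrix(c(1, 0.6, 0.6, 1), 2)))
  z <- c(1, -1)
  expect_equal(noncentered_transform(z, 0.5, L), 0.5 * drop(L %*% z))
  expect_error(noncentered_transform(c(1, 2, 3), 1, L), "dimensions")
  expect_error(noncentered_transform(1, -1), "nonnegative")
})

test_that("noncentered sampling matches the centered formulation", {
  # r = z * sigma with z ~ N(0,1), sigma ~ Exp(1) versus r | sigma ~
  # N(0, sigma): same marginal distribution
  set.seed(123)
  n <- 1e5
  nonc <- rnorm(n) * rexp(n)
  cent <- rnorm(n, 0, rexp(n))
  ks <- suppressWarnings(stats::ks.test(nonc, cent))
  expect_gt(ks$p.value, 0.01)
})

test_that("fits are reproducible from the seed", {
  prep <- toy_prepared()
  f1 <- fit_model(prep, chains = 1, iter = 80, warmup = 40, seed = 33)
  f2 <- fit_model(prep, chains = 1, iter = 80, warmup = 40, seed = 33)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_model(prep, chains = 1, iter = 80, warmup = 40, seed = 34)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("split-Rhat and ESS behave on known chains", {
  set.seed(4)
  white <- replicate(4, rnorm(500), simplify = FALSE)
  expect_equal(threatrends:::rhat_value(white), 1, tolerance = 0.01)
  # well separated chains inflate Rhat far beyond 1.1
  apart <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(threatrends:::rhat_value(apart), 1.1)
  # independent draws: ESS close to the draw count
  ess <- threatrends:::ess_value(white)
  expect_gt(ess, 0.8 * 2000)
  expect_lte(ess, 2000)
  # strongly autocorrelated draws: ESS far below the draw count
  ar <- replicate(2, as.numeric(stats::arima.sim(list(ar = 0.95), 500)),
                  simplify = FALSE)
  expect_lt(threatrends:::ess_value(ar), 500)
})

test_that("diagnostics reports per-parameter convergence", {
  fit <- small_fit()
  dg <- diagnostics(fit)
  expect_true(all(c("parameter", "rhat", "ess", "flagged") %in% names(dg)))
  expect_true(all(is.finite(dg$rhat)))
  expect_true(all(dg$ess > 0))
  expect_type(attr(dg, "divergences"), "integer")
  # single chain: Rhat still computed from halves, but with a warning
  f1 <- fit_model(toy_prepared(), chains = 1, iter = 80, warmup = 40,
                  seed = 3)
  expect_warning(diagnostics(f1), "single chain")
})

test_that("posterior predictive checks detect AR(1) misspecification", {
  # strong residual autocorrelation, moderate series count
  cfg <- generator_config(
    n_species = 15, populations_per_species = 2, n_sites = 8,
    threat_prevalence = c(none = 0.5, exploitation = 0.5),
    true_rho = 0.6, true_sigma_species = 0, true_sigma_population = 0,
    true_sigma_site = 0, missingness = 0, seed = 19)
  sim <- simulate_populations(cfg)
  prep <- sim$truth$model_frame

  with_ar <- fit_model(prep, chains = 1, iter = 400, warmup = 200,
                       seed = 19)
  ppc_ar <- posterior_predictive(with_ar, ndraws = 50)
  expect_lt(abs(ppc_ar$residual_report$mean_residual), 0.05)
  expect_lt(abs(ppc_ar$residual_report$lag1_whitened), 0.1)

  without_ar <- fit_model(prep, chains = 1, iter = 400, warmup = 200,
                          seed = 19, ar1 = FALSE)
  ppc_no <- posterior_predictive(without_ar, ndraws = 50)
  expect_gt(ppc_no$residual_report$lag1_raw, 0.3)
  # replicated data live on the observed scale
  expect_equal(dim(ppc_ar$yrep), c(50, length(with_ar$model_data$y)))
})
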