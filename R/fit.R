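#' Fit the multilevel threat-trend model
#'
#' Samples the joint posterior of the Gaussian model of centred log
#' abundance: `y ~ Normal(mu, sigma)` with
#' `mu = X beta + year * (rS + rP + rL) + rho * eps[t-1]`, where `X` is the
#' threat-combination design, `rS`/`rP` are independent noncentered random
#' year slopes for species and populations, `rL` are site slopes correlated
#' through the Cholesky factor of the Haversine proximity matrix, and `eps`
#' is the lagged within-series residual of the linear predictor (AR(1);
#' the first observation of a series has no lag term). Priors:
#' `beta, z ~ Normal(0, 1)`, all scales `~ Exponential(1)`,
#' `rho ~ Normal(0, 0.25)`. Sampling uses the package's adaptive
#' Hamiltonian Monte Carlo sampler.
#'
#' The defaults (4 chains x 5000 iterations, 2500 warmup) are the
#' full-scale analysis profile; desk-scale work typically uses
#' `chains = 2, iter = 1500, warmup = 750`.
#'
#' @param prepared Long observation tibble from [prepare_series()].
#' @param design Optional [build_design()] result (rebuilt against the
#'   internally sorted observations); defaults to the design enumerated
#'   from the observed threat sets.
#' @param proximity Optional [build_site_proximity()] result; defaults to
#'   the proximity matrix of the observed sites.
#' @param chains,iter,warmup MCMC settings; `warmup < iter`.
#' @param seed Integer seed (chain `c` uses `seed + c`).
#' @param ar1 Include the AR(1) residual term (default `TRUE`).
#' @param control Sampler tuning overrides (`target_accept`, `int_time`,
#'   `max_leapfrog`).
#' @return An object of class `mtfit` with the posterior draws, the design,
#'   the model frame, and sampler reports. Use [tidy()]/[glance()] for
#'   summaries and [diagnostics()] for convergence checks.
#' @export
fit_model <- function(prepared, design = NULL, proximity = NULL,
                      chains = 4, iter = 5000, warmup = iter / 2,
                      seed = 1, ar1 = TRUE, control = list()) {
  if (warmup >= iter) abort("warmup must be smaller than iter")
  if (chains < 1) abort("at least one chain is required")
  md <- make_model_data(prepared, design, proximity, ar1 = ar1)
  pt <- param_template(md)
  lp_grad <- function(theta) log_posterior_grad(theta, md, pt)

  chain_res <- purrr::map(seq_len(chains), function(ch) {
    set.seed(seed + ch)
    init <- rnorm(pt$n, 0, 0.1)
    init[pt$idx$log_sigma] <- log(max(0.2, sd(md$y)))
    hmc_chain(lp_grad, init, iter = iter, warmup = floor(warmup),
              seed = seed + ch, control = control)
  })

  draws <- purrr::map(chain_res, function(cr) {
    colnames(cr$draws) <- pt$names
    cr$draws
  })

  structure(
    list(
      draws = draws, param_names = pt$names, param_index = pt$idx,
      model_data = md, design = md$design, proximity = md$proximity,
      spec = list(chains = chains, iter = iter, warmup = floor(warmup),
                  seed = seed, ar1 = ar1,
                  priors = list(beta = "Normal(0,1)", z = "Normal(0,1)",
                                sigma = "Exponential(1)",
                                rho = "Normal(0,0.25)")),
      method = "hmc",
      sampler = list(
        accept_rate = purrr::map_dbl(chain_res, "accept_rate"),
        stepsize = purrr::map_dbl(chain_res, "stepsize"),
        divergences = purrr::map_int(chain_res, "divergences")
      )
    ),
    class = "mtfit"
  )
}

#' Fast conjugate fit of the fixed-effect Gaussian core
#'
#' Exact posterior draws of the fixed effects for the reduced model
#' `y ~ Normal(X beta, sigma)` with `beta ~ Normal(0, 1)` and `sigma` fixed
#' at its maximum-likelihood value (no random slopes, no AR(1)). The
#' posterior is the standard ridge-form multivariate normal, so thousands of
#' replicate "fits" cost milliseconds; this is the posterior-re-simulation
#' backend for classifier calibration experiments. The result supports the
#' same trend/classification tooling as [fit_model()] (conditional
#' predictions only).
#'
#' @inheritParams fit_model
#' @param ndraws Number of posterior draws, default 2000.
#' @param seed Integer seed.
#' @return An `mtfit` (method `"conjugate"`, single chain).
#' @export
fit_fixed_effects <- function(prepared, design = NULL, ndraws = 2000,
                              seed = 1) {
  md <- make_model_data(prepared, design, proximity = NULL, ar1 = FALSE)
  X <- md$X
  y <- md$y
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  # sigma at its MLE under the ridge mean
  A0 <- XtX + diag(p) # unit-information start for the mean
  b0 <- solve(A0, Xty)
  sigma2 <- sum((y - drop(X %*% b0))^2) / n
  A <- XtX / sigma2 + diag(p)
  R <- chol(A)
  mean_beta <- backsolve(R, forwardsolve(t(R), Xty / sigma2))
  set.seed(seed)
  Z <- matrix(rnorm(ndraws * p), ndraws, p)
  B <- t(mean_beta + backsolve(R, t(Z)))
  colnames(B) <- paste0("beta[", colnames(X), "]")
  draws <- cbind(B, `log_sigma` = log(sqrt(sigma2)))
  pt_idx <- list(beta = seq_len(p), log_sigma = p + 1L)

  structure(
    list(
      draws = list(draws), param_names = colnames(draws),
      param_index = pt_idx, model_data = md, design = md$design,
      proximity = md$proximity,
      spec = list(chains = 1, iter = ndraws, warmup = 0, seed = seed,
                  ar1 = FALSE),
      method = "conjugate",
      sampler = list(accept_rate = 1, stepsize = NA_real_,
                     divergences = 0L)
    ),
    class = "mtfit"
  )
}

# stacked post-warmup draws (draws x params) across chains
draw_matrix <- function(fit) {
  do.call(rbind, fit$draws)
}

# evenly spaced deterministic subsample of draw row indices
draw_subsample <- function(fit, ndraws = NULL) {
  total <- sum(purrr::map_int(fit$draws, nrow))
  if (is.null(ndraws) || ndraws >= total) return(seq_len(total))
  unique(round(seq(1, total, length.out = ndraws)))
}

# named natural-scale parameter draws for one component
beta_draws <- function(fit, cols = NULL) {
  B <- draw_matrix(fit)[, fit$param_index$beta, drop = FALSE]
  colnames(B) <- sub("^beta\\[(.*)\\]$", "\\1", colnames(B))
  if (!is.null(cols)) {
    missing_cols <- setdiff(cols, colnames(B))
    if (length(missing_cols) > 0) {
      abort(sprintf("unknown design column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    B <- B[, cols, drop = FALSE]
  }
  B
}

# random-slope draws per group level (draws x levels), on the slope scale
random_slope_draws <- function(fit, which = c("species", "population",
                                              "site")) {
  which <- match.arg(which)
  if (fit$method != "hmc") {
    abort("random effects are only available for full model fits")
  }
  M <- draw_matrix(fit)
  idx <- fit$param_index
  md <- fit$model_data
  switch(which,
    species = exp(M[, idx$log_sigma_S]) * M[, idx$zS, drop = FALSE],
    population = exp(M[, idx$log_sigma_P]) * M[, idx$zP, drop = FALSE],
    site = {
      Z <- M[, idx$zL, drop = FALSE]
      exp(M[, idx$log_sigma_L]) * t(md$L %*% t(Z))
    }
  )
}

#' @export
print.mtfit <- function(x, ...) {
  nd <- sum(purrr::map_int(x$draws, nrow))
  cat(sprintf("<mtfit> %s fit: %d observations, %d fixed effects, %d draws (%d chain%s)\n",
              x$method, length(x$model_data$y), ncol(x$model_data$X), nd,
              x$spec$chains, if (x$spec$chains > 1) "s" else ""))
  if (x$method == "hmc") {
    cat(sprintf("  accept rate %.2f, divergences %d\n",
                mean(x$sampler$accept_rate), sum(x$sampler$divergences)))
  }
  invisible(x)
}
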