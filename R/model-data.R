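# Internal assembly of the model frame: response, design, grouping indices,
# lag pointers and the site-slope Cholesky factor. Observations are sorted
# by (population, year) so the AR(1) lag structure is well defined and the
# log density is invariant to the input row order.
make_model_data <- function(prepared, design = NULL, proximity = NULL,
                            ar1 = TRUE) {
  needed <- c("population_id", "species_id", "site_id", "centered_year",
              "centered_log_abundance", "threats")
  missing_cols <- setdiff(needed, names(prepared))
  if (length(missing_cols) > 0) {
    abort(sprintf("prepared data lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ord <- order(prepared$population_id, prepared$year %||%
                 prepared$centered_year, prepared$centered_year)
  prepared <- prepared[ord, , drop = FALSE]
  if (any(!is.finite(prepared$centered_log_abundance))) {
    abort("non-finite response values")
  }

  if (is.null(design)) {
    design <- build_design(prepared)
  } else {
    if (nrow(design$matrix) != nrow(prepared)) {
      abort("design rows do not align with observations")
    }
    design$threats <- purrr::map(prepared$threats,
                                 function(s) sort(unique(s)))
    design$centered_year <- prepared$centered_year
    design <- design_rebuild(design)
  }
  if (is.null(proximity)) {
    proximity <- build_site_proximity(
      dplyr::distinct(prepared, .data$site_id, .data$latitude,
                      .data$longitude)
    )
  }

  species <- factor(prepared$species_id)
  popn <- factor(prepared$population_id)
  site <- factor(prepared$site_id, levels = proximity$site_ids)
  if (anyNA(site)) abort("observation site not present in proximity matrix")

  pop_rows <- !duplicated(popn)

  n <- nrow(prepared)
  first <- !duplicated(popn)
  prev <- c(0L, seq_len(n - 1L))
  prev[first] <- 0L

  list(
    y = prepared$centered_log_abundance,
    X = design$matrix,
    year = prepared$centered_year,
    sp_idx = as.integer(species),
    pop_idx = as.integer(popn),
    site_idx = as.integer(site),
    species_levels = levels(species),
    population_levels = levels(popn),
    site_levels = proximity$site_ids,
    n_species = nlevels(species),
    n_pop = nlevels(popn),
    n_site = length(proximity$site_ids),
    prev = prev,
    first = first,
    L = proximity$chol,
    design = design,
    proximity = proximity,
    prepared = prepared,
    ar1 = ar1,
    # per-population metadata (row-aligned with population_levels)
    pop_meta = {
      m <- prepared[pop_rows, c("population_id", "species_id", "site_id",
                                "threats")]
      m[order(m$population_id), , drop = FALSE]
    }
  )
}

# Parameter vector layout: beta (p), log_sigma, [rho], log_sigma_S,
# log_sigma_P, log_sigma_L, zS, zP, zL.
param_template <- function(md) {
  p <- ncol(md$X)
  nm <- c(paste0("beta[", colnames(md$X), "]"), "log_sigma",
          if (md$ar1) "rho",
          "log_sigma_S", "log_sigma_P", "log_sigma_L",
          paste0("zS[", md$species_levels, "]"),
          paste0("zP[", md$population_levels, "]"),
          paste0("zL[", md$site_levels, "]"))
  idx <- list(beta = seq_len(p))
  pos <- p
  take <- function(k) {
    out <- pos + seq_len(k)
    pos <<- pos + k
    out
  }
  idx$log_sigma <- take(1)
  if (md$ar1) idx$rho <- take(1)
  idx$log_sigma_S <- take(1)
  idx$log_sigma_P <- take(1)
  idx$log_sigma_L <- take(1)
  idx$zS <- take(md$n_species)
  idx$zP <- take(md$n_pop)
  idx$zL <- take(md$n_site)
  list(names = nm, idx = idx, n = pos)
}

unpack_params <- function(theta, md, pt) {
  i <- pt$idx
  list(
    beta = theta[i$beta],
    sigma = exp(theta[i$log_sigma]),
    rho = if (md$ar1) theta[i$rho] else 0,
    sigma_S = exp(theta[i$log_sigma_S]),
    sigma_P = exp(theta[i$log_sigma_P]),
    sigma_L = exp(theta[i$log_sigma_L]),
    zS = theta[i$zS], zP = theta[i$zP], zL = theta[i$zL]
  )
}

#' Noncentered random-slope transform
#'
#' Maps standard-normal draws to random slopes: `r = sigma * z` for
#' independent groups (species, populations) and
#' `r = sigma * (chol_factor %*% z)` when a correlation structure is
#' supplied (site slopes through the Cholesky factor of the proximity
#' matrix). This reparameterisation decorrelates the scale hyperparameters
#' from the slopes in the posterior.
#'
#' @param z Numeric vector of standard-normal draws.
#' @param sigma Nonnegative scale.
#' @param chol_factor Optional lower-triangular matrix (dimension must match
#'   `length(z)`).
#' @return Numeric vector of random slopes.
#' @export
noncentered_transform <- function(z, sigma, chol_factor = NULL) {
  if (sigma < 0) abort("sigma must be nonnegative")
  if (is.null(chol_factor)) return(sigma * z)
  if (!is.matrix(chol_factor) || nrow(chol_factor) != length(z) ||
      ncol(chol_factor) != length(z)) {
    abort("chol_factor dimensions do not match z")
  }
  sigma * drop(chol_factor %*% z)
}

# linear predictor eta = X beta + year * (rS + rP + rL)
linear_predictor <- function(md, par) {
  rS <- par$sigma_S * par$zS
  rP <- par$sigma_P * par$zP
  rL <- par$sigma_L * drop(md$L %*% par$zL)
  drop(md$X %*% par$beta) +
    md$year * (rS[md$sp_idx] + rP[md$pop_idx] + rL[md$site_idx])
}

# log posterior and gradient on the unconstrained scale; the workhorse of
# the HMC sampler. Returns list(lp, grad).
log_posterior_grad <- function(theta, md, pt, grad = TRUE) {
  par <- unpack_params(theta, md, pt)
  n <- length(md$y)
  eta <- linear_predictor(md, par)
  eps <- md$y - eta
  eps_prev <- c(0, eps)[md$prev + 1L]
  e <- eps - par$rho * eps_prev
  s2 <- par$sigma^2

  ll <- -n * log(par$sigma) - sum(e^2) / (2 * s2) - n * 0.5 * log(2 * pi)
  lp <- ll -
    sum(par$beta^2) / 2 -
    sum(par$zS^2) / 2 - sum(par$zP^2) / 2 - sum(par$zL^2) / 2 -
    (par$sigma + par$sigma_S + par$sigma_P + par$sigma_L) +
    (log(par$sigma) + log(par$sigma_S) + log(par$sigma_P) +
       log(par$sigma_L)) -
    if (md$ar1) par$rho^2 / (2 * 0.25^2) else 0

  if (!grad) return(list(lp = lp))

  # d loglik / d eta
  g <- e / s2
  lagged <- which(md$prev > 0L)
  if (par$rho != 0 && length(lagged)) {
    g[md$prev[lagged]] <- g[md$prev[lagged]] - par$rho * e[lagged] / s2
  }

  gr <- numeric(pt$n)
  gr[pt$idx$beta] <- drop(crossprod(md$X, g)) - par$beta
  # d loglik / d log sigma
  gr[pt$idx$log_sigma] <- sum(e^2) / s2 - n - par$sigma + 1
  if (md$ar1) {
    gr[pt$idx$rho] <- sum(e * eps_prev) / s2 - par$rho / 0.25^2
  }
  w <- md$year * g
  bS <- drop(rowsum(w, md$sp_idx))
  bP <- drop(rowsum(w, md$pop_idx))
  bL_raw <- numeric(md$n_site)
  agg <- rowsum(w, md$site_idx)
  bL_raw[as.integer(rownames(agg))] <- agg
  gr[pt$idx$zS] <- par$sigma_S * bS - par$zS
  gr[pt$idx$zP] <- par$sigma_P * bP - par$zP
  LtB <- drop(crossprod(md$L, bL_raw))
  gr[pt$idx$zL] <- par$sigma_L * LtB - par$zL
  gr[pt$idx$log_sigma_S] <- par$sigma_S * sum(par$zS * bS) - par$sigma_S + 1
  gr[pt$idx$log_sigma_P] <- par$sigma_P * sum(par$zP * bP) - par$sigma_P + 1
  gr[pt$idx$log_sigma_L] <- par$sigma_L * sum(par$zL * LtB) - par$sigma_L + 1

  list(lp = lp, grad = gr)
}

#' Evaluate the model's joint log density at a fixed parameter point
#'
#' Returns the log likelihood (sum of Gaussian log densities of centred log
#' abundance around `mu = X beta + year * (rS + rP + rL) + rho *
#' eps[t-1]`), optionally plus the log prior, at user-supplied natural-scale
#' parameters. Exposed so the density can be checked against independent
#' brute-force evaluation.
#'
#' @param fit A fitted model from [fit_model()], or the internal model-data
#'   list.
#' @param params Named list: `beta` (one per design column), `sigma`, `rho`,
#'   `sigma_S`, `sigma_P`, `sigma_L`, `zS`, `zP`, `zL`. Missing random-slope
#'   entries default to zero.
#' @param include_prior Add the log prior (and no Jacobian terms; this is
#'   the natural-scale density), default `FALSE`.
#' @return Scalar log density.
#' @export
model_log_density <- function(fit, params, include_prior = FALSE) {
  md <- if (inherits(fit, "mtfit")) fit$model_data else fit
  par <- list(
    beta = params$beta,
    sigma = params$sigma,
    rho = params$rho %||% 0,
    sigma_S = params$sigma_S %||% 0,
    sigma_P = params$sigma_P %||% 0,
    sigma_L = params$sigma_L %||% 0,
    zS = params$zS %||% numeric(md$n_species),
    zP = params$zP %||% numeric(md$n_pop),
    zL = params$zL %||% numeric(md$n_site)
  )
  if (length(par$beta) != ncol(md$X)) {
    abort("beta length does not match the design")
  }
  eta <- linear_predictor(md, par)
  eps <- md$y - eta
  eps_prev <- c(0, eps)[md$prev + 1L]
  mu <- eta + par$rho * eps_prev
  ll <- sum(dnorm(md$y, mu, par$sigma, log = TRUE))
  if (!include_prior) return(ll)
  dexp_log <- function(x) if (x > 0) -x else -Inf
  ll + sum(dnorm(par$beta, 0, 1, log = TRUE)) +
    sum(dnorm(c(par$zS, par$zP, par$zL), 0, 1, log = TRUE)) +
    dexp_log(par$sigma) + dexp_log(par$sigma_S) + dexp_log(par$sigma_P) +
    dexp_log(par$sigma_L) +
    dnorm(par$rho, 0, 0.25, log = TRUE)
}
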