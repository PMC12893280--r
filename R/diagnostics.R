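# split-Rhat and effective sample size (BDA3-style, Geyer initial positive
# sequence), computed from a list of per-chain draw vectors

split_chains <- function(chains) {
  unlist(purrr::map(chains, function(x) {
    n <- length(x)
    h <- floor(n / 2)
    list(x[seq_len(h)], x[(n - h + 1):n])
  }), recursive = FALSE)
}

rhat_value <- function(chains) {
  sc <- split_chains(chains)
  m <- length(sc)
  n <- length(sc[[1]])
  if (n < 2) return(NA_real_)
  means <- purrr::map_dbl(sc, mean)
  vars <- purrr::map_dbl(sc, var)
  W <- mean(vars)
  B <- n * var(means)
  vhat <- (n - 1) / n * W + B / n
  if (W <= 0) return(ifelse(B <= 1e-300, 1, Inf))
  sqrt(vhat / W)
}

ess_value <- function(chains) {
  sc <- split_chains(chains)
  m <- length(sc)
  n <- length(sc[[1]])
  if (n < 4) return(NA_real_)
  means <- purrr::map_dbl(sc, mean)
  vars <- purrr::map_dbl(sc, var)
  W <- mean(vars)
  vhat <- (n - 1) / n * W + n * var(means) / n
  if (vhat <= 0) return(NA_real_)
  max_lag <- min(n - 2, 500)
  acov <- purrr::map(sc, function(x) {
    a <- acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
             demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- purrr::map_dbl(seq_len(max_lag), function(t) {
    1 - (W - mean(purrr::map_dbl(acov, ~ .x[t + 1]))) / vhat
  })
  # Geyer: sum consecutive pairs while positive
  total <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    total <- total + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * total)
  min(ess, m * n)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split-Rhat and effective sample size per parameter and reports
#' the post-warmup divergence count. Parameters with Rhat above 1.01 are
#' flagged.
#'
#' @param fit An `mtfit` from [fit_model()].
#' @param pars Optional regular expression selecting parameters (default:
#'   fixed effects and scale/correlation parameters, not the standardised
#'   random slopes).
#' @param rhat_threshold Flagging threshold, default 1.01.
#' @return Tibble with `parameter`, `rhat`, `ess`, `flagged`; the total
#'   divergence count is attached as attribute `divergences`. With a single
#'   chain Rhat is omitted (`NA`) with a warning.
#' @export
diagnostics <- function(fit, pars = NULL, rhat_threshold = 1.01) {
  if (is.null(pars)) pars <- "^beta\\[|^log_sigma|^rho$"
  sel <- grep(pars, fit$param_names, value = TRUE)
  single <- length(fit$draws) < 2
  if (single) {
    warn("single chain: split-Rhat is computed from within-chain halves only")
  }
  res <- purrr::map(sel, function(pn) {
    chains <- purrr::map(fit$draws, ~ .x[, pn])
    tibble::tibble(
      parameter = pn,
      rhat = rhat_value(chains),
      ess = ess_value(chains)
    )
  })
  out <- dplyr::bind_rows(res)
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_threshold
  attr(out, "divergences") <- sum(fit$sampler$divergences)
  out
}

#' Posterior predictive replication and residual report
#'
#' Draws replicated centred log abundances from the fitted model (per
#' posterior draw: `yrep ~ Normal(mu, sigma)` with the AR(1) term computed
#' from the observed lagged residuals) and summarises residual behaviour at
#' the posterior median parameters: mean residual, variance constancy
#' (first/second-half variance ratio), and the pooled lag-1 autocorrelation
#' of both the raw linear-predictor residuals and the AR(1)-whitened
#' residuals.
#'
#' @param fit An `mtfit` from [fit_model()].
#' @param ndraws Number of replicated datasets, default 200.
#' @return A list of class `mt_ppc`: `yrep` (ndraws x n matrix),
#'   `residual_report` (one-row tibble), `observed` (the data vector).
#' @export
posterior_predictive <- function(fit, ndraws = 200) {
  md <- fit$model_data
  M <- draw_matrix(fit)
  rows <- draw_subsample(fit, ndraws)
  n <- length(md$y)

  yrep <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    theta <- M[rows[i], ]
    par <- unpack_draw(fit, theta)
    eta <- linear_predictor(md, par)
    eps <- md$y - eta
    eps_prev <- c(0, eps)[md$prev + 1L]
    mu <- eta + par$rho * eps_prev
    yrep[i, ] <- rnorm(n, mu, par$sigma)
  }

  med_theta <- apply(M, 2, median)
  par <- unpack_draw(fit, med_theta)
  eta <- linear_predictor(md, par)
  eps <- md$y - eta
  eps_prev <- c(0, eps)[md$prev + 1L]
  white <- eps - par$rho * eps_prev
  lag_ok <- md$prev > 0L
  lag1 <- function(x) {
    a <- x[lag_ok]
    b <- x[md$prev[lag_ok]]
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  half <- seq_len(floor(n / 2))
  report <- tibble::tibble(
    mean_residual = mean(white),
    sd_residual = sd(white),
    variance_ratio = var(white[half]) / var(white[-half]),
    lag1_raw = lag1(eps),
    lag1_whitened = lag1(white),
    rho_median = par$rho,
    sigma_median = par$sigma
  )
  structure(list(yrep = yrep, residual_report = report, observed = md$y),
            class = "mt_ppc")
}

# natural-scale parameter list from one draw row
unpack_draw <- function(fit, theta) {
  idx <- fit$param_index
  md <- fit$model_data
  grab <- function(nm, default) {
    if (!is.null(idx[[nm]])) unname(theta[idx[[nm]]]) else default
  }
  list(
    beta = unname(theta[idx$beta]),
    sigma = exp(grab("log_sigma", 0)),
    rho = grab("rho", 0),
    sigma_S = exp(grab("log_sigma_S", -Inf)),
    sigma_P = exp(grab("log_sigma_P", -Inf)),
    sigma_L = exp(grab("log_sigma_L", -Inf)),
    zS = grab("zS", numeric(md$n_species)),
    zP = grab("zP", numeric(md$n_pop)),
    zL = grab("zL", numeric(md$n_site))
  )
}

#' @export
print.mt_ppc <- function(x, ...) {
  cat(sprintf("<mt_ppc> %d replicated datasets of %d observations\n",
              nrow(x$yrep), ncol(x$yrep)))
  print(x$residual_report)
  invisible(x)
}
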