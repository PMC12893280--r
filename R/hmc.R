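# Adaptive Hamiltonian Monte Carlo with dual-averaging step-size tuning and
# diagonal mass-matrix adaptation (Stan-like warmup phases). Trajectory
# length is set from a target integration time and jittered to avoid
# resonance. Kept dependency-free because no MCMC backend ships with the
# package's environment.

hmc_chain <- function(lp_grad, init, iter, warmup, seed,
                      control = list()) {
  set.seed(seed)
  ctl <- utils::modifyList(list(
    target_accept = 0.8, int_time = 3.0, max_leapfrog = 128,
    init_stepsize = 0.1, divergence_threshold = 1000
  ), control)

  d <- length(init)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) abort("non-finite log density at initial point")
  inv_mass <- rep(1, d)

  # dual averaging state (Hoffman & Gelman 2014 defaults)
  da_init <- function(eps0) {
    list(mu = log(10 * eps0), log_eps = log(eps0), log_eps_bar = 0,
         h_bar = 0, m = 0, gamma = 0.05, t0 = 10, kappa = 0.75)
  }
  da_update <- function(da, accept, target) {
    da$m <- da$m + 1
    da$h_bar <- (1 - 1 / (da$m + da$t0)) * da$h_bar +
      (target - accept) / (da$m + da$t0)
    da$log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
    w <- da$m^(-da$kappa)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }

  leapfrog <- function(theta, r, eps, L, grad0) {
    g <- grad0
    r <- r + 0.5 * eps * g
    for (l in seq_len(L)) {
      theta <- theta + eps * inv_mass * r
      st <- lp_grad(theta)
      if (!is.finite(st$lp)) return(list(ok = FALSE))
      g <- st$grad
      if (l < L) r <- r + eps * g
    }
    r <- r + 0.5 * eps * g
    list(ok = TRUE, theta = theta, r = r, state = st)
  }

  eps <- ctl$init_stepsize / sqrt(d)^(1 / 4)
  # crude step-size initialisation: adjust until one-step accept ~ 0.5
  for (k in 1:20) {
    r0 <- rnorm(d) / sqrt(inv_mass)
    stp <- leapfrog(theta, r0, eps, 1L, cur$grad)
    if (!stp$ok) {
      eps <- eps / 2
      next
    }
    h0 <- cur$lp - 0.5 * sum(r0^2 * inv_mass)
    h1 <- stp$state$lp - 0.5 * sum(stp$r^2 * inv_mass)
    a <- exp(min(0, h1 - h0))
    if (a > 0.8) eps <- eps * 1.6 else if (a < 0.3) eps <- eps / 1.6
    else break
  }
  da <- da_init(eps)

  # warmup phases: step-size only / variance accumulation / step-size only
  p1 <- max(25L, floor(0.15 * warmup))
  p3 <- max(25L, floor(0.1 * warmup))
  var_lo <- min(p1 + 1L, warmup)
  var_hi <- max(var_lo, warmup - p3)

  draws <- matrix(NA_real_, iter - warmup, d)
  acc_sum <- 0
  divergences <- 0L
  vacc_n <- 0
  vacc_mean <- numeric(d)
  vacc_m2 <- numeric(d)

  for (it in seq_len(iter)) {
    in_warmup <- it <= warmup
    eps_it <- if (in_warmup) exp(da$log_eps) else exp(da$log_eps_bar)
    L <- max(1L, min(ctl$max_leapfrog, ceiling(ctl$int_time / eps_it)))
    L <- sample(seq(ceiling(L / 2), L), 1L) # jitter to avoid resonance
    r0 <- rnorm(d) / sqrt(inv_mass)
    h0 <- cur$lp - 0.5 * sum(r0^2 * inv_mass)
    stp <- leapfrog(theta, r0, eps_it, L, cur$grad)
    if (stp$ok) {
      h1 <- stp$state$lp - 0.5 * sum(stp$r^2 * inv_mass)
      dh <- h1 - h0
      if (!is.finite(dh) || dh < -ctl$divergence_threshold) {
        if (!in_warmup) divergences <- divergences + 1L
        a <- 0
      } else {
        a <- exp(min(0, dh))
        if (runif(1) < a) {
          theta <- stp$theta
          cur <- stp$state
        }
      }
    } else {
      if (!in_warmup) divergences <- divergences + 1L
      a <- 0
    }

    if (in_warmup) {
      da <- da_update(da, a, ctl$target_accept)
      if (it >= var_lo && it <= var_hi) {
        vacc_n <- vacc_n + 1
        delta <- theta - vacc_mean
        vacc_mean <- vacc_mean + delta / vacc_n
        vacc_m2 <- vacc_m2 + delta * (theta - vacc_mean)
      }
      if (it == var_hi && vacc_n > 10) {
        v <- vacc_m2 / (vacc_n - 1)
        # regularise towards unit scale as Stan does
        v <- (vacc_n / (vacc_n + 5)) * v + (5 / (vacc_n + 5)) * 1e-3
        inv_mass <- pmax(v, 1e-8)
        da <- da_init(exp(da$log_eps))
      }
      if (it == warmup) da$log_eps_bar <- da$log_eps_bar
    } else {
      acc_sum <- acc_sum + a
      draws[it - warmup, ] <- theta
    }
  }

  list(draws = draws, stepsize = exp(da$log_eps_bar),
       accept_rate = acc_sum / max(1, iter - warmup),
       divergences = divergences, inv_mass = inv_mass)
}
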