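## Static-trajectory Hamiltonian Monte Carlo with dual-averaging step-size
## adaptation and diagonal mass-matrix estimation. The posterior blocks of
## the transition model are smooth, moderate-dimensional and standardized by
## the non-centered parameterization, which this sampler is tuned for.

## lp_grad(theta) must return list(lp = scalar, grad = vector).
hmcSample <- function(lp_grad, n_par, chains = 4L, warmup = 500L,
                      sampling = 1000L, seed = 1L, L_max = 20L,
                      target_accept = 0.8, init_fun = NULL,
                      divergence_energy = 1000) {
  stopifnot(n_par >= 1L, chains >= 1L, warmup >= 50L, sampling >= 1L)
  draws <- vector("list", chains)
  divergences <- integer(chains)
  step_sizes <- numeric(chains)
  accept_rates <- numeric(chains)

  withLocalSeed(seed, {
    for (ch in seq_len(chains)) {
      theta <- if (is.null(init_fun)) stats::rnorm(n_par, 0, 0.3) else init_fun(ch)
      cur <- lp_grad(theta)
      if (!is.finite(cur$lp)) stopf("non-finite log posterior at initial values")
      inv_mass <- rep(1, n_par)
      sqrt_mass <- rep(1, n_par)

      ## dual averaging state
      eps <- findEpsilon(lp_grad, theta, cur, inv_mass, sqrt_mass)
      mu <- log(10 * eps)
      log_eps_bar <- 0; H_bar <- 0; da_count <- 0
      gamma <- 0.05; t0 <- 10; kappa <- 0.75

      mass_at <- floor(warmup * 0.75)
      mass_from <- floor(warmup * 0.25) + 1L
      warm_buf <- matrix(0, mass_at - mass_from + 1L, n_par)

      ch_draws <- matrix(0, sampling, n_par)
      n_div <- 0L; n_acc <- 0
      total <- warmup + sampling
      for (it in seq_len(total)) {
        adapt <- it <= warmup
        p0 <- stats::rnorm(n_par) * sqrt_mass
        L <- sample.int(L_max, 1L)
        L <- max(L, floor(L_max / 2))
        H0 <- -cur$lp + 0.5 * sum(p0 * p0 * inv_mass)

        th <- theta; p <- p0; gr <- cur$grad
        divergent <- FALSE
        p <- p + 0.5 * eps * gr
        for (l in seq_len(L)) {
          th <- th + eps * p * inv_mass
          prop <- lp_grad(th)
          if (!is.finite(prop$lp)) { divergent <- TRUE; break }
          p <- p + (if (l < L) eps else 0.5 * eps) * prop$grad
        }
        if (!divergent) {
          H1 <- -prop$lp + 0.5 * sum(p * p * inv_mass)
          dH <- H1 - H0
          if (!is.finite(dH) || dH > divergence_energy) divergent <- TRUE
        }
        if (divergent) {
          alpha <- 0
          if (!adapt) n_div <- n_div + 1L
        } else {
          alpha <- min(1, exp(-dH))
          if (stats::runif(1) < alpha) {
            theta <- th; cur <- prop
          }
        }
        if (adapt) {
          da_count <- da_count + 1
          H_bar <- (1 - 1 / (da_count + t0)) * H_bar +
            (target_accept - alpha) / (da_count + t0)
          log_eps <- mu - sqrt(da_count) / gamma * H_bar
          w <- da_count^(-kappa)
          log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
          eps <- exp(log_eps)
          if (it >= mass_from && it <= mass_at)
            warm_buf[it - mass_from + 1L, ] <- theta
          if (it == mass_at) {
            v <- apply(warm_buf, 2L, stats::var)
            nw <- nrow(warm_buf)
            v <- (nw / (nw + 5)) * v + (5 / (nw + 5)) * 1e-3  # regularized
            inv_mass <- pmax(v, 1e-8)
            sqrt_mass <- 1 / sqrt(inv_mass)
            eps <- findEpsilon(lp_grad, theta, cur, inv_mass, sqrt_mass)
            mu <- log(10 * eps)
            log_eps_bar <- 0; H_bar <- 0; da_count <- 0
          }
          if (it == warmup) eps <- exp(log_eps_bar)
        } else {
          n_acc <- n_acc + alpha
          ch_draws[it - warmup, ] <- theta
        }
      }
      draws[[ch]] <- ch_draws
      divergences[ch] <- n_div
      step_sizes[ch] <- eps
      accept_rates[ch] <- n_acc / sampling
    }
  })
  list(draws = draws, divergences = divergences, step_size = step_sizes,
       accept_rate = accept_rates)
}

## Crude initial step size: double/halve until the one-step acceptance
## probability crosses 0.5 (Hoffman & Gelman's heuristic).
findEpsilon <- function(lp_grad, theta, cur, inv_mass, sqrt_mass, eps = 0.1) {
  oneStep <- function(eps) {
    p0 <- stats::rnorm(length(theta)) * sqrt_mass
    H0 <- -cur$lp + 0.5 * sum(p0 * p0 * inv_mass)
    p <- p0 + 0.5 * eps * cur$grad
    th <- theta + eps * p * inv_mass
    prop <- lp_grad(th)
    if (!is.finite(prop$lp)) return(-Inf)
    p <- p + 0.5 * eps * prop$grad
    -(-prop$lp + 0.5 * sum(p * p * inv_mass)) + H0
  }
  log_a <- oneStep(eps)
  dir <- if (is.finite(log_a) && log_a > log(0.5)) 1 else -1
  for (i in 1:40) {
    eps <- eps * 2^dir
    log_a <- oneStep(eps)
    if (!is.finite(log_a)) { if (dir > 0) { eps <- eps / 2; break } else next }
    if ((dir == 1 && log_a < log(0.5)) || (dir == -1 && log_a > log(0.5))) break
  }
  max(eps, 1e-8)
}

## Split-Rhat (Gelman et al.): each chain halved, potential scale reduction
## across the 2*chains half-chains. Vectorized over parameters.
splitRhat <- function(chain_list) {
  halves <- list()
  for (d in chain_list) {
    n2 <- floor(nrow(d) / 2)
    halves <- c(halves, list(d[seq_len(n2), , drop = FALSE],
                             d[(nrow(d) - n2 + 1):nrow(d), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1L]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1L]])))
  vars <- vapply(halves, function(d) apply(d, 2L, stats::var),
                 numeric(ncol(halves[[1L]])))
  if (is.null(dim(means))) { means <- matrix(means, 1L); vars <- matrix(vars, 1L) }
  B <- n * apply(means, 1L, stats::var)
  W <- rowMeans(vars)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W < 1e-300] <- 1
  rhat
}

## Effective sample size via Geyer's initial positive sequence on the
## chain-averaged autocorrelation.
essBasic <- function(chain_list, max_lag = 200L) {
  m <- length(chain_list); n <- nrow(chain_list[[1L]]); k <- ncol(chain_list[[1L]])
  max_lag <- min(max_lag, n - 2L)
  ess <- numeric(k)
  for (j in seq_len(k)) {
    acfs <- sapply(chain_list, function(d) {
      stats::acf(d[, j], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    })
    rho <- rowMeans(acfs)
    if (!all(is.finite(rho))) { ess[j] <- m * n; next }
    ## sum consecutive pairs while positive
    tau <- 1; t <- 1L
    while (t + 1L <= length(rho) - 1L) {
      pair <- rho[t + 1L] + rho[t + 2L]
      if (!is.finite(pair) || pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2L
    }
    ess[j] <- m * n / tau
  }
  ess
}
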