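## Approximate leave-one-out cross-validation by Pareto-smoothed importance
## sampling (PSIS), with pseudo-BMA+ and stacking model weights.

## Maximum-likelihood generalized-Pareto fit to positive exceedances, using
## the Zhang & Stephens profile-posterior estimator with the usual weak
## prior regularization of the shape towards 0.5. Returns the shape k
## (positive = heavy tail) and scale sigma.
gpdFit <- function(x) {
  x <- sort(x)
  N <- length(x)
  if (N < 5L || x[N] <= 0) return(list(k = NaN, sigma = NaN))
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[N] / 2
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  ## profile log likelihood; theta and k(theta) share a sign at any optimum
  ## (heavy tails have both negative in this parameterization)
  kt <- vapply(theta, function(b) -mean(log1p(-b * x)), 0)
  ratio <- theta / kt
  ll <- ifelse(is.finite(ratio) & ratio > 0, N * (log(ratio) + kt - 1), -Inf)
  if (!any(is.finite(ll))) return(list(k = NaN, sigma = NaN))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  b <- sum(theta * w)
  if (!is.finite(b) || b == 0) return(list(k = NaN, sigma = NaN))
  k <- mean(log1p(-b * x))          # = -k_ZS; heavy tails give k > 0
  sigma <- -k / b
  k <- (N * k + 10 * 0.5) / (N + 10)
  list(k = k, sigma = sigma)
}

## Quantile of the generalized Pareto distribution (location 0).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

## PSIS-smooth one vector of log importance ratios. Returns the smoothed
## log weights (normalized to max 0) and the Pareto-k diagnostic.
psisSmooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  if (stats::sd(lw) < 1e-12) return(list(lw = lw, k = -Inf))
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1L):S]
  cut_lw <- lw[ord[S - M]]
  exc <- exp(lw[tail_idx]) - exp(cut_lw)
  fit <- gpdFit(exc)
  if (is.finite(fit$k)) {
    p <- (seq_len(M) - 0.5) / M
    sm <- log(exp(cut_lw) + qgpd(p, fit$k, fit$sigma))
    sm <- pmin(sm, 0)
    lw[tail_idx[order(lw[tail_idx])]] <- sm
  }
  list(lw = lw, k = fit$k)
}

#' PSIS leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out cross-validation from the pointwise log-likelihood table of
#' a fit, smoothing each observation's importance ratios with a generalized
#' Pareto fit to the tail. Observations whose Pareto-k diagnostic exceeds
#' 0.7 are reported with a warning, not refitted.
#'
#' @param x A [KolamFit-class] with a stored log-likelihood table, or a
#'   draws x observations log-likelihood matrix.
#' @param k_threshold Diagnostic threshold for warnings (default 0.7).
#' @return A [LooResult-class].
#' @export
psisLoo <- function(x, k_threshold = 0.7) {
  ll <- if (methods::is(x, "KolamFit")) x@loglik else x
  if (!is.matrix(ll) || !nrow(ll)) stopf("a log-likelihood matrix is required")
  if (!all(is.finite(ll))) stopf("log-likelihood table contains non-finite values")
  S <- nrow(ll); n <- ncol(ll)
  if (S < 100L) stopf("at least 100 draws are required for tail smoothing, got %d", S)
  elpd_i <- numeric(n); k_i <- numeric(n); lpd_i <- numeric(n)
  for (j in seq_len(n)) {
    sm <- psisSmooth(-ll[, j])
    lw <- sm$lw
    elpd_i[j] <- logSumExp(lw + ll[, j]) - logSumExp(lw)
    lpd_i[j] <- logSumExp(ll[, j]) - log(S)
    k_i[j] <- sm$k
  }
  n_bad <- sum(is.finite(k_i) & k_i > k_threshold)
  if (n_bad) warnf("%d observation(s) with Pareto k > %.2f; elpd may be unreliable",
                   n_bad, k_threshold)
  methods::new("LooResult", elpd_loo = sum(elpd_i),
               se = sqrt(n * stats::var(elpd_i)),
               p_loo = sum(lpd_i - elpd_i),
               pointwise = data.frame(elpd = elpd_i, lpd = lpd_i, k = k_i),
               n_draws = S)
}

#' Pseudo-BMA+ and stacking weights for a set of models
#'
#' Combines per-model PSIS-LOO pointwise elpd values into model weights:
#' pseudo-BMA weights regularized by the Bayesian bootstrap (Dirichlet
#' reweighting of observations, 1,000 replicates by default) and stacking
#' weights maximizing the summed log of the weighted leave-one-out
#' predictive densities over the simplex. If a single model predicts best on
#' every observation its stacking weight is exactly 1; exact ties are broken
#' toward the uniform vector.
#'
#' @param loos Named list of [LooResult-class] objects sharing the same
#'   observation units.
#' @param n_boot Bayesian-bootstrap replicates for pseudo-BMA+.
#' @param seed Seed for the bootstrap.
#' @return A data.frame with columns `model`, `elpd_loo`, `se`,
#'   `pbma_weight`, `stacking_weight`.
#' @export
modelWeights <- function(loos, n_boot = 1000L, seed = 1L) {
  stopifnot(is.list(loos), length(loos) >= 2L)
  M <- length(loos)
  nm <- names(loos) %||% paste0("model", seq_len(M))
  n <- nrow(loos[[1L]]@pointwise)
  if (any(vapply(loos, function(l) nrow(l@pointwise), 0L) != n))
    stopf("models must share the same observation units")
  elpd <- vapply(loos, function(l) l@pointwise$elpd, numeric(n))

  ## pseudo-BMA+ via Bayesian bootstrap
  pbma <- withLocalSeed(seed, {
    acc <- numeric(M)
    for (b in seq_len(n_boot)) {
      w_obs <- -log(stats::runif(n))
      w_obs <- w_obs / sum(w_obs)
      zb <- n * as.vector(crossprod(w_obs, elpd))
      acc <- acc + exp(zb - max(zb)) / sum(exp(zb - max(zb)))
    }
    acc / n_boot
  })

  ## stacking: maximize sum_n log sum_m w_m exp(elpd_nm) over the simplex
  obj <- function(w) sum(apply(elpd, 1L, function(e) logSumExp(e + log(w))))
  interior <- stackingOptim(elpd)
  vertex_obj <- vapply(seq_len(M), function(m) sum(elpd[, m]), 0)
  best_v <- which.max(vertex_obj)
  stacking <- interior
  if (vertex_obj[best_v] > obj(interior) + 1e-10) {
    stacking <- numeric(M); stacking[best_v] <- 1
  }
  data.frame(model = nm,
             elpd_loo = vapply(loos, methods::slot, 0, "elpd_loo"),
             se = vapply(loos, methods::slot, 0, "se"),
             pbma_weight = pbma, stacking_weight = stacking,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Interior stacking solution via softmax-parameterized BFGS started at the
## uniform vector (exact ties therefore stay uniform).
stackingOptim <- function(elpd) {
  M <- ncol(elpd)
  fn <- function(v) {
    w <- exp(c(v, 0)); w <- w / sum(w)
    -sum(apply(elpd, 1L, function(e) logSumExp(e + log(w))))
  }
  gr <- function(v) {
    w <- exp(c(v, 0)); w <- w / sum(w)
    mx <- apply(elpd, 1L, max)
    p_mat <- exp(elpd - mx)           # row-rescaled; the ratio is invariant
    denom <- as.vector(p_mat %*% w)
    full <- -colSums(p_mat / denom)   # d(-objective)/dw
    J <- diag(w)[, seq_len(M - 1L), drop = FALSE] -
      tcrossprod(w, w[seq_len(M - 1L)])
    as.vector(crossprod(J, full))
  }
  res <- stats::optim(rep(0, M - 1L), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  w <- exp(c(res$par, 0)); w / sum(w)
}

#' @describeIn psisLoo LOO summary.
#' @param object A `LooResult`.
#' @export
setMethod("show", "LooResult", function(object) {
  cat(sprintf("LooResult: elpd_loo = %.2f (se %.2f), p_loo = %.2f over %d observations\n",
              object@elpd_loo, object@se, object@p_loo, nrow(object@pointwise)))
  bad <- sum(is.finite(object@pointwise$k) & object@pointwise$k > 0.7)
  if (bad) cat("  ", bad, "observation(s) with Pareto k > 0.7\n")
})
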