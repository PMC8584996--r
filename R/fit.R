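## Hierarchical Bayesian multinomial-logit transition model.
##
## Every row of each of the four transition matrices (between-space S and
## within-space O, T, D) is a multinomial over its columns, modeled on the
## logit scale with the softmax link and the row's last category as
## reference (logit 0). The linear predictor for artist i and non-reference
## category c of row r is
##
##   eta[i,c] = alpha[r,c] + a[i,r,c] + g[caste(i),r,c] + u[nb(i),r,c]
##              + b_prac[r,c] * z_i + b_nat[r,c] * native_i
##
## with partial pooling a ~ N(0, sigma_artist[r]), g ~ N(0, sigma_caste[r]),
## u ~ N(0, sigma_neigh[r]) (one sigma per term and row, shared across the
## row's categories; optionally shared across rows). Sampling uses the
## non-centered parameterization a = sigma * z_a with z_a ~ N(0, 1).

MATRIX_IDS <- c("S", "O", "T", "D")

matrixInfo <- function(m) {
  switch(m,
         S = list(labels = KOLAM_SPACES, pretty = "across-spaces"),
         O = list(labels = KOLAM_STATE_NAMES[1:6], pretty = "orthogonal"),
         T = list(labels = KOLAM_STATE_NAMES[7:10], pretty = "transitional"),
         D = list(labels = KOLAM_STATE_NAMES[11:14], pretty = "diagonal"),
         stopf("unknown matrix id '%s'", m))
}

getCountArray <- function(design, m) {
  if (m == "S") design@counts@S else design@counts@W[[m]]
}

## Active (non-structural-zero) column sets per row of a matrix.
activeCats <- function(m, n_cat, structural_zeros) {
  act <- rep(list(seq_len(n_cat)), if (m == "S") 3L else n_cat)
  if (structural_zeros && m == "S") {
    act[[1L]] <- c(1L, 2L)  # O row: D unreachable
    act[[3L]] <- c(2L, 3L)  # D row: O unreachable
  }
  act
}

## Build the data, parameter layout and log-posterior/gradient closure for
## one transition matrix.
buildBlock <- function(design, model, priors, m) {
  info <- matrixInfo(m)
  Yarr <- getCountArray(design, m)
  R <- dim(Yarr)[2L]; C <- dim(Yarr)[3L]
  n <- length(design@artist_ids)
  terms <- model@terms
  act <- activeCats(m, C, model@structural_zeros)

  gidx <- design@caste_index; Gn <- design@n_castes
  kidx <- design@neighborhood_index; Kn <- design@n_neighborhoods
  z <- design@z_practice; nat <- as.numeric(design@native)

  has <- function(t) t %in% terms
  rows <- vector("list", R)
  nm <- character(0)
  prior_sd <- numeric(0)
  pos <- 0L
  take <- function(k, names_, sd_) {
    idx <- pos + seq_len(k)
    pos <<- pos + k
    nm <<- c(nm, names_)
    prior_sd <<- c(prior_sd, rep(sd_, k))
    idx
  }
  for (r in seq_len(R)) {
    a <- act[[r]]
    Yact <- matrix(Yarr[, r, a], n, length(a))
    forb <- setdiff(seq_len(C), a)
    if (length(forb) && any(Yarr[, r, forb] > 0))
      stopf("matrix %s row %s has counts in a structural-zero cell", m, info$labels[r])
    K <- length(a) - 1L
    rl <- info$labels[r]
    cl <- info$labels[a[seq_len(K)]]
    lay <- list(active = a, K = K, Yact = Yact,
                Yfree = Yact[, seq_len(K), drop = FALSE],
                Ntot = rowSums(Yact))
    lay$alpha <- take(K, sprintf("%s.%s.alpha.%s", m, rl, cl), priors@intercept_sd)
    if (has("practice"))
      lay$bp <- take(K, sprintf("%s.%s.b_prac.%s", m, rl, cl), priors@slope_sd)
    if (has("nativity"))
      lay$bn <- take(K, sprintf("%s.%s.b_nat.%s", m, rl, cl), priors@slope_sd)
    if (has("artist"))
      lay$za <- matrix(take(n * K, sprintf("%s.%s.z_a.%s", m, rl,
                                           outer(design@artist_ids, cl, paste, sep = ".")), 1), n, K)
    if (has("caste"))
      lay$zc <- matrix(take(Gn * K, sprintf("%s.%s.z_c.%s", m, rl,
                                            outer(seq_len(Gn), cl, paste, sep = ".")), 1), Gn, K)
    if (has("neighborhood"))
      lay$zu <- matrix(take(Kn * K, sprintf("%s.%s.z_u.%s", m, rl,
                                            outer(seq_len(Kn), cl, paste, sep = ".")), 1), Kn, K)
    rows[[r]] <- lay
  }
  shared <- model@sigma_sharing == "matrix"
  nsig <- if (shared) 1L else R
  siglab <- if (shared) "all" else info$labels
  ls <- list()
  for (t in c("artist", "caste", "neighborhood")) {
    if (has(t)) {
      short <- c(artist = "sigma_artist", caste = "sigma_caste",
                 neighborhood = "sigma_neigh")[[t]]
      ls[[t]] <- take(nsig, sprintf("%s.%s.log_%s", m, siglab, short), NA_real_)
    }
  }
  n_par <- pos
  is_ls <- is.na(prior_sd)
  norm_sd <- prior_sd; norm_sd[is_ls] <- 1  # placeholder, masked below
  s0 <- priors@sigma_scale
  lsrow <- function(t, r) if (shared) ls[[t]][1L] else ls[[t]][r]

  lp_grad <- function(th) {
    lp <- 0
    grad <- numeric(n_par)
    for (r in seq_len(R)) {
      lay <- rows[[r]]
      K <- lay$K
      eta <- matrix(th[lay$alpha], n, K, byrow = TRUE)
      if (!is.null(lay$za)) {
        sa <- exp(th[lsrow("artist", r)])
        ZA <- matrix(th[lay$za], n, K)
        eta <- eta + sa * ZA
      }
      if (!is.null(lay$zc)) {
        sc <- exp(th[lsrow("caste", r)])
        ZC <- matrix(th[lay$zc], Gn, K)
        eta <- eta + sc * ZC[gidx, , drop = FALSE]
      }
      if (!is.null(lay$zu)) {
        su <- exp(th[lsrow("neighborhood", r)])
        ZU <- matrix(th[lay$zu], Kn, K)
        eta <- eta + su * ZU[kidx, , drop = FALSE]
      }
      if (!is.null(lay$bp)) eta <- eta + tcrossprod(z, th[lay$bp])
      if (!is.null(lay$bn)) eta <- eta + tcrossprod(nat, th[lay$bn])

      mx <- eta[, 1L]
      if (K > 1L) for (j in 2:K) mx <- pmax(mx, eta[, j])
      mx <- pmax(mx, 0)
      lse <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
      lp <- lp + sum(lay$Yfree * eta) - sum(lay$Ntot * lse)
      P <- exp(eta - lse)
      G <- lay$Yfree - lay$Ntot * P
      grad[lay$alpha] <- grad[lay$alpha] + colSums(G)
      if (!is.null(lay$bp)) grad[lay$bp] <- grad[lay$bp] + as.vector(crossprod(z, G))
      if (!is.null(lay$bn)) grad[lay$bn] <- grad[lay$bn] + as.vector(crossprod(nat, G))
      if (!is.null(lay$za)) {
        grad[lay$za] <- grad[lay$za] + sa * G
        i <- lsrow("artist", r)
        grad[i] <- grad[i] + sa * sum(ZA * G)
      }
      if (!is.null(lay$zc)) {
        grad[lay$zc] <- grad[lay$zc] + sc * rowsum(G, gidx)
        i <- lsrow("caste", r)
        grad[i] <- grad[i] + sc * sum(ZC[gidx, , drop = FALSE] * G)
      }
      if (!is.null(lay$zu)) {
        grad[lay$zu] <- grad[lay$zu] + su * rowsum(G, kidx)
        i <- lsrow("neighborhood", r)
        grad[i] <- grad[i] + su * sum(ZU[kidx, , drop = FALSE] * G)
      }
    }
    sel <- !is_ls
    lp <- lp - 0.5 * sum((th[sel] / norm_sd[sel])^2)
    grad[sel] <- grad[sel] - th[sel] / norm_sd[sel]^2
    if (any(is_ls)) {
      lsv <- th[is_ls]
      sig <- exp(lsv)
      lp <- lp + sum(lsv) - 0.5 * sum((sig / s0)^2)
      grad[is_ls] <- grad[is_ls] + 1 - sig^2 / s0^2
    }
    list(lp = lp, grad = grad)
  }

  list(matrix = m, info = info, rows = rows, ls = ls, lsrow = lsrow,
       n_par = n_par, names = nm, is_ls = is_ls, R = R, C = C,
       n = n, Gn = Gn, Kn = Kn, gidx = gidx, kidx = kidx, z = z, nat = nat,
       act = act, lp_grad = lp_grad)
}

#' Fit the hierarchical transition model
#'
#' Jointly fits the rows of the requested transition matrices as independent
#' multinomial likelihoods sharing the artist/caste/neighbourhood grouping
#' structure, by Hamiltonian Monte Carlo. Convergence is checked with
#' split-Rhat and divergence counts; by default the fit fails loudly when
#' any parameter has Rhat >= `rhat_max` or the divergence rate exceeds
#' `divergence_cap`.
#'
#' @param design A [KolamDesign-class] from [buildDesign()].
#' @param model A [KolamModelSpec-class] (default: the full model).
#' @param priors A [KolamPriors-class].
#' @param matrices Which matrices to fit, subset of `c("S","O","T","D")`.
#' @param chains,warmup,sampling MCMC geometry; the default four chains of
#'   1,000 retained draws follow standard practice for this model family.
#' @param seed Integer seed; all chains and matrices derive their streams
#'   from it.
#' @param L_max Maximum leapfrog steps per HMC trajectory.
#' @param target_accept Dual-averaging target acceptance rate.
#' @param convergence `"error"` (default), `"warn"` or `"none"`.
#' @param rhat_max,divergence_cap Convergence thresholds.
#' @param compute_loglik Store the pointwise log-likelihood table (one
#'   observation = one artist x matrix-row multinomial) needed for LOO.
#' @return A [KolamFit-class].
#' @export
fitKolam <- function(design, model = kolamModel("full"),
                     priors = defaultPriors(),
                     matrices = MATRIX_IDS, chains = 4L, warmup = 500L,
                     sampling = 1000L, seed = 1L, L_max = 60L,
                     target_accept = 0.9,
                     convergence = c("error", "warn", "none"),
                     rhat_max = 1.01, divergence_cap = 0.02,
                     compute_loglik = TRUE) {
  convergence <- match.arg(convergence)
  stopifnot(all(matrices %in% MATRIX_IDS))
  if (!length(design@artist_ids)) stopf("empty design")
  blocks <- list()
  diag_rows <- list()
  for (mi in seq_along(matrices)) {
    m <- matrices[mi]
    blk <- buildBlock(design, model, priors, m)
    res <- hmcSample(blk$lp_grad, blk$n_par, chains = chains, warmup = warmup,
                     sampling = sampling,
                     seed = deriveSeed(seed, mi), L_max = L_max,
                     target_accept = target_accept)
    blk$chain_draws <- res$draws
    blk$draws <- do.call(rbind, res$draws)
    colnames(blk$draws) <- blk$names
    blk$divergences <- res$divergences
    blk$step_size <- res$step_size
    blk$accept_rate <- res$accept_rate
    rhat <- splitRhat(res$draws)
    pop <- !grepl("\\.z_[acu]\\.", blk$names)
    ess <- rep(NA_real_, blk$n_par)
    ess[pop] <- essBasic(lapply(res$draws, function(d) d[, pop, drop = FALSE]))
    diag_rows[[m]] <- data.frame(matrix = m, parameter = blk$names,
                                 mean = colMeans(blk$draws),
                                 sd = apply(blk$draws, 2L, stats::sd),
                                 rhat = rhat, ess = ess,
                                 stringsAsFactors = FALSE, row.names = NULL)
    blocks[[m]] <- blk
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  n_div <- sum(vapply(blocks, function(b) sum(b$divergences), 0))
  div_rate <- n_div / (length(blocks) * chains * sampling)
  worst <- max(diagnostics$rhat, na.rm = TRUE)
  if (convergence != "none") {
    msgs <- character(0)
    if (worst >= rhat_max)
      msgs <- c(msgs, sprintf("max split-Rhat %.4f >= %.3f (%s)", worst, rhat_max,
                              diagnostics$parameter[which.max(diagnostics$rhat)]))
    if (div_rate > divergence_cap)
      msgs <- c(msgs, sprintf("divergence rate %.3f exceeds cap %.3f", div_rate, divergence_cap))
    if (length(msgs)) {
      msg <- paste("model did not converge:", paste(msgs, collapse = "; "))
      if (convergence == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  fit <- methods::new("KolamFit", model = model, priors = priors,
                      design = design, blocks = blocks,
                      diagnostics = diagnostics,
                      loglik = matrix(numeric(0), 0L, 0L),
                      obs = data.frame(),
                      mcmc = list(chains = chains, warmup = warmup,
                                  sampling = sampling, seed = seed,
                                  divergences = n_div, div_rate = div_rate,
                                  max_rhat = worst))
  if (compute_loglik) {
    pw <- pointwiseLogLik(fit)
    fit@loglik <- pw$loglik
    fit@obs <- pw$obs
  }
  fit
}

## Per-draw linear predictor (free categories) for one artist in one row of
## one block: returns an S x K matrix.
etaDrawsArtist <- function(blk, r, i) {
  d <- blk$draws
  lay <- blk$rows[[r]]
  K <- lay$K
  eta <- d[, lay$alpha, drop = FALSE]
  if (!is.null(lay$za)) {
    sa <- exp(d[, blk$lsrow("artist", r)])
    eta <- eta + sa * d[, lay$za[i, ], drop = FALSE]
  }
  if (!is.null(lay$zc)) {
    sc <- exp(d[, blk$lsrow("caste", r)])
    eta <- eta + sc * d[, lay$zc[blk$gidx[i], ], drop = FALSE]
  }
  if (!is.null(lay$zu)) {
    su <- exp(d[, blk$lsrow("neighborhood", r)])
    eta <- eta + su * d[, lay$zu[blk$kidx[i], ], drop = FALSE]
  }
  if (!is.null(lay$bp)) eta <- eta + blk$z[i] * d[, lay$bp, drop = FALSE]
  if (!is.null(lay$bn)) eta <- eta + blk$nat[i] * d[, lay$bn, drop = FALSE]
  eta
}

## Softmax over draws: S x K free-category logits -> S x (K+1) probabilities.
probDraws <- function(eta) {
  M <- cbind(eta, 0)
  mx <- M[, 1L]
  for (j in seq_len(ncol(M))[-1L]) mx <- pmax(mx, M[, j])
  P <- exp(M - mx)
  P / rowSums(P)
}

#' Pointwise log-likelihood table of a fit
#'
#' One observation unit is the multinomial count row of one artist in one
#' transition-matrix row; the log pmf (including the multinomial
#' coefficient) is evaluated at every posterior draw.
#'
#' @param fit A [KolamFit-class].
#' @return List with `loglik` (draws x observations matrix) and `obs`
#'   (data.frame describing each observation).
#' @export
pointwiseLogLik <- function(fit) {
  blocks <- fit@blocks
  n <- length(fit@design@artist_ids)
  cols <- list(); meta <- list()
  for (m in names(blocks)) {
    blk <- blocks[[m]]
    for (r in seq_len(blk$R)) {
      lay <- blk$rows[[r]]
      lconst <- lgamma(lay$Ntot + 1) - rowSums(lgamma(lay$Yact + 1))
      for (i in seq_len(n)) {
        eta <- etaDrawsArtist(blk, r, i)
        M <- cbind(eta, 0)
        mx <- M[, 1L]
        for (j in seq_len(ncol(M))[-1L]) mx <- pmax(mx, M[, j])
        lse <- mx + log(rowSums(exp(M - mx)))
        ll <- lconst[i] + as.vector(M %*% lay$Yact[i, ]) - lay$Ntot[i] * lse
        cols[[length(cols) + 1L]] <- ll
        meta[[length(meta) + 1L]] <-
          data.frame(matrix = m, row = blk$info$labels[r],
                     artist_id = fit@design@artist_ids[i],
                     total = lay$Ntot[i], stringsAsFactors = FALSE)
      }
    }
  }
  list(loglik = do.call(cbind, cols), obs = do.call(rbind, meta))
}

#' Posterior transition-matrix estimates
#'
#' Per-draw row probabilities via the softmax link, averaged over draws
#' (posterior mean). At the population level all group offsets are zero and
#' covariates sit at their reference values (mean practice, native); for a
#' named artist her offsets and covariates are plugged in.
#'
#' @param fit A [KolamFit-class].
#' @param level `"population"` or an artist id present in the design.
#' @return List with `S` (3x3 between-space matrix, rows O/T/D order) and
#'   `W` (within-space matrices), each row summing to 1. Only matrices that
#'   were fitted are returned.
#' @export
transitionMatrixEstimate <- function(fit, level = "population") {
  pop <- identical(level, "population")
  if (!pop) {
    i <- match(level, fit@design@artist_ids)
    if (is.na(i)) stopf("unknown artist '%s'", level)
  }
  out <- list(W = list())
  for (m in names(fit@blocks)) {
    blk <- fit@blocks[[m]]
    C <- blk$C
    est <- matrix(0, blk$R, C, dimnames = list(blk$info$labels, blk$info$labels))
    for (r in seq_len(blk$R)) {
      lay <- blk$rows[[r]]
      eta <- if (pop) blk$draws[, lay$alpha, drop = FALSE] else etaDrawsArtist(blk, r, i)
      pm <- colMeans(probDraws(eta))
      est[r, lay$active] <- pm
    }
    if (m == "S") out$S <- est else out$W[[m]] <- est
  }
  out
}

#' @describeIn fitKolam Fit summary.
#' @param object A `KolamFit`.
#' @export
setMethod("show", "KolamFit", function(object) {
  cat("KolamFit: model '", object@model@name, "' on ",
      length(object@design@artist_ids), " artists; matrices: ",
      paste(names(object@blocks), collapse = ", "), "\n",
      "  chains = ", object@mcmc$chains, ", retained draws = ",
      object@mcmc$chains * object@mcmc$sampling,
      ", max Rhat = ", sprintf("%.4f", object@mcmc$max_rhat),
      ", divergences = ", object@mcmc$divergences, "\n", sep = "")
})
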