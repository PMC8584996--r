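#' Stationary distribution of a stochastic matrix
#'
#' Solves pi P = pi, sum(pi) = 1 by a linear least-squares solve after
#' verifying that the chain has a single recurrent communicating class
#' (otherwise the stationary law is not unique and an error is raised).
#' A power-iteration method is available as an alternative.
#'
#' @param P Square row-stochastic matrix.
#' @param method `"solve"` (default) or `"power"`.
#' @param tol Row-sum and residual tolerance.
#' @return A [StationaryDistribution-class].
#' @export
#' @examples
#' stationaryDistribution(matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE))
stationaryDistribution <- function(P, method = c("solve", "power"), tol = 1e-9) {
  method <- match.arg(method)
  if (!is.matrix(P) || nrow(P) != ncol(P)) stopf("P must be a square matrix")
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8))
    stopf("P must be row-stochastic")
  k <- nrow(P)
  ## recurrent classes = strongly connected components with no exit edges
  g <- igraph::graph_from_adjacency_matrix(P > tol, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  n_recurrent <- 0L
  for (cl in unique(comp)) {
    inside <- comp == cl
    if (all(P[inside, !inside, drop = FALSE] <= tol)) n_recurrent <- n_recurrent + 1L
  }
  if (n_recurrent != 1L)
    stopf("stationary distribution is not unique: %d recurrent classes", n_recurrent)

  if (method == "solve") {
    A <- rbind(t(P) - diag(k), rep(1, k))
    b <- c(rep(0, k), 1)
    pi_hat <- as.vector(qr.solve(A, b))
  } else {
    pi_hat <- rep(1 / k, k)
    for (it in seq_len(100000L)) {
      nxt <- as.vector(pi_hat %*% P)
      nxt <- nxt / sum(nxt)
      if (max(abs(nxt - pi_hat)) < 1e-14) { pi_hat <- nxt; break }
      pi_hat <- nxt
    }
  }
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  resid <- max(abs(as.vector(pi_hat %*% P) - pi_hat))
  if (resid > 1e-10)
    stopf("stationary solve failed: residual %g", resid)
  if (!is.null(rownames(P))) names(pi_hat) <- rownames(P)
  methods::new("StationaryDistribution", pi = pi_hat, residual = resid,
               method = method)
}

#' Equilibrium space occupancies implied by a fit
#'
#' The long-run fraction of gestures an artist draws in each geometric
#' space, i.e. the stationary distribution of her posterior-mean 3x3
#' between-space transition matrix. With `per_draw = TRUE` the stationary
#' law is computed per posterior draw and averaged instead.
#'
#' @param fit A [KolamFit-class] that includes the between-space matrix.
#' @param artists Artist ids (default: all in the design); the string
#'   `"population"` gives the population-level occupancy.
#' @param per_draw Average per-draw stationary laws instead of using the
#'   posterior-mean matrix.
#' @return Matrix with one row per requested level and columns O, T, D.
#' @export
equilibriumOccupancy <- function(fit, artists = NULL, per_draw = FALSE) {
  if (!"S" %in% names(fit@blocks))
    stopf("fit does not include the between-space matrix")
  if (is.null(artists)) artists <- fit@design@artist_ids
  out <- matrix(NA_real_, length(artists), 3L,
                dimnames = list(artists, KOLAM_SPACES))
  blk <- fit@blocks[["S"]]
  for (ai in seq_along(artists)) {
    lvl <- artists[ai]
    if (per_draw) {
      Sdr <- nrow(blk$draws)
      Pd <- array(0, c(Sdr, 3L, 3L))
      for (r in 1:3) {
        lay <- blk$rows[[r]]
        eta <- if (identical(lvl, "population")) blk$draws[, lay$alpha, drop = FALSE]
               else etaDrawsArtist(blk, r, match(lvl, fit@design@artist_ids))
        Pd[, r, lay$active] <- probDraws(eta)
      }
      pis <- t(vapply(seq_len(Sdr), function(s)
        stationaryDistribution(Pd[s, , ])@pi, numeric(3L)))
      out[ai, ] <- colMeans(pis)
    } else {
      est <- transitionMatrixEstimate(fit, level = lvl)
      out[ai, ] <- stationaryDistribution(est$S)@pi
    }
  }
  out
}

#' @describeIn stationaryDistribution Print the distribution.
#' @param object A `StationaryDistribution`.
#' @export
setMethod("show", "StationaryDistribution", function(object) {
  cat("StationaryDistribution (", object@method, "): ", sep = "")
  cat(sprintf("%.4f", object@pi), sep = ", ")
  cat("  [residual", format(object@residual, digits = 2), "]\n")
})
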