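#' Intraclass correlations by prediction-variance decomposition
#'
#' For every posterior draw and every transition-matrix cell (row x
#' non-reference category, on the logit scale), each model term's isolated
#' contribution to the linear predictor is computed per individual: the
#' artist offset, the caste offset via membership, the neighbourhood offset
#' via residence, the practice slope times standardized practice, and the
#' nativity slope times the indicator. The ICC of a term is its variance
#' across individuals divided by the sum of the five variances; by
#' construction the shares are non-negative and sum to 1. Shares are then
#' averaged over draws and over the cells of each matrix.
#'
#' @param fit A [KolamFit-class] for a model with at least one term.
#' @param weights `"uniform"` (default) averages cells equally within a
#'   matrix; `"counts"` weights each cell by its observed transition total.
#' @return An [ICCTable-class]: rows = fitted matrices (across-spaces,
#'   orthogonal, diagonal, transitional), columns = individual, expertise,
#'   nativity, caste, residence.
#' @export
iccDecompose <- function(fit, weights = c("uniform", "counts")) {
  weights <- match.arg(weights)
  terms <- fit@model@terms
  if (!length(terms)) stopf("ICC decomposition needs a model with at least one term")
  term_cols <- c(artist = "individual", practice = "expertise",
                 nativity = "nativity", caste = "caste",
                 neighborhood = "residence")
  cols <- unname(term_cols)
  design <- fit@design
  n <- length(design@artist_ids)
  z <- design@z_practice; nat <- as.numeric(design@native)
  gidx <- design@caste_index; kidx <- design@neighborhood_index
  vz <- stats::var(z); vnat <- stats::var(nat)

  rows <- list()
  order_m <- intersect(c("S", "O", "D", "T"), names(fit@blocks))
  for (m in order_m) {
    blk <- fit@blocks[[m]]
    Sdr <- nrow(blk$draws)
    acc <- stats::setNames(numeric(5L), cols)
    wsum <- 0
    for (r in seq_len(blk$R)) {
      lay <- blk$rows[[r]]
      for (cc in seq_len(lay$K)) {
        V <- matrix(0, Sdr, 5L, dimnames = list(NULL, cols))
        if (!is.null(lay$za)) {
          sa <- exp(blk$draws[, blk$lsrow("artist", r)])
          X <- blk$draws[, lay$za[, cc], drop = FALSE]   # S x n
          V[, "individual"] <- sa^2 *
            (rowMeans(X^2) - rowMeans(X)^2) * n / (n - 1)
        }
        if (!is.null(lay$zc)) {
          sc <- exp(blk$draws[, blk$lsrow("caste", r)])
          X <- blk$draws[, lay$zc[, cc], drop = FALSE][, gidx, drop = FALSE]
          V[, "caste"] <- sc^2 * (rowMeans(X^2) - rowMeans(X)^2) * n / (n - 1)
        }
        if (!is.null(lay$zu)) {
          su <- exp(blk$draws[, blk$lsrow("neighborhood", r)])
          X <- blk$draws[, lay$zu[, cc], drop = FALSE][, kidx, drop = FALSE]
          V[, "residence"] <- su^2 * (rowMeans(X^2) - rowMeans(X)^2) * n / (n - 1)
        }
        if (!is.null(lay$bp)) V[, "expertise"] <- blk$draws[, lay$bp[cc]]^2 * vz
        if (!is.null(lay$bn)) V[, "nativity"] <- blk$draws[, lay$bn[cc]]^2 * vnat
        tot <- rowSums(V)
        keep <- tot > 0
        if (any(keep)) {
          sh <- V[keep, , drop = FALSE] / tot[keep]
          wcell <- if (weights == "counts") sum(lay$Yact) else 1
          acc <- acc + wcell * colMeans(sh)
          wsum <- wsum + wcell
        }
      }
    }
    if (wsum == 0) stopf("matrix %s has no informative cells for the ICC", m)
    rows[[blk$info$pretty]] <- acc / wsum
  }
  tab <- do.call(rbind, rows)
  methods::new("ICCTable", table = tab)
}

#' @describeIn iccDecompose Access the ICC matrix.
#' @param x An `ICCTable`.
#' @export
iccTable <- function(x) x@table

#' @describeIn iccDecompose Print the table.
#' @param object An `ICCTable`.
#' @export
setMethod("show", "ICCTable", function(object) {
  cat("ICCTable (share of across-individual prediction variance):\n")
  print(round(object@table, 3))
})
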