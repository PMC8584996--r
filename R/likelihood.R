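#' Softmax transition probabilities for one matrix row
#'
#' Maps a vector of linear predictors (logits) onto the probability simplex.
#' In the transition model the last category of each row is the reference
#' with its logit fixed at zero; the softmax is invariant to adding a
#' constant to all logits.
#'
#' @param eta Numeric vector of finite linear predictors, one per category
#'   (including the reference).
#' @return Probability vector of the same length; positive, sums to 1.
#' @export
#' @examples
#' rowProbability(c(0, 0, 0))        # uniform
#' rowProbability(c(log(4), 0, 0))   # (2/3, 1/6, 1/6)
rowProbability <- function(eta) {
  if (!length(eta) || any(!is.finite(eta)))
    stopf("linear predictors must be finite")
  ex <- exp(eta - max(eta))
  ex / sum(ex)
}

#' Multinomial log likelihood of one count row
#'
#' Log probability mass of observing `counts` under category probabilities
#' `probs`, including the multinomial coefficient. A row with zero total
#' contributes 0; a positive count on a zero-probability category yields
#' `-Inf` and a warning, flagging a data/model conflict.
#'
#' @param counts Non-negative integer vector.
#' @param probs Probability vector of the same length (sums to 1).
#' @return Log density (scalar).
#' @export
#' @examples
#' multinomialLogLik(c(1, 1), c(0.5, 0.5))  # log(0.5)
multinomialLogLik <- function(counts, probs) {
  if (length(counts) != length(probs)) stopf("counts and probs lengths differ")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-8)
    stopf("probs must lie on the simplex")
  n <- sum(counts)
  if (n == 0) return(0)
  conflict <- counts > 0 & probs <= 0
  if (any(conflict)) {
    warnf("positive count on zero-probability category: data/model conflict")
    return(-Inf)
  }
  pos <- counts > 0
  lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(counts[pos] * log(probs[pos]))
}
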