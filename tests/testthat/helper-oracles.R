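# Exact leave-one-out oracle: refit the model once per observation with that
# observation's counts removed, then score the held-out multinomial row
# under the refit posterior. Only used on tiny between-space fits.
exact_loo_elpd <- function(fit, ...) {
  obs <- fit@obs
  des <- fit@design
  model <- fit@model
  stopifnot(all(obs$matrix == "S"))
  row_labels <- c("O", "T", "D")
  elpd <- numeric(nrow(obs))
  for (j in seq_len(nrow(obs))) {
    i <- match(obs$artist_id[j], des@artist_ids)
    r <- match(obs$row[j], row_labels)
    y <- des@counts@S[i, r, ]
    des_j <- des
    cnt <- des_j@counts
    cnt@S[i, r, ] <- 0
    cnt@W[[row_labels[r]]][i, , ] <- 0  # keep factored totals consistent
    des_j@counts <- cnt
    refit <- fitKolam(des_j, model, matrices = "S", convergence = "none",
                      compute_loglik = FALSE, ...)
    blk <- refit@blocks$S
    eta <- KolamMarkov:::etaDrawsArtist(blk, r, i)
    M <- cbind(eta, 0)
    mx <- apply(M, 1, max)
    lse <- mx + log(rowSums(exp(M - mx)))
    lconst <- lgamma(sum(y) + 1) - sum(lgamma(y + 1))
    ll <- lconst + as.vector(M %*% y) - sum(y) * lse
    elpd[j] <- KolamMarkov:::logSumExp(ll) - log(length(ll))
  }
  elpd
}
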