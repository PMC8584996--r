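# Internal numerical helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

## Row-wise log-sum-exp, tolerant of -Inf entries (structural zeros).
logRowSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

logSumExp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

## Run code with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a stream-specific 31-bit seed from a master seed.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 19991 + as.numeric(stream) * 7919) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
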