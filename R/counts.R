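## Per-artist cyclic transition counts and their factorization into one
## between-space matrix (3x3, order O, T, D) and three within-space
## matrices (6x6 orthogonal, 4x4 transitional, 4x4 diagonal).

SPACE_IDX <- list(O = 1:6, T = 7:10, D = 11:14)

#' Ordered transition pairs of a loop
#'
#' Returns the consecutive state pairs of a loop. Because loops are closed
#' and the starting gesture is unknown, the pair from the last state back to
#' the first is counted as well (cyclic closure); `cycle = FALSE` disables
#' this for validation studies.
#'
#' @param states Integer vector of model states (a loop), length >= 1.
#' @param cycle Count the wrap-around pair (default `TRUE`).
#' @return A two-column integer matrix (`from`, `to`) with one row per pair:
#'   `length(states)` rows with closure, one fewer without.
#' @export
#' @examples
#' loopTransitionPairs(c(1L, 2L))      # (1,2) and the wrap (2,1)
#' loopTransitionPairs(5L)             # the self-wrap (5,5)
loopTransitionPairs <- function(states, cycle = TRUE) {
  states <- as.integer(states)
  if (!length(states)) stopf("a loop must contain at least one state")
  if (cycle) {
    cbind(from = states, to = c(states[-1L], states[1L]))
  } else {
    if (length(states) == 1L) {
      cbind(from = integer(0), to = integer(0))
    } else {
      cbind(from = states[-length(states)], to = states[-1L])
    }
  }
}

## Tally a list of loops into a 14x14 matrix.
tallyLoops <- function(state_list, cycle = TRUE) {
  m <- matrix(0L, 14L, 14L, dimnames = list(KOLAM_STATE_NAMES, KOLAM_STATE_NAMES))
  for (st in state_list) {
    p <- loopTransitionPairs(st, cycle = cycle)
    if (nrow(p)) {
      tb <- tabulate((p[, 1L] - 1L) * 14L + p[, 2L], nbins = 196L)
      m <- m + matrix(tb, 14L, 14L, byrow = TRUE)
    }
  }
  m
}

#' Aggregate 14x14 transition counts for one artist
#'
#' Sums the transition pairs of every loop the artist drew, across all her
#' drawings, into one aggregate count matrix with rows indexing the current
#' gesture state and columns the next.
#'
#' @param corpus A [KolamCorpus-class].
#' @param artist_id Artist identifier.
#' @param cycle Count wrap-around pairs (default `TRUE`).
#' @return A 14x14 integer matrix; all-zero (with a warning) for an artist
#'   without loops.
#' @export
aggregateCounts <- function(corpus, artist_id, cycle = TRUE) {
  if (!artist_id %in% corpus@artists$artist_id)
    stopf("unknown artist_id: %s", artist_id)
  sel <- corpus@loops$artist_id == artist_id
  if (!any(sel)) warnf("artist %s has no loops; counts are all zero", artist_id)
  tallyLoops(corpus@loops$states[sel], cycle = cycle)
}

#' Factor an aggregate count matrix into space and within-space counts
#'
#' The between-space matrix `S` sums each (space, space) block of the
#' aggregate matrix; the within-space matrices are the diagonal blocks.
#' Cross-space transitions therefore contribute only to `S`, consistent with
#' the factorization P(o2|o1) = P(O|O) x P(o2|o1, O|O).
#'
#' @param agg A 14x14 count matrix.
#' @return List with `S` (3x3, order O, T, D) and `W` (list of the 6x6
#'   orthogonal, 4x4 transitional and 4x4 diagonal diagonal blocks).
#' @export
factorCounts <- function(agg) {
  stopifnot(is.matrix(agg), all(dim(agg) == c(14L, 14L)), all(agg >= 0))
  S <- matrix(0, 3L, 3L, dimnames = list(KOLAM_SPACES, KOLAM_SPACES))
  for (a in 1:3) for (b in 1:3)
    S[a, b] <- sum(agg[SPACE_IDX[[a]], SPACE_IDX[[b]]])
  W <- lapply(SPACE_IDX, function(ix) agg[ix, ix, drop = FALSE])
  list(S = S, W = W)
}

#' Transition counts for every artist in a corpus
#'
#' Computes per-artist aggregate and factored counts in one pass.
#'
#' @param corpus A [KolamCorpus-class].
#' @param cycle Count wrap-around pairs (default `TRUE`).
#' @return A [KolamCounts-class] holding, per artist, the aggregate 14x14
#'   matrix, the 3x3 between-space matrix and the three within-space
#'   matrices.
#' @export
countTransitions <- function(corpus, cycle = TRUE) {
  ids <- sort(corpus@artists$artist_id)
  n <- length(ids)
  agg <- array(0, c(n, 14L, 14L),
               dimnames = list(ids, KOLAM_STATE_NAMES, KOLAM_STATE_NAMES))
  S <- array(0, c(n, 3L, 3L), dimnames = list(ids, KOLAM_SPACES, KOLAM_SPACES))
  W <- lapply(SPACE_IDX, function(ix) {
    array(0, c(n, length(ix), length(ix)),
          dimnames = list(ids, KOLAM_STATE_NAMES[ix], KOLAM_STATE_NAMES[ix]))
  })
  grp <- split(corpus@loops$states, factor(corpus@loops$artist_id, levels = ids))
  for (i in seq_len(n)) {
    m <- tallyLoops(grp[[i]], cycle = cycle)
    agg[i, , ] <- m
    f <- factorCounts(m)
    S[i, , ] <- f$S
    for (s in KOLAM_SPACES) W[[s]][i, , ] <- f$W[[s]]
  }
  methods::new("KolamCounts", artist_ids = ids, aggregate = agg, S = S,
               W = W, cycle = cycle)
}

#' Export factored counts as a long-form CSV
#'
#' Columns: `artist_id`, `matrix` (one of `space`, `O`, `T`, `D`),
#' `from_state`, `to_state`, `count`.
#'
#' @param counts A [KolamCounts-class].
#' @param path Output CSV path.
#' @export
exportCounts <- function(counts, path) {
  rows <- list()
  mk <- function(arr, label) {
    dn <- dimnames(arr)
    do.call(rbind, lapply(seq_along(counts@artist_ids), function(i) {
      g <- expand.grid(from_state = dn[[2L]], to_state = dn[[3L]],
                       stringsAsFactors = FALSE)
      data.frame(artist_id = counts@artist_ids[i], matrix = label,
                 g, count = as.vector(arr[i, , ]), stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(mk(counts@S, "space"), mk(counts@W$O, "O"),
               mk(counts@W$T, "T"), mk(counts@W$D, "D"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn countTransitions Counts summary.
#' @param object A `KolamCounts`.
#' @export
setMethod("show", "KolamCounts", function(object) {
  cat("KolamCounts for", length(object@artist_ids), "artists;",
      sum(object@aggregate), "transitions",
      if (object@cycle) "(with cyclic closure)\n" else "(no cyclic closure)\n")
})
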