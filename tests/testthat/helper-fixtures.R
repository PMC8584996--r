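# Shared fixtures: corpora are built in code, never stored.

state_space_of <- rep(c("O", "T", "D"), c(6, 4, 4))

# Random grammar-valid loop (wrap pair included), independent of the
# package's simulator: walk over spaces avoiding O-D adjacency, then patch
# the wrap with a transitional state if needed.
rand_valid_loop <- function(len) {
  pick <- function(space) switch(space, O = sample(1:6, 1),
                                 T = sample(7:10, 1), D = sample(11:14, 1))
  sp <- sample(c("O", "T", "D"), 1)
  states <- pick(sp)
  while (length(states) < len) {
    cur <- state_space_of[states[length(states)]]
    nxt <- switch(cur,
                  O = sample(c("O", "T"), 1),
                  D = sample(c("D", "T"), 1),
                  T = sample(c("O", "T", "D"), 1))
    states <- c(states, pick(nxt))
  }
  a <- state_space_of[states[length(states)]]
  b <- state_space_of[states[1]]
  if ((a == "O" && b == "D") || (a == "D" && b == "O"))
    states <- c(states, pick("T"))
  states
}

# Brute-force recount oracle: enumerate pairs as strings and tabulate.
brute_count <- function(state_lists, cycle = TRUE) {
  m <- matrix(0L, 14, 14)
  for (st in state_lists) {
    if (cycle) {
      pairs <- cbind(st, c(st[-1], st[1]))
    } else {
      if (length(st) < 2) next
      pairs <- cbind(st[-length(st)], st[-1])
    }
    for (k in seq_len(nrow(pairs)))
      m[pairs[k, 1], pairs[k, 2]] <- m[pairs[k, 1], pairs[k, 2]] + 1L
  }
  m
}

# Write a small corpus to temp files and read it back through the package.
# loops: named list artist_id -> list of character token vectors.
# artists: data.frame(artist_id, age, practice_years, native, caste_id, lat, lon)
corpus_from_tokens <- function(loops, artists, dir = tempfile("corp")) {
  dir.create(dir)
  seq_path <- file.path(dir, "sequences.tsv")
  lines <- character(0)
  for (aid in names(loops)) {
    for (li in seq_along(loops[[aid]]))
      lines <- c(lines, paste(aid, paste0(aid, "_d1"), li,
                              paste(loops[[aid]][[li]], collapse = " "), sep = "\t"))
  }
  writeLines(lines, seq_path)
  sv_path <- file.path(dir, "survey.csv")
  write.csv(artists[, c("artist_id", "age", "practice_years", "native", "caste_id")],
            sv_path, row.names = FALSE, quote = FALSE)
  gps_path <- file.path(dir, "gps.csv")
  write.csv(artists[, c("artist_id", "lat", "lon")], gps_path,
            row.names = FALSE, quote = FALSE)
  readDataset(seq_path, sv_path, gps_path, quiet = TRUE)
}

default_artists <- function(ids, lat = 10.2, lon = 77.5) {
  n <- length(ids)
  data.frame(artist_id = ids, age = seq(25, 45, length.out = n),
             practice_years = seq(4, 4 + 2 * (n - 1), by = 2)[seq_len(n)],
             native = rep(c(0, 1), length.out = n),
             caste_id = rep(1:3, length.out = n),
             lat = lat + seq_len(n) * 1e-5, lon = rep(lon, n),
             stringsAsFactors = FALSE)
}

# Canonical raw code of each model state under the default lexicon.
canon_codes <- function() {
  e <- defaultLexicon()@entries
  vapply(1:14, function(s) e$raw_code[match(s, e$state)], "")
}

# Ground truth with a balanced between-space matrix: every space is visited
# often, so estimator checks are not starved of counts in any row.
balanced_truth <- function(sigma = 0, beta = 0, sigma_artist = sigma,
                           sigma_caste = sigma, sigma_neigh = sigma) {
  S <- matrix(c(0.70, 0.30, 0.00,
                0.35, 0.30, 0.35,
                0.00, 0.30, 0.70), 3, 3, byrow = TRUE,
              dimnames = list(c("O", "T", "D"), c("O", "T", "D")))
  defaultGroundTruth(sigma_artist = sigma_artist, sigma_caste = sigma_caste,
                     sigma_neigh = sigma_neigh, beta_practice = beta,
                     beta_nativity = beta, S_pop = S)
}

# Independent power-iteration oracle for stationary distributions.
power_iter_pi <- function(P, iters = 200000, tol = 1e-14) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    nv <- as.vector(v %*% P)
    nv <- nv / sum(nv)
    if (max(abs(nv - v)) < tol) return(nv)
    v <- nv
  }
  v
}
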