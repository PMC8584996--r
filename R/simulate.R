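## Synthetic-corpus generator: the generative inverse of the transition
## model, with a known ground truth, used to validate every pipeline stage
## without field data.

#' Ground truth for the synthetic-corpus generator
#'
#' Population-level row logits for the four transition matrices plus the
#' group-effect standard deviations and covariate slopes. The default
#' between-space matrix follows the population-level pattern reported for
#' field corpora (orthogonal drawings almost never leave orthogonal space;
#' diagonal drawings split roughly evenly between staying and moving to
#' transitional space), with the grammar-forbidden O-D cells structurally
#' zero; within-space rows mildly favour self-transitions. Group effects
#' default to an artist-dominant hierarchy: `sigma_artist` = 1,
#' `sigma_caste` = `sigma_neigh` = 0.2, practice slope 0.4, nativity slope
#' 0.2 on every row.
#'
#' @param sigma_artist,sigma_caste,sigma_neigh Group standard deviations
#'   (scalars, applied to every matrix row).
#' @param beta_practice,beta_nativity Slopes (scalars, every row/category).
#' @param S_pop Optional 3x3 population between-space matrix (rows O, T, D;
#'   rows must sum to 1; zeros allowed only on the grammar-forbidden cells).
#' @param self_weight Within-space self-transition probability used to build
#'   the default within-space rows.
#' @return A list with class `"KolamGroundTruth"`.
#' @export
defaultGroundTruth <- function(sigma_artist = 1, sigma_caste = 0.2,
                               sigma_neigh = 0.2, beta_practice = 0.4,
                               beta_nativity = 0.2, S_pop = NULL,
                               self_weight = 0.45) {
  if (is.null(S_pop)) {
    S_pop <- matrix(c(0.99, 0.01, 0.00,
                      0.51, 0.30, 0.19,
                      0.00, 0.51, 0.49), 3L, 3L, byrow = TRUE,
                    dimnames = list(KOLAM_SPACES, KOLAM_SPACES))
  }
  stopifnot(all(dim(S_pop) == 3L), all(abs(rowSums(S_pop) - 1) < 1e-8))
  if (S_pop[1L, 1L] <= 0 || S_pop[3L, 3L] <= 0)
    stopf("degenerate between-space truth")
  mkW <- function(k) {
    W <- matrix((1 - self_weight) / (k - 1), k, k)
    ## mild gradient so states are not exchangeable
    for (r in seq_len(k)) {
      off <- setdiff(seq_len(k), r)
      w <- seq(1.5, 0.5, length.out = k - 1)
      W[r, off] <- (1 - self_weight) * w / sum(w)
      W[r, r] <- self_weight
    }
    W
  }
  truth <- list(S = S_pop,
                W = list(O = mkW(6L), T = mkW(4L), D = mkW(4L)),
                sigma = c(artist = sigma_artist, caste = sigma_caste,
                          neighborhood = sigma_neigh),
                beta = c(practice = beta_practice, nativity = beta_nativity))
  class(truth) <- "KolamGroundTruth"
  truth
}

#' Configuration of a simulated corpus
#'
#' Defaults emulate the shape of the field study: 192 artists in 19 caste
#' categories and 8 neighbourhood clusters, 16 drawings per artist, about
#' 18 percent non-native artists, loop lengths following a shifted
#' geometric law (minimum 1).
#'
#' @param n_artists,n_castes,n_neighborhoods,drawings_per_artist,loops_per_drawing
#'   Corpus shape (all >= 1).
#' @param mean_loop_length Mean of the shifted-geometric loop length.
#' @param p_native Probability of being non-native (indicator 1).
#' @param decorative_rate Mean decorative gestures per drawing (Poisson).
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return A list with class `"KolamSimConfig"`.
#' @export
simConfig <- function(n_artists = 192L, n_castes = 19L, n_neighborhoods = 8L,
                      drawings_per_artist = 16L, loops_per_drawing = 2L,
                      mean_loop_length = 8, p_native = 0.18,
                      decorative_rate = 0.3, seed = 1L) {
  cfg <- list(n_artists = as.integer(n_artists), n_castes = as.integer(n_castes),
              n_neighborhoods = as.integer(n_neighborhoods),
              drawings_per_artist = as.integer(drawings_per_artist),
              loops_per_drawing = as.integer(loops_per_drawing),
              mean_loop_length = mean_loop_length, p_native = p_native,
              decorative_rate = decorative_rate, seed = as.integer(seed))
  stopifnot(cfg$n_artists >= 1L, cfg$n_castes >= 1L, cfg$n_neighborhoods >= 1L,
            cfg$drawings_per_artist >= 1L, cfg$loops_per_drawing >= 1L,
            cfg$mean_loop_length >= 1, cfg$p_native >= 0, cfg$p_native <= 1)
  class(cfg) <- "KolamSimConfig"
  cfg
}

## Softmax rows of a matrix of logits (-Inf allowed for structural zeros).
softmaxRows <- function(L) {
  P <- exp(L - apply(L, 1L, function(x) max(x[is.finite(x)])))
  P[!is.finite(P)] <- 0
  P / rowSums(P)
}

## Per-artist transition matrices implied by the truth and one artist's
## offsets/covariates. eta additions are applied to logits relative to the
## row's last category.
artistMatrices <- function(truth, shift) {
  shiftRow <- function(p, sh) {
    lg <- log(p)                       # -Inf marks structural zeros
    lg[-length(lg)] <- lg[-length(lg)] + sh
    ex <- exp(lg - max(lg[is.finite(lg)]))
    ex / sum(ex)
  }
  out <- list(S = truth$S, W = truth$W)
  for (r in 1:3) out$S[r, ] <- shiftRow(truth$S[r, ], shift$S[[r]])
  for (s in KOLAM_SPACES) {
    k <- ncol(truth$W[[s]])
    for (r in seq_len(k)) out$W[[s]][r, ] <- shiftRow(truth$W[[s]][r, ], shift$W[[s]][[r]])
  }
  out
}

## Neighborhood centers laid out on a ~1.1 km grid around Kodaikanal-like
## coordinates, so complete-linkage clustering at 500 m separates them
## cleanly while the whole extent stays within a few kilometres.
neighborhoodCenters <- function(K) {
  base_lat <- 10.2381; base_lon <- 77.4892
  side <- ceiling(sqrt(K))
  g <- expand.grid(gx = seq_len(side) - 1L, gy = seq_len(side) - 1L)[seq_len(K), ]
  dlat <- 1100 / 111320
  dlon <- 1100 / (111320 * cos(base_lat * pi / 180))
  cbind(lat = base_lat + g$gy * dlat, lon = base_lon + g$gx * dlon)
}

#' Simulate a grammar-valid kolam corpus from a known ground truth
#'
#' Samples group memberships, covariates and per-artist transition matrices
#' from the generative model, then emits loops by Markov simulation: the
#' initial space is drawn from the artist's between-space stationary law and
#' the initial gesture from the within-space stationary law; same-space
#' steps follow the within-space row of the current gesture, and space
#' switches land on a gesture drawn from the destination space's stationary
#' law. If a loop would close with a grammar-forbidden wrap pair (orthogonal
#' against diagonal) the chain is extended until the wrap is legal, so every
#' simulated loop passes the grammar validator. GPS coordinates are placed
#' at the artist's neighbourhood center plus at most 100 m of jitter, so
#' clustering at 500 m recovers the true neighbourhoods exactly.
#'
#' @param truth A ground truth from [defaultGroundTruth()].
#' @param config A [simConfig()].
#' @return A list: `corpus` (a [KolamCorpus-class]), `truth`, `config`, and
#'   `artist_truth` (per-artist true matrices and memberships).
#' @export
simulateDataset <- function(truth = defaultGroundTruth(), config = simConfig()) {
  stopifnot(inherits(truth, "KolamGroundTruth"), inherits(config, "KolamSimConfig"))
  lex <- defaultLexicon()
  n <- config$n_artists
  ids <- sprintf("A%03d", seq_len(n))
  withLocalSeed(config$seed, {
    ## membership probabilities mildly imbalanced, as in field samples
    cw <- seq(2, 0.5, length.out = config$n_castes)
    caste <- sample.int(config$n_castes, n, replace = TRUE, prob = cw / sum(cw))
    nb <- sample.int(config$n_neighborhoods, n, replace = TRUE)
    native <- stats::rbinom(n, 1L, config$p_native)
    age <- round(pmin(60, pmax(15, stats::rnorm(n, 31.9, 10.1))))
    start_age <- pmax(4, round(stats::rnorm(n, 6, 1)))
    practice <- pmax(0, age - start_age)
    zp <- (practice - mean(practice)) / stats::sd(practice)

    centers <- neighborhoodCenters(config$n_neighborhoods)
    rj <- 100 * sqrt(stats::runif(n)); aj <- stats::runif(n, 0, 2 * pi)
    lat <- centers[nb, "lat"] + rj * sin(aj) / 111320
    lon <- centers[nb, "lon"] + rj * cos(aj) / (111320 * cos(centers[nb, "lat"] * pi / 180))

    ## group offsets, one per (group level, matrix row, non-reference
    ## category) -- matching the model's parameterization
    dims_all <- list(S = c(3L, 2L), O = c(6L, 5L), T = c(4L, 3L), D = c(4L, 3L))
    drawOffsets <- function(n_lev, sigma) {
      lapply(dims_all, function(d) {
        array(stats::rnorm(n_lev * d[1L] * d[2L], 0, sigma),
              c(n_lev, d[1L], d[2L]))
      })
    }
    off_artist <- drawOffsets(n, truth$sigma[["artist"]])
    off_caste <- drawOffsets(config$n_castes, truth$sigma[["caste"]])
    off_nb <- drawOffsets(config$n_neighborhoods, truth$sigma[["neighborhood"]])

    artist_truth <- vector("list", n)
    loops <- list(); deco <- list()
    for (i in seq_len(n)) {
      fx <- truth$beta[["practice"]] * zp[i] + truth$beta[["nativity"]] * native[i]
      shift <- list(
        S = lapply(1:3, function(r)
          off_artist$S[i, r, ] + off_caste$S[caste[i], r, ] + off_nb$S[nb[i], r, ] + fx),
        W = lapply(stats::setNames(KOLAM_SPACES, KOLAM_SPACES), function(s)
          lapply(seq_len(ncol(truth$W[[s]])), function(r)
            off_artist[[s]][i, r, ] + off_caste[[s]][caste[i], r, ] +
              off_nb[[s]][nb[i], r, ] + fx)))
      mats <- artistMatrices(truth, shift)
      pi_S <- stationaryDistribution(mats$S)@pi
      if (any(pi_S < 1e-6))
        warnf("artist %s: a geometric space is essentially unreachable", ids[i])
      pi_W <- lapply(mats$W, function(w) stationaryDistribution(w)@pi)
      artist_truth[[i]] <- list(mats = mats, pi_S = pi_S, caste = caste[i],
                                neighborhood = nb[i])

      p_geom <- 1 / config$mean_loop_length
      for (d in seq_len(config$drawings_per_artist)) {
        did <- sprintf("%s_d%02d", ids[i], d)
        for (l in seq_len(config$loops_per_drawing)) {
          len <- 1L + stats::rgeom(1L, p_geom)
          st <- simulateLoop(mats, pi_S, pi_W, len)
          loops[[length(loops) + 1L]] <-
            list(artist_id = ids[i], drawing_id = did, loop_index = l, states = st)
        }
        nd <- stats::rpois(1L, config$decorative_rate)
        if (nd > 0) {
          codes <- sample(lex@entries$raw_code[lex@entries$space == "X"], nd, replace = TRUE)
          tb <- table(codes)
          deco[[length(deco) + 1L]] <-
            data.frame(artist_id = ids[i], drawing_id = did,
                       raw_code = names(tb), count = as.integer(tb),
                       stringsAsFactors = FALSE)
        }
      }
    }
    artists <- data.frame(artist_id = ids, age = age, practice_years = practice,
                          native = native, caste_id = caste, lat = lat, lon = lon,
                          stringsAsFactors = FALSE)
    loops_df <- data.frame(artist_id = vapply(loops, `[[`, "", "artist_id"),
                           drawing_id = vapply(loops, `[[`, "", "drawing_id"),
                           loop_index = vapply(loops, `[[`, 0L, "loop_index"),
                           stringsAsFactors = FALSE)
    loops_df$states <- lapply(loops, `[[`, "states")
    deco_df <- if (length(deco)) do.call(rbind, deco) else NULL
    corpus <- makeCorpus(lex, artists, loops_df, deco_df)
    names(artist_truth) <- ids
    list(corpus = corpus, truth = truth, config = config,
         artist_truth = artist_truth)
  })
}

## One Markov loop of target length `len` (possibly extended so the wrap
## pair from last back to first state is grammar-legal).
simulateLoop <- function(mats, pi_S, pi_W, len) {
  space_of <- KOLAM_STATE_SPACE
  base <- c(O = 0L, T = 6L, D = 10L)
  s <- sample.int(3L, 1L, prob = pi_S)           # space index in (O,T,D)
  sp <- KOLAM_SPACES[s]
  g <- sample.int(length(pi_W[[sp]]), 1L, prob = pi_W[[sp]])
  states <- integer(0)
  states[1L] <- base[[sp]] + g
  step <- function(cur) {
    cur_sp <- space_of[cur]
    si <- match(cur_sp, KOLAM_SPACES)
    s2 <- sample.int(3L, 1L, prob = mats$S[si, ])
    sp2 <- KOLAM_SPACES[s2]
    if (sp2 == cur_sp) {
      within <- cur - base[[cur_sp]]
      g2 <- sample.int(ncol(mats$W[[sp2]]), 1L, prob = mats$W[[sp2]][within, ])
    } else {
      g2 <- sample.int(length(pi_W[[sp2]]), 1L, prob = pi_W[[sp2]])
    }
    base[[sp2]] + g2
  }
  while (length(states) < len) states[length(states) + 1L] <- step(states[length(states)])
  ## extend until the wrap pair (last, first) is legal
  guard <- 0L
  repeat {
    a <- space_of[states[length(states)]]; b <- space_of[states[1L]]
    if (!((a == "O" && b == "D") || (a == "D" && b == "O"))) break
    states[length(states) + 1L] <- step(states[length(states)])
    guard <- guard + 1L
    if (guard > 1000L) stopf("could not close loop legally; degenerate truth?")
  }
  states
}
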