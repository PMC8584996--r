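test_that("PSIS-LOO handles degenerate and identical posteriors", {
  S <- 200; n <- 5
  base <- matrix(rep(c(-1.2, -0.7, -2.1, -0.4, -1.6), each = S), S, n)
  loo1 <- psisLoo(base)  # point-mass posterior: no importance variance
  expect_equal(loo1@elpd_loo, sum(base[1, ]))
  expect_equal(loo1@p_loo, 0, tolerance = 1e-10)
  expect_true(all(loo1@pointwise$k == -Inf))

  set.seed(9)
  ll <- base + matrix(rnorm(S * n, 0, 0.3), S, n)
  looA <- psisLoo(ll); looB <- psisLoo(ll)
  expect_equal(looA@elpd_loo - looB@elpd_loo, 0)
  expect_error(psisLoo(ll[1:50, ]), "at least 100 draws")
})

test_that("model weights lie on the simplex with exact dominance and tie rules", {
  set.seed(10)
  S <- 300; n <- 12
  llB <- matrix(rnorm(S * n, -1.5, 0.4), S, n)
  llA <- llB + 0.8  # A strictly better on every draw and observation
  looA <- psisLoo(llA); looB <- psisLoo(llB)
  w <- modelWeights(list(A = looA, B = looB), seed = 3)
  expect_equal(sum(w$stacking_weight), 1, tolerance = 1e-9)
  expect_equal(sum(w$pbma_weight), 1, tolerance = 1e-9)
  expect_true(all(w$stacking_weight >= 0) && all(w$pbma_weight >= 0))
  expect_identical(w$stacking_weight[w$model == "A"], 1)  # dominant vertex, exactly
  expect_gt(w$pbma_weight[w$model == "A"], 0.95)

  # two identical models: declared tie-break toward uniform
  w2 <- modelWeights(list(A = looB, B = looB), seed = 4)
  expect_equal(w2$stacking_weight, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(w2$pbma_weight, c(0.5, 0.5), tolerance = 1e-9)

  expect_error(modelWeights(list(A = looA, B = psisLoo(llB[, 1:4])), seed = 1),
               "same observation units")
})

test_that("stacking prefers the generating model across seeded replicates", {
  truth <- balanced_truth(sigma_artist = 1, sigma_caste = 0, sigma_neigh = 0)
  wins <- 0L
  for (s in 1:10) {
    sim <- simulateDataset(truth, simConfig(n_artists = 12L, drawings_per_artist = 6L,
                                            seed = 100L + s))
    des <- buildDesign(sim$corpus, clusterNeighborhoods(distanceMatrix(sim$corpus)),
                       cycle = FALSE)
    fits <- lapply(c("m1", "m2"), function(mn)
      fitKolam(des, kolamModel(mn), matrices = "S", chains = 2L, warmup = 200L,
               sampling = 200L, seed = s, L_max = 30L, convergence = "none"))
    w <- suppressWarnings(  # high Pareto k is expected on these tiny fits
      modelWeights(list(m1 = psisLoo(fits[[1]]), m2 = psisLoo(fits[[2]])),
                   seed = s))
    if (w$stacking_weight[w$model == "m2"] > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("ICC shares isolate single- and equal-variance terms", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 6L, drawings_per_artist = 3L, seed = 12L))
  des <- buildDesign(sim$corpus, clusterNeighborhoods(distanceMatrix(sim$corpus)))

  # only artist offsets present: all variance is individual
  fit2 <- fitKolam(des, kolamModel("m2"), matrices = "S", chains = 1L,
                   warmup = 100L, sampling = 120L, seed = 5L, L_max = 15L,
                   convergence = "none", compute_loglik = FALSE)
  tab2 <- iccTable(iccDecompose(fit2))
  expect_equal(unname(tab2[, "individual"]), 1)
  expect_equal(unname(tab2[, "caste"]), 0)

  # doctored draws: artist offsets equal to the practice effect -> 0.5 each
  fit3 <- fitKolam(des, kolamModel("m3"), matrices = "S", chains = 1L,
                   warmup = 100L, sampling = 120L, seed = 6L, L_max = 15L,
                   convergence = "none", compute_loglik = FALSE)
  blk <- fit3@blocks$S
  d <- blk$draws
  d[, grepl("log_sigma_artist", colnames(d))] <- 0
  for (r in 1:3) {
    lay <- blk$rows[[r]]
    for (cc in seq_len(lay$K)) {
      d[, lay$za[, cc]] <- matrix(des@z_practice, nrow(d), length(des@artist_ids),
                                  byrow = TRUE)
      d[, lay$bp[cc]] <- 1
    }
  }
  fit3@blocks$S$draws <- d
  tab3 <- iccTable(iccDecompose(fit3))
  expect_equal(unname(tab3[, "individual"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(tab3[, "expertise"]), 0.5, tolerance = 1e-12)
  expect_equal(rowSums(tab3), 1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stationary distributions match closed forms and reject reducible chains", {
  expect_equal(stationaryDistribution(matrix(0.5, 2, 2))@pi, c(0.5, 0.5))
  p <- stationaryDistribution(matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE))
  expect_equal(p@pi, c(5 / 6, 1 / 6))
  expect_error(stationaryDistribution(diag(2)), "not unique")
  # one absorbing state: unique stationary law concentrated on it
  expect_equal(stationaryDistribution(matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE))@pi,
               c(1, 0))
  expect_error(stationaryDistribution(matrix(c(0.9, 0.2, 0.5, 0.5), 2, byrow = TRUE)),
               "row-stochastic")

  set.seed(13)
  for (k in 1:30) {
    n <- sample(2:6, 1)
    P <- matrix(rgamma(n * n, 1), n); P <- P / rowSums(P)
    pi_pkg <- stationaryDistribution(P)@pi
    expect_lt(max(abs(pi_pkg - power_iter_pi(P))), 1e-8)
    expect_lt(max(abs(pi_pkg %*% P - pi_pkg)), 1e-10)
    expect_equal(stationaryDistribution(P, method = "power")@pi, pi_pkg,
                 tolerance = 1e-8)
  }
})
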