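test_that("softmax row probabilities match closed forms and shift invariance", {
  expect_equal(rowProbability(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(rowProbability(c(log(4), 0, 0)), c(2 / 3, 1 / 6, 1 / 6))
  eta <- c(0.3, -1.2, 2.1, 0)
  expect_equal(rowProbability(eta), rowProbability(eta + 5))
  expect_equal(sum(rowProbability(rnorm(6))), 1)
  expect_error(rowProbability(c(0, Inf)), "finite")
})

test_that("multinomial log likelihood includes the coefficient and edge cases", {
  expect_equal(multinomialLogLik(c(1, 1), c(0.5, 0.5)), log(0.5))
  expect_equal(multinomialLogLik(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  expect_equal(multinomialLogLik(c(2, 0), c(1, 0)), 0)
  expect_warning(ll <- multinomialLogLik(c(1, 1), c(1, 0)), "conflict")
  expect_identical(ll, -Inf)
  # agrees with dmultinom on a generic case
  expect_equal(multinomialLogLik(c(3, 1, 2), c(0.5, 0.2, 0.3)),
               dmultinom(c(3, 1, 2), prob = c(0.5, 0.2, 0.3), log = TRUE))
})

test_that("design assembly standardizes practice and indexes groups deterministically", {
  arts <- default_artists(c("A1", "A2", "A3"))  # practice 4, 6, 8
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l")),
                                  A2 = list(c("o1l", "o3l")),
                                  A3 = list(c("d1l", "d2l"))), arts)
  nb <- clusterNeighborhoods(distanceMatrix(corp))
  des <- buildDesign(corp, nb)
  expect_equal(des@z_practice, c(-1, 0, 1))
  expect_equal(des@native, c(0L, 1L, 0L))
  expect_equal(des@caste_index, 1:3)

  corp2 <- corp
  corp2@artists$caste_id[1] <- NA
  expect_error(buildDesign(corp2, nb), "A1 is missing covariate 'caste_id'")

  corp3 <- corp
  corp3@artists$practice_years <- rep(5, 3)
  expect_error(buildDesign(corp3, nb), "zero variance")
})

test_that("with no data the posterior reproduces the prior", {
  arts <- default_artists(sprintf("A%d", 1:5))
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l"))), arts)
  corp@loops <- corp@loops[0, ]  # zero-count design
  des <- buildDesign(corp, clusterNeighborhoods(distanceMatrix(corp)))
  fit <- fitKolam(des, kolamModel("m1"), matrices = "S", chains = 2L,
                  warmup = 300L, sampling = 600L, seed = 8L,
                  convergence = "none", compute_loglik = FALSE)
  al <- fit@blocks$S$draws[, grepl("alpha", colnames(fit@blocks$S$draws))]
  expect_lt(abs(mean(al)), 0.1)
  expect_equal(sd(as.vector(al)), 1, tolerance = 0.1)
  expect_equal(unname(quantile(as.vector(al), c(0.05, 0.95))),
               qnorm(c(0.05, 0.95)), tolerance = 0.12)
})

test_that("the intercept-only model recovers a known population matrix", {
  truth <- balanced_truth(sigma = 0, beta = 0)
  sim <- simulateDataset(truth, simConfig(n_artists = 50L, drawings_per_artist = 10L,
                                          loops_per_drawing = 2L, seed = 21L))
  des <- buildDesign(sim$corpus, clusterNeighborhoods(distanceMatrix(sim$corpus)),
                     cycle = FALSE)
  fit <- fitKolam(des, kolamModel("m1"), matrices = "S", chains = 2L,
                  warmup = 300L, sampling = 500L, seed = 2L,
                  convergence = "warn", compute_loglik = FALSE)
  est <- transitionMatrixEstimate(fit)$S
  expect_lt(max(abs(est - truth$S)), 0.03)
})

test_that("equality-constrained sigmas and structural zeros are honoured", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 6L, drawings_per_artist = 3L, seed = 2L))
  des <- buildDesign(sim$corpus, clusterNeighborhoods(distanceMatrix(sim$corpus)))

  fit_sh <- fitKolam(des, kolamModel("m2", sigma_sharing = "matrix"),
                     matrices = "S", chains = 1L, warmup = 100L, sampling = 120L,
                     seed = 1L, L_max = 15L, convergence = "none",
                     compute_loglik = FALSE)
  sig_cols <- grep("log_sigma", colnames(fit_sh@blocks$S$draws), value = TRUE)
  expect_equal(sig_cols, "S.all.log_sigma_artist")  # one sigma across all rows

  fit_sz <- fitKolam(des, kolamModel("m2", structural_zeros = TRUE),
                     matrices = "S", chains = 1L, warmup = 100L, sampling = 120L,
                     seed = 1L, L_max = 15L, convergence = "none",
                     compute_loglik = FALSE)
  est <- transitionMatrixEstimate(fit_sz)$S
  expect_identical(est["O", "D"], 0)
  expect_identical(est["D", "O"], 0)
  expect_equal(rowSums(est), rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the default synthetic fixture converges cleanly", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 20L, drawings_per_artist = 8L, seed = 1L))
  des <- buildDesign(sim$corpus, clusterNeighborhoods(distanceMatrix(sim$corpus)))
  fit <- fitKolam(des, kolamModel("m2"), matrices = "S", chains = 4L,
                  warmup = 600L, sampling = 1000L, seed = 1L, L_max = 80L,
                  target_accept = 0.95, convergence = "none")
  expect_lt(fit@mcmc$max_rhat, 1.01)
  expect_lte(fit@mcmc$div_rate, 0.02)

  # estimated rows are probability simplexes, at population and artist level
  est <- transitionMatrixEstimate(fit)
  expect_equal(rowSums(est$S), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  aid <- des@artist_ids[3]
  est_a <- transitionMatrixEstimate(fit, level = aid)
  expect_equal(rowSums(est_a$S), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(max(abs(est_a$S - est$S)), 0)  # artist level differs from population
  expect_error(transitionMatrixEstimate(fit, level = "ghost"), "unknown artist")

  # equilibrium occupancies are simplexes under both averaging orders
  eq <- equilibriumOccupancy(fit, artists = c("population", aid))
  expect_equal(rowSums(eq), rep(1, 2), tolerance = 1e-8, ignore_attr = TRUE)
  eq_d <- equilibriumOccupancy(fit, artists = aid, per_draw = TRUE)
  expect_equal(sum(eq_d), 1, tolerance = 1e-8)
  expect_true(all(eq >= 0) && all(eq_d >= 0))
})
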