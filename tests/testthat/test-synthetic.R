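test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simConfig(n_artists = 8L, drawings_per_artist = 4L, seed = 99L)
  s1 <- simulateDataset(config = cfg)
  s2 <- simulateDataset(config = cfg)
  d1 <- tempfile(); dir.create(d1); d2 <- tempfile(); dir.create(d2)
  writeDataset(s1$corpus, file.path(d1, "s"), file.path(d1, "v"), file.path(d1, "g"))
  writeDataset(s2$corpus, file.path(d2, "s"), file.path(d2, "v"), file.path(d2, "g"))
  for (f in c("s", "v", "g"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed changes the corpus
  s3 <- simulateDataset(config = simConfig(n_artists = 8L, drawings_per_artist = 4L,
                                           seed = 100L))
  expect_false(identical(s1$corpus@loops$states, s3$corpus@loops$states))
})

test_that("every simulated loop passes the grammar validator, wrap included", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 15L, drawings_per_artist = 6L, seed = 31L))
  codes <- canon_codes()
  for (st in sim$corpus@loops$states) {
    expect_gte(length(st), 1)
    expect_silent(encodeLoop(codes[st], sim$corpus@lexicon))
  }
})

test_that("with no group variation empirical frequencies converge to the truth", {
  truth <- balanced_truth(sigma = 0, beta = 0)
  # well over 50,000 transitions so every within-space row is visited often
  sim <- simulateDataset(truth, simConfig(n_artists = 2L, drawings_per_artist = 3000L,
                                          loops_per_drawing = 2L, mean_loop_length = 14,
                                          seed = 41L))
  cnt <- countTransitions(sim$corpus, cycle = FALSE)
  S_tot <- apply(cnt@S, c(2, 3), sum)
  expect_gt(sum(S_tot), 50000)
  S_hat <- S_tot / rowSums(S_tot)
  expect_lt(max(abs(S_hat - truth$S)), 0.02)
  for (s in c("O", "T", "D")) {
    W_tot <- apply(cnt@W[[s]], c(2, 3), sum)
    W_hat <- W_tot / rowSums(W_tot)
    expect_lt(max(abs(W_hat - truth$W[[s]])), 0.02)
  }
})

test_that("the default corpus shape emulates the field study", {
  sim <- simulateDataset(config = simConfig(seed = 77L))
  a <- sim$corpus@artists
  expect_equal(nrow(a), 192)
  expect_equal(nDrawings(sim$corpus), 192 * 16)
  expect_equal(length(unique(a$caste_id)), 19)
  # non-native share within the binomial 95% band around 0.18
  band <- qbinom(c(0.025, 0.975), 192, 0.18)
  expect_gte(sum(a$native), band[1])
  expect_lte(sum(a$native), band[2])
  # clustering the jittered coordinates at 500 m recovers the 8 neighbourhoods
  nb <- clusterNeighborhoods(distanceMatrix(sim$corpus))
  expect_equal(max(nb@assignment), 8)
  # and the recovered clusters coincide with the generator's memberships
  true_nb <- vapply(sim$artist_truth, `[[`, 0L, "neighborhood")[names(nb@assignment)]
  expect_equal(length(unique(paste(true_nb, nb@assignment))), 8)
})

test_that("per-artist empirical rows approach each artist's true matrices", {
  truth <- balanced_truth(sigma_artist = 1, sigma_caste = 0.2, sigma_neigh = 0.2)
  sim <- simulateDataset(truth, simConfig(n_artists = 3L, drawings_per_artist = 400L,
                                          loops_per_drawing = 2L, mean_loop_length = 8,
                                          seed = 55L))
  cnt <- countTransitions(sim$corpus, cycle = FALSE)
  for (i in 1:3) {
    S_hat <- cnt@S[i, , ] / rowSums(cnt@S[i, , ])
    expect_lt(max(abs(S_hat - sim$artist_truth[[i]]$mats$S)), 0.03)
  }
})
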