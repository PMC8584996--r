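test_that("loop transition pairs include the cyclic closure", {
  p <- loopTransitionPairs(c(1L, 2L))
  expect_equal(nrow(p), 2)
  expect_setequal(paste(p[, 1], p[, 2]), c("1 2", "2 1"))

  p1 <- loopTransitionPairs(5L)
  expect_equal(unname(p1), matrix(c(5L, 5L), 1))

  # o1 t1 d1 t2 in state indices
  p4 <- loopTransitionPairs(c(1L, 7L, 11L, 8L))
  expect_setequal(paste(p4[, 1], p4[, 2]), c("1 7", "7 11", "11 8", "8 1"))

  # no-closure mode drops the wrap pair
  p_nc <- loopTransitionPairs(c(1L, 7L, 11L, 8L), cycle = FALSE)
  expect_equal(nrow(p_nc), 3)
  expect_equal(nrow(loopTransitionPairs(5L, cycle = FALSE)), 0)
})

test_that("aggregate counts sum loops and match the worked example", {
  arts <- default_artists("A1")
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l"), "o1l")), arts)
  m <- aggregateCounts(corp, "A1")
  expect_equal(sum(m), 3)
  expect_equal(m["o1", "o2"], 1)
  expect_equal(m["o2", "o1"], 1)
  expect_equal(m["o1", "o1"], 1)
  expect_error(aggregateCounts(corp, "nope"), "unknown artist")
})

test_that("an artist without loops yields an all-zero matrix with a warning", {
  arts <- default_artists(c("A1", "A2"))
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l"))), arts)
  expect_warning(m <- aggregateCounts(corp, "A2"), "no loops")
  expect_equal(sum(m), 0)
})

test_that("factored counts are block sums of the aggregate matrix", {
  arts <- default_artists("A1")
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "t1l", "d1l", "t2l"))), arts)
  f <- factorCounts(aggregateCounts(corp, "A1"))
  expect_equal(f$S["O", "T"], 1); expect_equal(f$S["T", "D"], 1)
  expect_equal(f$S["D", "T"], 1); expect_equal(f$S["T", "O"], 1)
  expect_equal(sum(f$W$O) + sum(f$W$T) + sum(f$W$D), 0)

  corp2 <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l", "o1r"))), arts)
  f2 <- factorCounts(aggregateCounts(corp2, "A1"))
  expect_equal(f2$S["O", "O"], 3)
  expect_equal(f2$W$O["o1", "o2"], 1)
  expect_equal(f2$W$O["o2", "o1"], 1)
  expect_equal(f2$W$O["o1", "o1"], 1)  # chirality collapsed o1r -> o1, wrap o1->o1

  f0 <- factorCounts(matrix(0L, 14, 14))
  expect_equal(sum(f0$S), 0)
})

test_that("module counts equal a brute-force recount on random valid loops", {
  set.seed(42)
  loops <- replicate(300, rand_valid_loop(sample(1:12, 1)), simplify = FALSE)
  codes <- canon_codes()
  arts <- default_artists("A1")
  corp <- corpus_from_tokens(list(A1 = lapply(loops, function(s) codes[s])), arts)
  for (cyc in c(TRUE, FALSE)) {
    m <- aggregateCounts(corp, "A1", cycle = cyc)
    expect_equal(unname(unclass(m)), brute_count(loops, cycle = cyc),
                 ignore_attr = TRUE)
  }
})

test_that("counts conserve totals and are invariant to loop order", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 5L, drawings_per_artist = 4L, seed = 5L))
  corp <- sim$corpus
  cnt <- countTransitions(corp)
  for (i in seq_along(cnt@artist_ids)) {
    aid <- cnt@artist_ids[i]
    len_sum <- sum(lengths(corp@loops$states[corp@loops$artist_id == aid]))
    expect_equal(sum(cnt@S[i, , ]), len_sum)
    for (s in c("O", "T", "D")) {
      si <- match(s, c("O", "T", "D"))
      expect_equal(cnt@S[i, si, si], sum(cnt@W[[s]][i, , ]))
    }
    # grammar-validated input leaves the O<->D space cells empty
    expect_equal(cnt@S[i, 1, 3] + cnt@S[i, 3, 1], 0)
  }
  # permuting loop order leaves counts unchanged
  perm <- corp
  set.seed(1)
  ord <- sample(nrow(perm@loops))
  perm@loops <- perm@loops[ord, ]
  expect_equal(countTransitions(perm)@aggregate, cnt@aggregate)
})

test_that("counts export uses the long-form schema", {
  arts <- default_artists("A1")
  corp <- corpus_from_tokens(list(A1 = list(c("o1l", "o2l"))), arts)
  f <- tempfile(fileext = ".csv")
  exportCounts(countTransitions(corp), f)
  df <- read.csv(f)
  expect_named(df, c("artist_id", "matrix", "from_state", "to_state", "count"))
  expect_setequal(unique(df$matrix), c("space", "O", "T", "D"))
  expect_equal(sum(df$count[df$matrix == "space"]), 2)
})
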