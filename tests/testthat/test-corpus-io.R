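test_that("reading the three input files builds a validated corpus", {
  arts <- default_artists(c("A1", "A2"))
  loops <- list(A1 = list(c("o1l", "o2l"), c("o1l", "x1")),
                A2 = list(c("d1l", "d2r", "t1l")))
  corp <- corpus_from_tokens(loops, arts)
  expect_s4_class(corp, "KolamCorpus")
  expect_equal(nrow(corp@artists), 2)
  expect_equal(nrow(corp@loops), 3)
  expect_equal(sum(corp@decorative$count), 1)
  expect_equal(nDrawings(corp), 2)
})

test_that("sequence, survey and GPS validation errors are informative", {
  arts <- default_artists(c("A1", "A2"))
  expect_error(corpus_from_tokens(list(A9 = list(c("o1l", "o2l"))), arts),
               "unknown artist A9")

  bad_caste <- arts; bad_caste$caste_id[1] <- 25
  dir <- tempfile(); dir.create(dir)
  write.csv(bad_caste[, c("artist_id", "age", "practice_years", "native", "caste_id")],
            file.path(dir, "survey.csv"), row.names = FALSE)
  write.csv(arts[, c("artist_id", "lat", "lon")], file.path(dir, "gps.csv"),
            row.names = FALSE)
  writeLines("A1\tA1_d1\t1\to1l o2l", file.path(dir, "sequences.tsv"))
  expect_error(readDataset(file.path(dir, "sequences.tsv"), file.path(dir, "survey.csv"),
                           file.path(dir, "gps.csv"), caste_levels = 1:19, quiet = TRUE),
               "caste code outside")

  bad_gps <- arts; bad_gps$lat[2] <- 123
  write.csv(arts[, c("artist_id", "age", "practice_years", "native", "caste_id")],
            file.path(dir, "survey.csv"), row.names = FALSE)
  write.csv(bad_gps[, c("artist_id", "lat", "lon")], file.path(dir, "gps.csv"),
            row.names = FALSE)
  expect_error(readDataset(file.path(dir, "sequences.tsv"), file.path(dir, "survey.csv"),
                           file.path(dir, "gps.csv"), quiet = TRUE),
               "malformed coordinates")

  na_sv <- arts; na_sv$practice_years[1] <- NA
  write.csv(na_sv[, c("artist_id", "age", "practice_years", "native", "caste_id")],
            file.path(dir, "survey.csv"), row.names = FALSE)
  write.csv(arts[, c("artist_id", "lat", "lon")], file.path(dir, "gps.csv"),
            row.names = FALSE)
  expect_error(readDataset(file.path(dir, "sequences.tsv"), file.path(dir, "survey.csv"),
                           file.path(dir, "gps.csv"), quiet = TRUE),
               "missing practice_years")
})

test_that("an empty sequences file yields zero drawings with a warning", {
  arts <- default_artists("A1")
  dir <- tempfile(); dir.create(dir)
  writeLines(character(0), file.path(dir, "sequences.tsv"))
  write.csv(arts[, c("artist_id", "age", "practice_years", "native", "caste_id")],
            file.path(dir, "survey.csv"), row.names = FALSE)
  write.csv(arts[, c("artist_id", "lat", "lon")], file.path(dir, "gps.csv"),
            row.names = FALSE)
  expect_warning(
    corp <- readDataset(file.path(dir, "sequences.tsv"), file.path(dir, "survey.csv"),
                        file.path(dir, "gps.csv"), quiet = TRUE),
    "zero drawings")
  expect_equal(nDrawings(corp), 0)
})

test_that("write/read round-trip reproduces canonical files byte for byte", {
  sim <- simulateDataset(defaultGroundTruth(),
                         simConfig(n_artists = 6L, drawings_per_artist = 3L, seed = 7L))
  d1 <- tempfile(); dir.create(d1)
  p1 <- file.path(d1, c("s.tsv", "sv.csv", "g.csv"))
  writeDataset(sim$corpus, p1[1], p1[2], p1[3])
  corp2 <- readDataset(p1[1], p1[2], p1[3], quiet = TRUE)
  d2 <- tempfile(); dir.create(d2)
  p2 <- file.path(d2, c("s.tsv", "sv.csv", "g.csv"))
  writeDataset(corp2, p2[1], p2[2], p2[3])
  for (k in 1:3)
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  # same loops and decorative totals survive the round trip
  expect_equal(sort(lengths(corp2@loops$states)),
               sort(lengths(sim$corpus@loops$states)))
  expect_equal(sum(corp2@decorative$count), sum(sim$corpus@decorative$count))
})
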