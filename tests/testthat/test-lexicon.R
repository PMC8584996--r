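test_that("packaged default lexicon satisfies all structural invariants", {
  lex <- defaultLexicon()
  e <- lex@entries
  expect_s4_class(lex, "GestureLexicon")
  expect_equal(nrow(e), 29)
  expect_equal(sum(e$space == "X"), 3)
  expect_true(all(is.na(e$state[e$space == "X"])))
  loop <- e[e$space != "X", ]
  expect_setequal(unique(loop$state), 1:14)
  st <- kolamStates()
  expect_equal(table(st$space)[c("O", "T", "D")],
               table(factor(c(rep("O", 6), rep("T", 4), rep("D", 4)),
                            levels = c("O", "T", "D")))[c("O", "T", "D")],
               ignore_attr = TRUE)
  # chirality pairs collapse onto one state
  expect_equal(loop$state[loop$raw_code == "o1l"], loop$state[loop$raw_code == "o1r"])
  expect_equal(loop$state[loop$raw_code == "d3l"], loop$state[loop$raw_code == "d3r"])
})

test_that("malformed lexicon files raise distinct validation errors", {
  base <- read.csv(system.file("extdata", "kolam_lexicon.csv", package = "KolamMarkov"),
                   colClasses = "character")
  write_lex <- function(df) {
    f <- tempfile(fileext = ".csv")
    write.csv(df, f, row.names = FALSE, quote = FALSE, na = "")
    f
  }
  expect_error(loadLexicon(write_lex(base[-1, ])), "29")
  dup <- base; dup$raw_code[2] <- dup$raw_code[1]
  expect_error(loadLexicon(write_lex(dup)), "duplicate")
  holes <- base; holes$model_state[holes$raw_code == "o6"] <- ""
  expect_error(loadLexicon(write_lex(holes)), "non-total|model_state")
  wrong <- base; wrong$space[wrong$raw_code == "o6"] <- "D"
  expect_error(loadLexicon(write_lex(wrong)), "6 O \\+ 4 T \\+ 4 D")
  expect_error(loadLexicon(tempfile()), "not found")
})

test_that("encodeLoop maps tokens, strips decoratives and enforces the grammar", {
  lex <- defaultLexicon()
  lp <- encodeLoop(c("o1l", "t1l", "d1l", "t2l"), lex)
  expect_equal(stateSpace(lp$states), c("O", "T", "D", "T"))
  expect_length(lp$states, 4)

  # orthogonal adjacent to diagonal is ungrammatical, wrap pair included
  expect_error(encodeLoop(c("o1l", "d1l"), lex), "grammar")
  expect_error(encodeLoop(c("o1l", "t1l", "d1l"), lex), "grammar")  # wrap d -> o
  expect_warning(encodeLoop(c("o1l", "d1l"), lex, permissive = TRUE), "grammar")

  dec <- encodeLoop(c("o1l", "x1", "o2l"), lex)
  expect_equal(length(dec$states), 2)
  expect_equal(unname(dec$decorative["x1"]), 1L)

  expect_error(encodeLoop(c("o1l", "zzz"), lex), "'zzz' at position 2")
  expect_error(encodeLoop(character(0), lex), "empty")
})
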