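## Reading and writing the three standard input files:
##   sequences: UTF-8 TSV, one loop per line:
##     artist_id <tab> drawing_id <tab> loop_index <tab> code code code ...
##   survey: CSV with header artist_id,age,practice_years,native,caste_id
##   gps:    CSV with header artist_id,lat,lon

## Internal constructor shared by readDataset() and the simulator.
makeCorpus <- function(lexicon, artists, loops, decorative) {
  if (is.null(loops) || !nrow(loops)) {
    loops <- data.frame(artist_id = character(0), drawing_id = character(0),
                        loop_index = integer(0), stringsAsFactors = FALSE)
    loops$states <- list()
  }
  if (is.null(decorative) || !nrow(decorative)) {
    decorative <- data.frame(artist_id = character(0), drawing_id = character(0),
                             raw_code = character(0), count = integer(0),
                             stringsAsFactors = FALSE)
  }
  methods::new("KolamCorpus", lexicon = lexicon, artists = artists,
               loops = loops, decorative = decorative)
}

readSurvey <- function(path, caste_levels = NULL) {
  sv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("artist_id", "age", "practice_years", "native", "caste_id")
  if (!all(need %in% names(sv)))
    stopf("survey file must have columns %s", paste(need, collapse = ","))
  sv$artist_id <- as.character(sv$artist_id)
  for (col in c("age", "practice_years", "native", "caste_id")) {
    if (anyNA(sv[[col]]))
      stopf("missing %s for artist(s) %s", col,
            paste(sv$artist_id[is.na(sv[[col]])], collapse = ", "))
  }
  if (!all(sv$native %in% c(0L, 1L)))
    stopf("native must be coded 0 (native) / 1 (non-native)")
  if (any(sv$practice_years < 0)) stopf("practice_years must be non-negative")
  if (any(sv$caste_id != round(sv$caste_id) | sv$caste_id < 1))
    stopf("caste_id must be a positive integer category")
  if (!is.null(caste_levels) && !all(sv$caste_id %in% caste_levels))
    stopf("caste code outside declared categories: %s",
          paste(unique(sv$caste_id[!sv$caste_id %in% caste_levels]), collapse = ", "))
  sv
}

readGps <- function(path) {
  gps <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("artist_id", "lat", "lon") %in% names(gps)))
    stopf("gps file must have columns artist_id,lat,lon")
  gps$artist_id <- as.character(gps$artist_id)
  if (anyNA(gps$lat) || anyNA(gps$lon) ||
      any(abs(gps$lat) > 90) || any(abs(gps$lon) > 180))
    stopf("malformed coordinates in gps file")
  gps
}

#' Read a kolam dataset from its three standard input files
#'
#' Parses the loop-sequence TSV (one loop per line: artist id, drawing id,
#' loop index, then whitespace-separated gesture codes), the artist survey
#' CSV and the GPS CSV into a validated [KolamCorpus-class]. Decorative
#' gestures are stripped from loops and recorded per drawing; every loop is
#' checked against the adjacency grammar.
#'
#' @param sequences_path,survey_path,gps_path Paths to the three input files.
#' @param lexicon A [GestureLexicon-class] (defaults to the packaged one).
#' @param permissive Passed to [encodeLoop()].
#' @param caste_levels Optional vector of admissible caste codes; survey rows
#'   outside it raise a validation error.
#' @param quiet Suppress the summary message.
#' @return A [KolamCorpus-class].
#' @export
readDataset <- function(sequences_path, survey_path, gps_path,
                        lexicon = defaultLexicon(), permissive = FALSE,
                        caste_levels = NULL, quiet = FALSE) {
  sv <- readSurvey(survey_path, caste_levels)
  gps <- readGps(gps_path)
  missing_gps <- setdiff(sv$artist_id, gps$artist_id)
  if (length(missing_gps))
    stopf("missing coordinates for artist(s) %s", paste(missing_gps, collapse = ", "))
  artists <- merge(sv, gps, by = "artist_id", sort = TRUE)

  lines <- readLines(sequences_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) warnf("empty sequences file: dataset has zero drawings")

  loop_rows <- vector("list", length(lines))
  deco_rows <- list()
  for (li in seq_along(lines)) {
    f <- strsplit(trimws(lines[li]), "[ \t]+")[[1L]]
    if (length(f) < 4L)
      stopf("sequence line %d: expected artist_id, drawing_id, loop_index and at least one gesture code", li)
    aid <- f[1L]; did <- f[2L]
    lix <- suppressWarnings(as.integer(f[3L]))
    if (is.na(lix)) stopf("sequence line %d: loop_index is not an integer", li)
    if (!aid %in% artists$artist_id)
      stopf("drawing %s references unknown artist %s", did, aid)
    enc <- encodeLoop(f[-(1:3)], lexicon, permissive = permissive)
    if (length(enc$states))
      loop_rows[[li]] <- list(artist_id = aid, drawing_id = did,
                              loop_index = lix, states = enc$states)
    if (length(enc$decorative))
      deco_rows[[length(deco_rows) + 1L]] <-
        data.frame(artist_id = aid, drawing_id = did,
                   raw_code = names(enc$decorative),
                   count = as.integer(enc$decorative), stringsAsFactors = FALSE)
  }
  loop_rows <- Filter(Negate(is.null), loop_rows)
  loops <- if (length(loop_rows)) {
    df <- data.frame(artist_id = vapply(loop_rows, `[[`, "", "artist_id"),
                     drawing_id = vapply(loop_rows, `[[`, "", "drawing_id"),
                     loop_index = vapply(loop_rows, `[[`, 0L, "loop_index"),
                     stringsAsFactors = FALSE)
    df$states <- lapply(loop_rows, `[[`, "states")
    df
  } else NULL
  deco <- if (length(deco_rows)) {
    d <- do.call(rbind, deco_rows)
    stats::aggregate(count ~ artist_id + drawing_id + raw_code, d, sum)
  } else NULL

  corpus <- makeCorpus(lexicon, artists, loops, deco)
  if (!quiet)
    message(sprintf("read %d artists, %d drawings, %d loops",
                    nrow(artists), nDrawings(corpus), nrow(corpus@loops)))
  corpus
}

#' Write a corpus back to the three canonical input files
#'
#' Emits canonicalized files: loops sorted by artist, drawing and loop index,
#' each state rendered as the first raw code that maps to it, and a
#' drawing's decorative gestures appended to its first loop line. Reading
#' the written files back reproduces the same loops, covariates and
#' decorative counts.
#'
#' @param corpus A [KolamCorpus-class].
#' @param sequences_path,survey_path,gps_path Output paths.
#' @export
writeDataset <- function(corpus, sequences_path, survey_path, gps_path) {
  e <- corpus@lexicon@entries
  canon <- vapply(1:14, function(s) e$raw_code[match(s, e$state)], "")
  lp <- corpus@loops
  dec <- corpus@decorative
  lines <- character(0)
  if (nrow(lp)) {
    ord <- order(lp$artist_id, lp$drawing_id, lp$loop_index)
    lp <- lp[ord, , drop = FALSE]
    seen_drawing <- character(0)
    lines <- vapply(seq_len(nrow(lp)), function(i) {
      codes <- canon[lp$states[[i]]]
      key <- paste(lp$artist_id[i], lp$drawing_id[i])
      if (!key %in% seen_drawing) {
        seen_drawing <<- c(seen_drawing, key)
        dd <- dec[dec$artist_id == lp$artist_id[i] & dec$drawing_id == lp$drawing_id[i], , drop = FALSE]
        if (nrow(dd)) {
          dd <- dd[order(dd$raw_code), , drop = FALSE]
          codes <- c(codes, rep(dd$raw_code, dd$count))
        }
      }
      paste(lp$artist_id[i], lp$drawing_id[i], lp$loop_index[i],
            paste(codes, collapse = " "), sep = "\t")
    }, "")
  }
  writeLines(lines, sequences_path, useBytes = TRUE)
  a <- corpus@artists[order(corpus@artists$artist_id), , drop = FALSE]
  utils::write.csv(a[, c("artist_id", "age", "practice_years", "native", "caste_id")],
                   survey_path, row.names = FALSE, quote = FALSE)
  gps <- data.frame(artist_id = a$artist_id,
                    lat = sprintf("%.6f", a$lat),   # ~0.1 m, canonical form
                    lon = sprintf("%.6f", a$lon), stringsAsFactors = FALSE)
  utils::write.csv(gps, gps_path, row.names = FALSE, quote = FALSE)
  invisible(c(sequences_path, survey_path, gps_path))
}

#' Number of drawings in a corpus
#' @param corpus A [KolamCorpus-class].
#' @export
nDrawings <- function(corpus) {
  keys <- unique(c(paste(corpus@loops$artist_id, corpus@loops$drawing_id),
                   paste(corpus@decorative$artist_id, corpus@decorative$drawing_id)))
  length(keys)
}

#' @describeIn readDataset Corpus summary.
#' @param object A `KolamCorpus`.
#' @export
setMethod("show", "KolamCorpus", function(object) {
  cat("KolamCorpus:", nrow(object@artists), "artists,", nDrawings(object),
      "drawings,", nrow(object@loops), "loops\n")
  if (nrow(object@artists))
    cat("  castes:", length(unique(object@artists$caste_id)),
        " non-native:", sum(object@artists$native == 1), "\n")
})
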