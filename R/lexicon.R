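#' Gesture lexicon for kolam transcriptions
#'
#' The lexicon maps the 29 raw gesture codes used when transcribing kolam
#' drawings onto the internal model: 26 loop gestures (12 left/right chiral
#' pairs plus 2 achiral gestures) collapse onto 14 model states, and 3
#' decorative gestures carry no state because they are never part of a loop.
#'
#' `loadLexicon()` reads and validates a lexicon CSV with header
#' `raw_code,space,chirality,model_state` where `model_state` is the 0-based
#' state index (0-13, ordered o1-o6, t1-t4, d1-d4) and is empty for
#' decorative gestures (space `"X"`). `defaultLexicon()` returns the lexicon
#' shipped with the package. The raw-code spellings of any field lexicon can
#' be substituted by pointing `loadLexicon()` at a user file with the same
#' layout.
#'
#' @param path Path to a lexicon CSV file.
#' @return A [GestureLexicon-class] object.
#' @export
#' @examples
#' lex <- defaultLexicon()
#' lex
loadLexicon <- function(path) {
  if (!file.exists(path)) stopf("lexicon file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character", "character"))
  need <- c("raw_code", "space", "chirality", "model_state")
  if (!all(need %in% names(raw)))
    stopf("lexicon file must have columns %s", paste(need, collapse = ", "))
  raw$raw_code <- trimws(raw$raw_code)
  if (nrow(raw) != 29L)
    stopf("lexicon must contain exactly 29 gestures, found %d", nrow(raw))
  dup <- raw$raw_code[duplicated(raw$raw_code)]
  if (length(dup)) stopf("duplicate raw_code in lexicon: %s", paste(unique(dup), collapse = ", "))
  if (!all(raw$space %in% c("O", "D", "T", "X")))
    stopf("gesture space must be one of O, D, T, X")
  if (!all(raw$chirality %in% c("left", "right", "none")))
    stopf("chirality must be one of left, right, none")

  ms <- suppressWarnings(as.integer(raw$model_state))
  deco <- raw$space == "X"
  if (sum(deco) != 3L)
    stopf("lexicon must declare exactly 3 decorative gestures, found %d", sum(deco))
  if (any(!is.na(ms[deco])))
    stopf("decorative gestures must have an empty model_state")
  if (any(is.na(ms[!deco])))
    stopf("non-total mapping: loop gestures without a model_state: %s",
          paste(raw$raw_code[!deco & is.na(ms)], collapse = ", "))
  if (any(ms[!deco] < 0L | ms[!deco] > 13L))
    stopf("model_state must lie in 0..13")

  state <- ifelse(deco, NA_integer_, ms + 1L)
  ## Declared space must agree with the canonical partition of the 14 states,
  ## which fixes the 6/4/4 split of orthogonal/transitional/diagonal states.
  implied <- KOLAM_STATE_SPACE[state[!deco]]
  if (any(implied != raw$space[!deco]))
    stopf("state counts not 6 O + 4 T + 4 D: gesture(s) %s declare a space inconsistent with their model_state",
          paste(raw$raw_code[!deco][implied != raw$space[!deco]], collapse = ", "))
  if (!setequal(unique(state[!deco]), 1:14))
    stopf("non-total mapping: model states must cover all 14 states exactly")

  entries <- data.frame(raw_code = raw$raw_code, space = raw$space,
                        chirality = raw$chirality, state = state,
                        stringsAsFactors = FALSE)
  methods::new("GestureLexicon", entries = entries, states = kolamStates())
}

#' @rdname loadLexicon
#' @export
defaultLexicon <- function() {
  loadLexicon(system.file("extdata", "kolam_lexicon.csv", package = "KolamMarkov",
                          mustWork = TRUE))
}

#' Geometric space of model states
#'
#' @param states Integer vector of model states (1-14).
#' @return Character vector of spaces (`"O"`, `"T"`, `"D"`).
#' @export
stateSpace <- function(states) KOLAM_STATE_SPACE[states]

## Return index of first grammar violation among consecutive + wrap pairs,
## or 0L if the loop is valid. O and D states must never be adjacent.
grammarViolation <- function(states) {
  if (length(states) < 2L) return(0L)
  sp <- KOLAM_STATE_SPACE[states]
  nxt <- c(sp[-1L], sp[1L])
  bad <- which((sp == "O" & nxt == "D") | (sp == "D" & nxt == "O"))
  if (length(bad)) bad[1L] else 0L
}

#' Encode a token sequence as a loop of model states
#'
#' Maps raw gesture codes onto model states, strips decorative gestures
#' (returning their counts separately for drawing-level bookkeeping), and
#' validates the adjacency grammar: orthogonal and diagonal states are only
#' ever connected through transitional states, including the wrap-around
#' pair from the last gesture back to the first.
#'
#' @param tokens Character vector of raw gesture codes.
#' @param lexicon A [GestureLexicon-class].
#' @param permissive If `TRUE`, a grammar violation is downgraded from an
#'   error to a warning (for noisy field transcriptions).
#' @return A list with class `"KolamLoop"`: `states` (integer vector of
#'   model states, possibly empty if all tokens were decorative) and
#'   `decorative` (named integer vector of decorative-gesture counts).
#' @export
#' @examples
#' lex <- defaultLexicon()
#' encodeLoop(c("o1l", "t1r", "d1l", "t2l"), lex)
encodeLoop <- function(tokens, lexicon = defaultLexicon(), permissive = FALSE) {
  if (!length(tokens)) stopf("cannot encode an empty token sequence")
  e <- lexicon@entries
  idx <- match(tokens, e$raw_code)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stopf("unknown gesture token '%s' at position %d", tokens[p], p)
  }
  deco <- e$space[idx] == "X"
  dcounts <- integer(0)
  if (any(deco)) {
    tb <- table(tokens[deco])
    dcounts <- stats::setNames(as.integer(tb), names(tb))
  }
  states <- e$state[idx][!deco]
  if (length(states)) {
    bad <- grammarViolation(states)
    if (bad > 0L) {
      msg <- sprintf(
        "grammar violation: orthogonal and diagonal gestures adjacent at loop position %d (%s -> %s)",
        bad, KOLAM_STATE_NAMES[states[bad]],
        KOLAM_STATE_NAMES[states[if (bad == length(states)) 1L else bad + 1L]])
      if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
    }
  }
  structure(list(states = as.integer(states), decorative = dcounts),
            class = "KolamLoop")
}

#' @describeIn loadLexicon Number of entries, decorative gestures and states.
#' @param object A `GestureLexicon`.
#' @export
setMethod("show", "GestureLexicon", function(object) {
  e <- object@entries
  cat("GestureLexicon with", nrow(e), "gestures:",
      sum(e$space != "X"), "loop gestures over 14 model states (6 O / 4 T / 4 D),",
      sum(e$space == "X"), "decorative\n")
})
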