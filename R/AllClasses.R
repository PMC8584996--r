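#' @import methods
NULL

## Canonical model-state table: 14 loop states ordered by geometric space
## (O, T, D) -- six orthogonal, four transitional, four diagonal states.
KOLAM_SPACES <- c("O", "T", "D")
KOLAM_STATE_SPACE <- rep(KOLAM_SPACES, c(6L, 4L, 4L))
KOLAM_STATE_NAMES <- c(paste0("o", 1:6), paste0("t", 1:4), paste0("d", 1:4))

#' Table of the 14 canonical model states
#'
#' Loop gestures map (chirality collapsed) onto 14 model states partitioned
#' into three geometric spaces: 6 orthogonal, 4 transitional and 4 diagonal
#' states. Space order is fixed as (O, T, D) throughout the package.
#'
#' @return A data.frame with columns `state` (1-based index), `name`
#'   (canonical state name, e.g. `"o1"`) and `space` (`"O"`, `"T"` or `"D"`).
#' @export
#' @examples
#' kolamStates()
kolamStates <- function() {
  data.frame(state = 1:14, name = KOLAM_STATE_NAMES, space = KOLAM_STATE_SPACE,
             stringsAsFactors = FALSE)
}

#' @rdname GestureLexicon-class
#' @aliases GestureLexicon
#' @exportClass GestureLexicon
setClass("GestureLexicon",
         representation(entries = "data.frame", states = "data.frame"))

setValidity("GestureLexicon", function(object) {
  e <- object@entries
  msgs <- character(0)
  if (nrow(e) != 29L)
    msgs <- c(msgs, sprintf("lexicon must contain exactly 29 gestures, found %d", nrow(e)))
  if (anyDuplicated(e$raw_code))
    msgs <- c(msgs, "duplicate raw_code entries")
  deco <- e$space == "X"
  if (sum(deco) != 3L)
    msgs <- c(msgs, sprintf("lexicon must contain exactly 3 decorative gestures, found %d", sum(deco)))
  if (any(!is.na(e$state[deco])))
    msgs <- c(msgs, "decorative gestures must not carry a model state")
  if (any(is.na(e$state[!deco])))
    msgs <- c(msgs, "every loop gesture must map to a model state")
  st <- e$state[!deco]
  if (length(st) && !setequal(unique(st), 1:14))
    msgs <- c(msgs, "model-state mapping must be surjective onto the 14 states")
  if (length(msgs)) msgs else TRUE
})

#' @rdname KolamCorpus-class
#' @aliases KolamCorpus
#' @exportClass KolamCorpus
setClass("KolamCorpus",
         representation(lexicon = "GestureLexicon", artists = "data.frame",
                        loops = "data.frame", decorative = "data.frame"))

setValidity("KolamCorpus", function(object) {
  msgs <- character(0)
  a <- object@artists
  if (nrow(a) && anyDuplicated(a$artist_id))
    msgs <- c(msgs, "artist_ids must be unique")
  if (nrow(object@loops)) {
    bad <- setdiff(unique(object@loops$artist_id), a$artist_id)
    if (length(bad))
      msgs <- c(msgs, paste0("loops reference unknown artists: ",
                             paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname KolamCounts-class
#' @aliases KolamCounts
#' @exportClass KolamCounts
setClass("KolamCounts",
         representation(artist_ids = "character", aggregate = "array",
                        S = "array", W = "list", cycle = "logical"))

setValidity("KolamCounts", function(object) {
  msgs <- character(0)
  n <- length(object@artist_ids)
  if (!identical(dim(object@aggregate), c(n, 14L, 14L)))
    msgs <- c(msgs, "aggregate must be an n x 14 x 14 array")
  if (!identical(dim(object@S), c(n, 3L, 3L)))
    msgs <- c(msgs, "S must be an n x 3 x 3 array")
  if (!identical(names(object@W), c("O", "T", "D")))
    msgs <- c(msgs, "W must be a list with elements O, T, D")
  if (!length(msgs) && n) {
    for (i in seq_len(n)) {
      Si <- object@S[i, , ]
      for (s in seq_along(KOLAM_SPACES)) {
        ws <- object@W[[KOLAM_SPACES[s]]][i, , ]
        if (abs(Si[s, s] - sum(ws)) > 1e-8) {
          msgs <- c(msgs, "within-space totals must equal the diagonal of S")
          break
        }
      }
      if (length(msgs)) break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname NeighborhoodAssignment-class
#' @aliases NeighborhoodAssignment
#' @exportClass NeighborhoodAssignment
setClass("NeighborhoodAssignment",
         representation(assignment = "integer", threshold_m = "numeric",
                        linkage = "character"))

setValidity("NeighborhoodAssignment", function(object) {
  if (!length(object@assignment)) return("assignment must label at least one artist")
  if (is.null(names(object@assignment))) return("assignment must be named by artist_id")
  if (anyNA(object@assignment)) return("every artist must be labelled")
  TRUE
})

#' @rdname KolamDesign-class
#' @aliases KolamDesign
#' @exportClass KolamDesign
setClass("KolamDesign",
         representation(counts = "KolamCounts", artist_ids = "character",
                        z_practice = "numeric", native = "integer",
                        caste_index = "integer", neighborhood_index = "integer",
                        n_castes = "integer", n_neighborhoods = "integer",
                        practice_center = "numeric", practice_scale = "numeric"))

setValidity("KolamDesign", function(object) {
  n <- length(object@artist_ids)
  msgs <- character(0)
  for (nm in c("z_practice", "native", "caste_index", "neighborhood_index"))
    if (length(slot(object, nm)) != n)
      msgs <- c(msgs, sprintf("%s must have one entry per artist", nm))
  if (n > 1 && (abs(mean(object@z_practice)) > 1e-6 ||
                abs(stats::sd(object@z_practice) - 1) > 1e-6))
    msgs <- c(msgs, "z_practice must be standardized (mean 0, sd 1)")
  if (length(object@caste_index) && max(object@caste_index) > object@n_castes)
    msgs <- c(msgs, "caste index out of range")
  if (length(object@neighborhood_index) &&
      max(object@neighborhood_index) > object@n_neighborhoods)
    msgs <- c(msgs, "neighborhood index out of range")
  if (length(msgs)) msgs else TRUE
})

#' @rdname KolamModelSpec-class
#' @aliases KolamModelSpec
#' @exportClass KolamModelSpec
setClass("KolamModelSpec",
         representation(name = "character", terms = "character",
                        sigma_sharing = "character", structural_zeros = "logical"))

KOLAM_TERMS <- c("artist", "caste", "neighborhood", "practice", "nativity")

setValidity("KolamModelSpec", function(object) {
  if (!all(object@terms %in% KOLAM_TERMS))
    return(paste0("terms must be a subset of: ", paste(KOLAM_TERMS, collapse = ", ")))
  if (!object@sigma_sharing %in% c("row", "matrix"))
    return("sigma_sharing must be 'row' or 'matrix'")
  TRUE
})

#' @rdname KolamPriors-class
#' @aliases KolamPriors
#' @exportClass KolamPriors
setClass("KolamPriors",
         representation(intercept_sd = "numeric", slope_sd = "numeric",
                        sigma_scale = "numeric"))

setValidity("KolamPriors", function(object) {
  if (any(c(object@intercept_sd, object@slope_sd, object@sigma_scale) <= 0))
    return("all prior scales must be positive")
  TRUE
})

#' @rdname KolamFit-class
#' @aliases KolamFit
#' @exportClass KolamFit
setClass("KolamFit",
         representation(model = "KolamModelSpec", priors = "KolamPriors",
                        design = "KolamDesign", blocks = "list",
                        diagnostics = "data.frame", loglik = "matrix",
                        obs = "data.frame", mcmc = "list"))

#' @rdname LooResult-class
#' @aliases LooResult
#' @exportClass LooResult
setClass("LooResult",
         representation(elpd_loo = "numeric", se = "numeric", p_loo = "numeric",
                        pointwise = "data.frame", n_draws = "integer"))

#' @rdname ICCTable-class
#' @aliases ICCTable
#' @exportClass ICCTable
setClass("ICCTable", representation(table = "matrix"))

setValidity("ICCTable", function(object) {
  tab <- object@table
  if (any(tab < -1e-12)) return("ICC entries must be non-negative")
  if (any(abs(rowSums(tab) - 1) > 1e-9)) return("each ICC row must sum to 1")
  TRUE
})

#' @rdname StationaryDistribution-class
#' @aliases StationaryDistribution
#' @exportClass StationaryDistribution
setClass("StationaryDistribution",
         representation(pi = "numeric", residual = "numeric", method = "character"))

setValidity("StationaryDistribution", function(object) {
  if (any(object@pi < -1e-12)) return("stationary probabilities must be non-negative")
  if (abs(sum(object@pi) - 1) > 1e-9) return("stationary probabilities must sum to 1")
  TRUE
})
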