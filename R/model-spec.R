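#' Transition-model specifications
#'
#' A model specification names the terms entering the linear predictor of
#' every transition-matrix row: partially pooled offsets for `artist`,
#' `caste` and `neighborhood`, plus fixed slopes for standardized `practice`
#' duration and the `nativity` indicator (0 = native, 1 = non-native).
#'
#' Seven named variants form the comparison ladder:
#' \describe{
#'   \item{m1}{intercepts only}
#'   \item{m2}{+ artist}
#'   \item{m3}{+ artist + practice}
#'   \item{m4}{+ artist + practice + nativity}
#'   \item{m5}{+ artist + caste}
#'   \item{m6}{+ artist + caste + neighborhood}
#'   \item{m7 (= full)}{all five terms}
#' }
#'
#' @param name One of `"m1"`..`"m7"`, `"full"`, or `"custom"`.
#' @param terms For `name = "custom"`, character subset of
#'   `c("artist", "caste", "neighborhood", "practice", "nativity")`.
#' @param sigma_sharing `"row"` (one group standard deviation per term,
#'   matrix and row -- the default) or `"matrix"` (equality constraint:
#'   shared across the rows of a matrix).
#' @param structural_zeros If `TRUE`, the grammar-forbidden between-space
#'   cells (O to D and D to O) are fixed at probability zero instead of
#'   being free softmax categories.
#' @return A [KolamModelSpec-class].
#' @export
#' @examples
#' kolamModel("full")
#' kolamModelSet()  # the seven-variant ladder
kolamModel <- function(name = "full", terms = NULL,
                       sigma_sharing = "row", structural_zeros = FALSE) {
  registry <- list(
    m1 = character(0),
    m2 = "artist",
    m3 = c("artist", "practice"),
    m4 = c("artist", "practice", "nativity"),
    m5 = c("artist", "caste"),
    m6 = c("artist", "caste", "neighborhood"),
    m7 = KOLAM_TERMS)
  if (name == "full") name <- "m7"
  if (name == "custom") {
    if (is.null(terms)) stopf("custom models must declare their terms")
  } else {
    if (!name %in% names(registry)) stopf("unknown model variant '%s'", name)
    terms <- registry[[name]]
  }
  methods::new("KolamModelSpec", name = name, terms = terms,
               sigma_sharing = sigma_sharing,
               structural_zeros = structural_zeros)
}

#' @rdname kolamModel
#' @export
kolamModelSet <- function(sigma_sharing = "row", structural_zeros = FALSE) {
  stats::setNames(lapply(paste0("m", 1:7), kolamModel,
                         sigma_sharing = sigma_sharing,
                         structural_zeros = structural_zeros),
                  paste0("m", 1:7))
}

#' Weakly informative default priors
#'
#' All parameters live on the logit scale: Normal(0, `intercept_sd`) for row
#' intercepts, Normal(0, `slope_sd`) for the practice and nativity slopes,
#' and half-Normal(0, `sigma_scale`) for the group standard deviations.
#' Unit scales keep prior-predictive transition rows away from the simplex
#' corners while allowing rows as skewed as those seen in field corpora.
#'
#' @param intercept_sd,slope_sd,sigma_scale Positive scales.
#' @return A [KolamPriors-class].
#' @export
defaultPriors <- function(intercept_sd = 1, slope_sd = 1, sigma_scale = 1) {
  methods::new("KolamPriors", intercept_sd = intercept_sd,
               slope_sd = slope_sd, sigma_scale = sigma_scale)
}

#' @describeIn kolamModel Specification summary.
#' @param object A `KolamModelSpec`.
#' @export
setMethod("show", "KolamModelSpec", function(object) {
  cat("KolamModelSpec '", object@name, "': terms = {",
      paste(object@terms, collapse = ", "), "}, sigma per ",
      object@sigma_sharing,
      if (object@structural_zeros) ", structural zeros on O<->D\n" else "\n",
      sep = "")
})
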