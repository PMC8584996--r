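#' Assemble the model design from a corpus and neighbourhood labels
#'
#' Pairs each artist's factored transition counts with her covariates:
#' practice duration standardized to mean 0, sd 1 (sample sd, denominator
#' n - 1), the nativity indicator, and caste / neighbourhood category
#' indices assigned by first appearance when artists are sorted by id.
#'
#' @param corpus A [KolamCorpus-class].
#' @param neighborhoods A [NeighborhoodAssignment-class] covering every
#'   artist.
#' @param cycle Passed to [countTransitions()].
#' @param counts Optional precomputed [KolamCounts-class].
#' @return A [KolamDesign-class].
#' @export
buildDesign <- function(corpus, neighborhoods, cycle = TRUE, counts = NULL) {
  a <- corpus@artists[order(corpus@artists$artist_id), , drop = FALSE]
  if (!nrow(a)) stopf("empty design: corpus has no artists")
  for (col in c("age", "practice_years", "native", "caste_id"))
    if (anyNA(a[[col]]))
      stopf("artist %s is missing covariate '%s'",
            a$artist_id[which(is.na(a[[col]]))[1L]], col)
  lab <- neighborhoods@assignment
  missing_nb <- setdiff(a$artist_id, names(lab))
  if (length(missing_nb))
    stopf("artist %s has no neighborhood label", missing_nb[1L])

  mu <- mean(a$practice_years)
  sdev <- stats::sd(a$practice_years)
  if (!is.finite(sdev) || sdev == 0)
    stopf("cannot standardize practice: zero variance")
  z <- (a$practice_years - mu) / sdev

  reindex <- function(x) {
    lev <- unique(x)  # artists already sorted by id: first-appearance order
    as.integer(match(x, lev))
  }
  caste_index <- reindex(a$caste_id)
  nb_index <- reindex(as.integer(lab[a$artist_id]))

  if (is.null(counts)) counts <- countTransitions(corpus, cycle = cycle)
  if (!identical(counts@artist_ids, a$artist_id))
    stopf("counts and corpus cover different artists")

  methods::new("KolamDesign", counts = counts, artist_ids = a$artist_id,
               z_practice = z, native = as.integer(a$native),
               caste_index = caste_index, neighborhood_index = nb_index,
               n_castes = max(caste_index), n_neighborhoods = max(nb_index),
               practice_center = mu, practice_scale = sdev)
}

#' @describeIn buildDesign Design summary.
#' @param object A `KolamDesign`.
#' @export
setMethod("show", "KolamDesign", function(object) {
  cat("KolamDesign:", length(object@artist_ids), "artists,",
      object@n_castes, "castes,", object@n_neighborhoods, "neighborhoods;",
      sum(object@counts@S), "transitions\n")
})
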