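#' Published stage-at-diagnosis counts for south-west Sweden melanoma
#'
#' The published tabulation of the 10,302 analytic cutaneous malignant
#' melanoma cases diagnosed 2008-2016 in the Southern and Western Swedish
#' Health Care Regions: stage-specific counts (I, II, III-IV) by five-year
#' age band, and by small-area deprivation quintile within three scopes —
#' the whole study region, Gothenburg and Malmoe. These printed margins are
#' used as reference input for the proportion-based analyses; the underlying
#' case-level records are confidential and are emulated by the synthetic
#' generator instead.
#'
#' @param scope Optional filter: `"age"`, `"region"`, `"gothenburg"` or
#'   `"malmoe"`.
#' @return Tibble with columns `scope`, `group`, `stage`, `n`.
#' @export
melanoma_stage_counts <- function(scope = NULL) {
  path <- system.file("extdata", "melanoma_stage_counts.csv",
                      package = "stagemap", mustWork = TRUE)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(scope)) {
    scope <- match.arg(scope, unique(d$scope))
    d <- d[d$scope == scope, ]
  }
  d
}
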