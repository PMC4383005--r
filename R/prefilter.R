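#' Variation filter for expressed, changing genes
#'
#' The pre-analysis gene filter: a gene is retained iff its log2 range
#' across all samples (max - min, equivalently the largest change between
#' any pair of samples) is at least `minRange` AND its maximum log2 level
#' in at least one sample is at least `minLevel`. Both comparisons are
#' inclusive (`>=`), so a gene changing by exactly one log2 unit passes.
#'
#' The range is taken across all samples pooled — both populations and all
#' stages — because the filter precedes any population split.
#'
#' @param em a \linkS4class{StageExpression}.
#' @param minRange minimum log2 change between some pair of samples,
#'   default 1.
#' @param minLevel minimum log2 level in at least one sample, default 3.
#' @return list with elements `expression` (the retained
#'   \linkS4class{StageExpression}, original gene order preserved) and
#'   `report` (n_input, n_retained and per-criterion failure counts).
#' @examples
#' d <- StageDesign(c("ES", "NE"), list(ES = "unsorted", NE = "HES5+"))
#' m <- matrix(c(5, 2, 5, 3.1), 2, 2,
#'             dimnames = list(c("flat", "up"), c("ES", "NE")))
#' em <- StageExpression(m, c("ES", "NE"), c("unsorted", "HES5+"), d)
#' variationFilter(em)$report
#' @export
variationFilter <- function(em, minRange = 1, minLevel = 3) {
  stopifnot(is(em, "StageExpression"), minRange >= 0, minLevel >= 0)
  if (nrow(em) == 0L) stop("empty expression matrix")
  v <- log2Values(em)
  mx <- apply(v, 1L, max)
  rng <- mx - apply(v, 1L, min)
  passRange <- rng >= minRange
  passLevel <- mx >= minLevel
  keep <- passRange & passLevel
  report <- list(
    n_input = nrow(v),
    n_retained = sum(keep),
    n_fail_range = sum(!passRange),
    n_fail_level = sum(!passLevel),
    min_range = minRange,
    min_level = minLevel)
  list(expression = em[keep, ], report = report)
}
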