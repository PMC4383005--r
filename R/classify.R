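#' Classify temporal expression patterns via cluster centroids
#'
#' The stage-wise clustering step: k-means is run on the per-gene,
#' baseline-subtracted stage trajectories of the Notch-active (HES5+)
#' samples (the zero baseline column included, features unstandardized so
#' the absolute log2 threshold theta keeps its meaning); each cluster
#' centroid's consecutive stage differences are then tested against the
#' pattern grammar, a cluster is matched to the first code it satisfies,
#' and member genes inherit their cluster's code. Clusters sharing a code
#' form one expression-pattern family. With the default grammar the codes
#' are mutually exclusive, so list order cannot change the outcome.
#'
#' @param delta a \linkS4class{DeltaExpression} (see [subtractBaseline()]).
#' @param k number of clusters, default 100 (intended for genome-scale
#'   filtered inputs; use a smaller k for small gene sets).
#' @param seed,nInit passed to [kmeansCluster()].
#' @param patterns list of \linkS4class{PatternCode}s, default
#'   [defaultPatternSet()] of the matrix's design.
#' @param population which population's trajectories to cluster, default
#'   `"HES5+"`.
#' @return a \linkS4class{PatternAssignment}.
#' @export
classifyClusters <- function(delta, k = 100L, seed = 0L, nInit = 10L,
                             patterns = NULL, population = "HES5+") {
  stopifnot(is(delta, "DeltaExpression"))
  if (is.null(patterns)) patterns <- defaultPatternSet(stageDesign(delta))
  traj <- stageTrajectories(delta, population)
  cr <- kmeansCluster(traj, k = k, seed = seed, nInit = nInit)
  centDiffs <- transitionDiffs(cr@centroids)
  clusterPattern <- rep(NA_character_, cr@k)
  for (c_ in seq_len(cr@k)) {
    if (!any(cr@assignment == c_)) next
    for (p in patterns) {
      if (matchesPattern(centDiffs[c_, ], p)) {
        clusterPattern[c_] <- p@code
        break
      }
    }
  }
  names(clusterPattern) <- as.character(seq_len(cr@k))
  genePattern <- setNames(clusterPattern[cr@assignment],
                          names(cr@assignment))
  new("PatternAssignment",
      genePattern = genePattern,
      clusterPattern = clusterPattern,
      clusterAssignment = cr@assignment,
      nClassified = sum(!is.na(genePattern)),
      families = .patternFamilies(patterns),
      method = "clusters")
}

#' Classify genes directly against the pattern grammar
#'
#' Gene-level mode bypassing k-means, for sensitivity analysis: each
#' gene's own consecutive stage differences are tested against the codes.
#' Deterministic; agrees exactly with [classifyClusters()] on noiseless
#' input when k is at least the number of planted codes.
#'
#' @inheritParams classifyClusters
#' @return a \linkS4class{PatternAssignment} with empty cluster slots.
#' @export
classifyGenesDirectly <- function(delta, patterns = NULL,
                                  population = "HES5+") {
  stopifnot(is(delta, "DeltaExpression"))
  if (is.null(patterns)) patterns <- defaultPatternSet(stageDesign(delta))
  traj <- stageTrajectories(delta, population)
  diffs <- transitionDiffs(traj)
  genePattern <- apply(diffs, 1L, function(d) {
    for (p in patterns) if (matchesPattern(d, p)) return(p@code)
    NA_character_
  })
  new("PatternAssignment",
      genePattern = genePattern,
      clusterPattern = character(),
      clusterAssignment = integer(),
      nClassified = sum(!is.na(genePattern)),
      families = .patternFamilies(patterns),
      method = "genes")
}

.patternFamilies <- function(patterns) {
  setNames(vapply(patterns, function(p) p@label, character(1)),
           vapply(patterns, function(p) p@code, character(1)))
}

#' @describeIn classifyClusters gene -> code (NA if unclassified).
#' @param x a \linkS4class{PatternAssignment}.
#' @export
setMethod("genePatterns", "PatternAssignment", function(x) x@genePattern)

#' @export
setMethod("show", "PatternAssignment", function(object) {
  cat("PatternAssignment (", object@method, " mode): ",
      object@nClassified, " of ", length(object@genePattern),
      " genes classified\n", sep = "")
  tab <- table(object@genePattern, useNA = "no")
  if (length(tab)) {
    cat("  codes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
    if (length(object@clusterPattern))
      cat("  matched clusters:", sum(!is.na(object@clusterPattern)),
          "of", length(object@clusterPattern), "\n")
  }
})

#' Export a pattern assignment as a data.frame
#'
#' @param assignment a \linkS4class{PatternAssignment}.
#' @return data.frame with columns gene, cluster (NA in direct mode),
#'   pattern, family.
#' @export
patternTable <- function(assignment) {
  stopifnot(is(assignment, "PatternAssignment"))
  g <- names(assignment@genePattern)
  cl <- if (length(assignment@clusterAssignment))
    unname(assignment@clusterAssignment[g]) else NA_integer_
  pat <- unname(assignment@genePattern)
  data.frame(gene = g, cluster = cl, pattern = pat,
             family = unname(assignment@families[pat]),
             stringsAsFactors = FALSE)
}
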