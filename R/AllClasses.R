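#' @import methods
#' @importFrom stats rnorm sd setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Stage design of a staged differentiation time course
#'
#' Describes the ordered differentiation stages and, per stage, the sorted
#' populations sampled there. The default design is the six-stage neural
#' progenitor course (ES, NE, E-RG, M-RG, L-RG, LNP) with an unsorted ES
#' sample and HES5+/HES5- FACS-sorted populations at every later stage.
#'
#' @slot stages ordered character vector of unique stage labels.
#' @slot populations named list, one character vector of population labels
#'   per stage.
#'
#' @export
setClass("StageDesign",
  slots = c(stages = "character", populations = "list"))

setValidity("StageDesign", function(object) {
  msg <- character()
  if (length(object@stages) < 1L)
    msg <- c(msg, "design needs at least one stage")
  if (anyDuplicated(object@stages))
    msg <- c(msg, "stage labels must be unique")
  if (!identical(sort(names(object@populations)), sort(object@stages)))
    msg <- c(msg, "populations must be a named list covering every stage")
  if (any(!vapply(object@populations, function(p)
    is.character(p) && length(p) >= 1L && !anyDuplicated(p), logical(1))))
    msg <- c(msg, "each stage needs at least one unique population label")
  if (length(msg)) msg else TRUE
})

#' Staged expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding log2 expression intensities
#' (assay \code{"log2"}) for genes (or probes, before collapse) in rows and
#' samples in columns, with \code{colData} columns \code{stage} and
#' \code{population} tying every sample to a \linkS4class{StageDesign}
#' stored in \code{metadata(x)$design}.
#'
#' @export
setClass("StageExpression", contains = "SummarizedExperiment")

setValidity("StageExpression", function(object) {
  msg <- character()
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  else {
    v <- SummarizedExperiment::assay(object, "log2")
    if (!is.numeric(v) || any(!is.finite(v)))
      msg <- c(msg, "log2 values must be finite numbers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "row (gene/probe) ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stage", "population") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'stage' and 'population'")
  des <- S4Vectors::metadata(object)$design
  if (is.null(des) || !is(des, "StageDesign")) {
    msg <- c(msg, "metadata(x)$design must hold a StageDesign")
  } else if (all(c("stage", "population") %in% colnames(cd))) {
    ok <- mapply(function(s, p) {
      s %in% des@stages && p %in% des@populations[[s]]
    }, as.character(cd$stage), as.character(cd$population))
    if (!all(ok))
      msg <- c(msg, paste0("samples with (stage, population) outside the design: ",
                           paste(colnames(object)[!ok], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Baseline-subtracted expression matrix
#'
#' A \linkS4class{StageExpression} whose values are log2 intensities minus
#' the same gene's value in the baseline-stage sample, so every baseline
#' column is identically zero.
#'
#' @slot baselineStage the stage whose sample was subtracted.
#' @export
setClass("DeltaExpression", contains = "StageExpression",
  slots = c(baselineStage = "character"))

setValidity("DeltaExpression", function(object) {
  cd <- SummarizedExperiment::colData(object)
  base <- which(as.character(cd$stage) == object@baselineStage)
  if (length(base) < 1L)
    return("no sample of the baseline stage present")
  v <- SummarizedExperiment::assay(object, "log2")[, base, drop = FALSE]
  zero <- apply(abs(v) <= 1e-8, 2L, all)
  if (!any(zero))
    return("the subtracted baseline-stage column must be zero")
  TRUE
})

#' Temporal pattern code
#'
#' A trit string over {U, F, D} (up / flat / down), with optional wildcard
#' \code{*}, describing a gene's behaviour at each consecutive stage
#' transition judged against an absolute log2 threshold \code{theta}:
#' U means the step is >= theta, D means <= -theta, F means |step| < theta.
#'
#' @slot code character string over the alphabet U, F, D, *.
#' @slot theta positive log2 threshold (default 1).
#' @slot label free-text label used for pattern families.
#' @export
setClass("PatternCode",
  slots = c(code = "character", theta = "numeric", label = "character"))

setValidity("PatternCode", function(object) {
  msg <- character()
  if (length(object@code) != 1L ||
      !grepl("^[UFD*]+$", object@code))
    msg <- c(msg, "code must be one string over the alphabet U, F, D, *")
  if (length(object@theta) != 1L || !is.finite(object@theta) ||
      object@theta <= 0)
    msg <- c(msg, "theta must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' K-means clustering result
#'
#' Partition of genes into k clusters of their feature vectors (Lloyd's
#' algorithm, Euclidean distance), keeping the feature matrix so that the
#' centroid/membership consistency invariant can be verified.
#'
#' @slot assignment named integer vector, gene -> cluster id in 1..k.
#' @slot centroids k x d matrix of cluster centres.
#' @slot features the clustered gene x d feature matrix.
#' @slot k,seed,nInit clustering parameters as used.
#' @slot inertia total within-cluster sum of squared distances.
#' @export
setClass("ClusterResult",
  slots = c(assignment = "integer", centroids = "matrix",
            features = "matrix", k = "integer", seed = "integer",
            nInit = "integer", inertia = "numeric"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  a <- object@assignment
  if (length(a) != nrow(object@features) ||
      is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignment must name every feature row exactly once")
  if (any(a < 1L | a > object@k))
    msg <- c(msg, "cluster ids must lie in 1..k")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "one centroid row per cluster required")
  for (c_ in unique(a)) {
    m <- colMeans(object@features[a == c_, , drop = FALSE])
    if (max(abs(m - object@centroids[c_, ])) > 1e-9) {
      msg <- c(msg, "centroids must equal the mean of their members (tol 1e-9)")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pattern assignment of clusters and genes
#'
#' Result of matching cluster centroids (or, in direct mode, individual
#' genes) against a list of \linkS4class{PatternCode}s. Genes inherit the
#' pattern of their cluster; clusters sharing a code form one expression
#' family.
#'
#' @slot genePattern named character, gene -> code string or NA.
#' @slot clusterPattern named character, cluster id -> code string or NA
#'   (empty in direct gene-level mode).
#' @slot clusterAssignment named integer, gene -> cluster id (empty in
#'   direct mode).
#' @slot nClassified number of genes with a matched pattern.
#' @slot families named character, code string -> family label.
#' @slot method \code{"clusters"} or \code{"genes"}.
#' @export
setClass("PatternAssignment",
  slots = c(genePattern = "character", clusterPattern = "character",
            clusterAssignment = "integer", nClassified = "integer",
            families = "character", method = "character"))

setValidity("PatternAssignment", function(object) {
  msg <- character()
  if (sum(!is.na(object@genePattern)) != object@nClassified)
    msg <- c(msg, "nClassified must equal the number of pattern-matched genes")
  if (length(object@clusterAssignment)) {
    inh <- object@clusterPattern[object@clusterAssignment]
    if (!identical(unname(inh), unname(object@genePattern)))
      msg <- c(msg, "each gene's pattern must equal its cluster's pattern")
  }
  if (length(msg)) msg else TRUE
})

#' Population fold-ratio matrix
#'
#' Per gene and post-baseline stage, the linear fold ratio between the two
#' sorted populations computed from baseline-subtracted log2 values:
#' fold = 2^(delta_plus - delta_minus) in direction \code{"plus"}
#' (HES5+/HES5-), its reciprocal in direction \code{"minus"}.
#'
#' @slot fold strictly positive gene x stage matrix.
#' @slot direction \code{"plus"} or \code{"minus"}.
#' @export
setClass("RatioMatrix",
  slots = c(fold = "matrix", direction = "character"))

setValidity("RatioMatrix", function(object) {
  msg <- character()
  if (!object@direction %in% c("plus", "minus"))
    msg <- c(msg, "direction must be 'plus' or 'minus'")
  if (any(!is.finite(object@fold)) || any(object@fold <= 0))
    msg <- c(msg, "folds must be finite and strictly positive")
  if (length(msg)) msg else TRUE
})

#' Stage-specific Notch selection
#'
#' Clusters (and their member genes) whose population fold profile exceeds
#' \code{hi} at exactly one stage while staying below \code{lo} at every
#' other stage, per direction (HES5+-enriched and HES5--enriched).
#'
#' @slot genes list with elements \code{plus}/\code{minus}, each a named
#'   list stage -> character vector of member genes.
#' @slot clusters list with elements \code{plus}/\code{minus}, each a named
#'   character vector mapping selected cluster id -> its hi stage.
#' @slot foldTable data.frame (direction, cluster, stage, fold) of per-
#'   cluster per-stage mean folds, both directions.
#' @slot params list with hi, lo, k, seed, averaging.
#' @slot clusterResult the shared \linkS4class{ClusterResult}.
#' @export
setClass("NotchSelection",
  slots = c(genes = "list", clusters = "list", foldTable = "data.frame",
            params = "list", clusterResult = "ClusterResult"))

setValidity("NotchSelection", function(object) {
  msg <- character()
  if (!all(c("plus", "minus") %in% names(object@genes)))
    msg <- c(msg, "genes must have 'plus' and 'minus' entries")
  for (dir in c("plus", "minus")) {
    g <- unlist(object@genes[[dir]], use.names = FALSE)
    if (anyDuplicated(g))
      msg <- c(msg, sprintf(
        "a gene may appear under at most one stage per direction (%s)", dir))
  }
  if (length(msg)) msg else TRUE
})

#' qPCR threshold-cycle table
#'
#' Long-format replicate Ct measurements per (gene, stage, population),
#' with a designated reference gene (default HPRT) measured in every
#' condition where a target gene is measured.
#'
#' @slot data data.frame with columns gene, stage, population, replicate, ct.
#' @slot referenceGene the reference gene symbol.
#' @export
setClass("CtTable",
  slots = c(data = "data.frame", referenceGene = "character"))

setValidity("CtTable", function(object) {
  msg <- character()
  need <- c("gene", "stage", "population", "replicate", "ct")
  if (!all(need %in% colnames(object@data)))
    return(paste("data needs columns", paste(need, collapse = ", ")))
  ct <- object@data$ct
  if (any(!is.finite(ct)) || any(ct <= 0))
    msg <- c(msg, "Ct values must be finite and positive")
  conds <- unique(object@data[, c("stage", "population")])
  refd <- object@data[object@data$gene == object@referenceGene, ]
  for (i in seq_len(nrow(conds))) {
    hit <- refd$stage == conds$stage[i] & refd$population == conds$population[i]
    if (!any(hit)) {
      msg <- c(msg, sprintf(
        "reference gene %s not measured at (%s, %s)", object@referenceGene,
        conds$stage[i], conds$population[i]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})
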