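#' Construct a staged expression matrix
#'
#' Wraps a log2 gene x sample matrix and its per-sample (stage, population)
#' annotation into a \linkS4class{StageExpression}
#' (a \linkS4class{SummarizedExperiment} with assay \code{"log2"}).
#'
#' @param values numeric matrix, genes (or probes) in rows, samples in
#'   columns; finite, with unique dimnames.
#' @param stage,population character vectors, one entry per column of
#'   `values`.
#' @param design a \linkS4class{StageDesign}; every (stage, population)
#'   pair must be part of it.
#' @return a \linkS4class{StageExpression}.
#' @examples
#' d <- StageDesign(c("ES", "NE"), list(ES = "unsorted", NE = "HES5+"))
#' m <- matrix(c(4, 6, 5, 7), 2, 2,
#'             dimnames = list(c("PAX6", "SOX2"), c("ES", "NE")))
#' StageExpression(m, stage = c("ES", "NE"),
#'                 population = c("unsorted", "HES5+"), design = d)
#' @export
StageExpression <- function(values, stage, population,
                            design = StageDesign()) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(stage = as.character(stage),
                                   population = as.character(population),
                                   row.names = colnames(values)))
  S4Vectors::metadata(se)$design <- design
  new("StageExpression", se)
}

#' @describeIn StageExpression the log2 value matrix.
#' @param x a StageExpression.
#' @export
setMethod("log2Values", "StageExpression", function(x)
  SummarizedExperiment::assay(x, "log2"))

#' @describeIn StageExpression per-sample stage labels (named by sample).
#' @export
setMethod("sampleStages", "StageExpression", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$stage), colnames(x)))

#' @describeIn StageExpression per-sample population labels (named by sample).
#' @export
setMethod("samplePopulations", "StageExpression", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$population),
           colnames(x)))

#' @describeIn StageExpression the design the samples are annotated against.
#' @export
setMethod("stageDesign", "StageExpression", function(x)
  S4Vectors::metadata(x)$design)

#' Locate the sample of a given stage (and optionally population)
#'
#' @param em a \linkS4class{StageExpression}.
#' @param stage a stage label.
#' @param population optional population label; if missing there must be
#'   exactly one sample at the stage.
#' @return the matching sample (column) name.
#' @export
sampleAt <- function(em, stage, population = NULL) {
  st <- sampleStages(em)
  hit <- st == stage
  if (!is.null(population))
    hit <- hit & samplePopulations(em) == population
  id <- colnames(em)[hit]
  if (length(id) == 0L)
    stop("no sample at stage ", stage,
         if (!is.null(population)) paste0(", population ", population))
  if (length(id) > 1L)
    stop("more than one sample matches stage ", stage,
         "; pass a population to disambiguate")
  id
}

#' Per-gene stage trajectories of one population
#'
#' Returns a gene x stage matrix following the design's stage order, taking
#' for each stage the sample of the requested population; a stage with a
#' single sample of any population (e.g. the unsorted ES baseline) is used
#' as-is.
#'
#' @param em a \linkS4class{StageExpression}.
#' @param population population label, default `"HES5+"`.
#' @return numeric matrix, genes x stages.
#' @export
stageTrajectories <- function(em, population = "HES5+") {
  des <- stageDesign(em)
  cols <- vapply(stageLabels(des), function(s) {
    pops <- stagePopulations(des, s)
    if (population %in% pops) sampleAt(em, s, population)
    else sampleAt(em, s)
  }, character(1))
  traj <- log2Values(em)[, cols, drop = FALSE]
  colnames(traj) <- stageLabels(des)
  traj
}

#' @export
setMethod("show", "StageExpression", function(object) {
  cat(class(object), "with", nrow(object), "genes x", ncol(object),
      "samples\n")
  des <- stageDesign(object)
  cat("  stages:", paste(stageLabels(des), collapse = " > "), "\n")
  cat("  samples:", paste(utils::head(colnames(object), 6), collapse = ", "),
      if (ncol(object) > 6) "...", "\n")
  if (is(object, "DeltaExpression"))
    cat("  baseline stage:", object@baselineStage, "\n")
})
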