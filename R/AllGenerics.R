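#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @export
setGeneric("stageDesign", function(x) standardGeneric("stageDesign"))

#' @export
setGeneric("log2Values", function(x) standardGeneric("log2Values"))

#' @export
setGeneric("sampleStages", function(x) standardGeneric("sampleStages"))

#' @export
setGeneric("samplePopulations", function(x) standardGeneric("samplePopulations"))

#' @export
setGeneric("foldValues", function(x) standardGeneric("foldValues"))

#' @export
setGeneric("selectedGenes", function(x, direction = "plus")
  standardGeneric("selectedGenes"))

#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @export
setGeneric("genePatterns", function(x) standardGeneric("genePatterns"))

#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))

#' @export
setGeneric("referenceGene", function(x) standardGeneric("referenceGene"))
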