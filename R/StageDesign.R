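#' Construct a stage design
#'
#' The default reproduces the six-stage neural progenitor course: an
#' unsorted embryonic stem cell (ES) sample followed by neuroepithelial
#' (NE), early/mid/late radial glial (E-RG, M-RG, L-RG) and long-term
#' neural progenitor (LNP) stages, each FACS-split into Notch-active
#' (HES5+) and Notch-inactive (HES5-) populations.
#'
#' @param stages ordered character vector of unique stage labels.
#' @param populations named list of population labels per stage; if `NULL`,
#'   the first stage gets `"unsorted"` and all others `c("HES5+", "HES5-")`.
#' @return a \linkS4class{StageDesign}.
#' @examples
#' d <- StageDesign()
#' stageLabels(d)
#' transitions(d)
#' @export
StageDesign <- function(stages = c("ES", "NE", "E-RG", "M-RG", "L-RG", "LNP"),
                        populations = NULL) {
  if (is.null(populations)) {
    populations <- c(list("unsorted"),
                     rep(list(c("HES5+", "HES5-")), length(stages) - 1L))
    names(populations) <- stages
  }
  new("StageDesign", stages = stages, populations = populations)
}

#' @describeIn StageDesign ordered stage labels.
#' @param x a StageDesign.
#' @export
setMethod("stageLabels", "StageDesign", function(x) x@stages)

#' @describeIn StageDesign consecutive stage transitions as a two-column
#'   data.frame (`from`, `to`) of length `length(stages) - 1`.
#' @export
setMethod("transitions", "StageDesign", function(x) {
  s <- x@stages
  data.frame(from = s[-length(s)], to = s[-1L])
})

#' Population labels per stage
#'
#' @param design a \linkS4class{StageDesign}.
#' @param stage a stage label.
#' @return character vector of population labels at that stage.
#' @export
stagePopulations <- function(design, stage) {
  stopifnot(is(design, "StageDesign"))
  if (!stage %in% design@stages)
    stop("unknown stage: ", stage)
  design@populations[[stage]]
}

#' All (stage, population) conditions of a design, stage-ordered
#'
#' @param design a \linkS4class{StageDesign}.
#' @return data.frame with columns `stage` and `population`.
#' @export
designConditions <- function(design) {
  stopifnot(is(design, "StageDesign"))
  do.call(rbind, lapply(design@stages, function(s)
    data.frame(stage = s, population = design@populations[[s]])))
}

#' @export
setMethod("show", "StageDesign", function(object) {
  cat("StageDesign with", length(object@stages), "stages:",
      paste(object@stages, collapse = " > "), "\n")
  for (s in object@stages)
    cat("  ", s, ": ", paste(object@populations[[s]], collapse = ", "),
        "\n", sep = "")
})
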