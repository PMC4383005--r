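#' Construct a temporal pattern code
#'
#' @param code string over U (up), F (flat), D (down) and the wildcard
#'   `*`, one character per consecutive stage transition.
#' @param theta absolute log2 threshold a step must reach to count as up
#'   or down, default 1.
#' @param label free-text family label; defaults to the code itself.
#' @return a \linkS4class{PatternCode}.
#' @examples
#' PatternCode("UFFFF")           # induced at NE, sustained
#' PatternCode("UDFFF")           # transient NE pulse
#' @export
PatternCode <- function(code, theta = 1, label = code) {
  new("PatternCode", code = code, theta = theta, label = label)
}

setMethod("show", "PatternCode", function(object) {
  cat("PatternCode", object@code, sprintf("(theta = %g", object@theta),
      if (!identical(object@label, object@code))
        paste0(", '", object@label, "'"), ")\n", sep = "")
})

#' Default temporal pattern grammar
#'
#' Builds the default set of predefined up/flat/down codes for a design:
#' every possible single upregulation onset between consecutive stages,
#' each as a sustained code (U at the onset transition, F elsewhere), plus
#' a transient variant (U then D at the next transition) for onsets that
#' leave at least two later transitions. For the default six-stage design
#' this yields exactly eight mutually exclusive codes: UFFFF, UDFFF,
#' FUFFF, FUDFF, FFUFF, FFUDF, FFFUF, FFFFU.
#'
#' The grammar is a plain list, so alternative sets — re-expression codes
#' such as UDUFF, or down-onset codes for genes high in ES — can be passed
#' to the classifiers instead.
#'
#' @param design a \linkS4class{StageDesign} with at least two stages.
#' @param theta log2 threshold shared by all codes, default 1.
#' @return list of \linkS4class{PatternCode}s.
#' @export
defaultPatternSet <- function(design = StageDesign(), theta = 1) {
  nT <- length(stageLabels(design)) - 1L
  if (nT < 1L) stop("design needs at least two stages")
  tr <- transitions(design)
  codes <- list()
  for (i in seq_len(nT)) {
    sustained <- rep("F", nT); sustained[i] <- "U"
    codes[[length(codes) + 1L]] <- PatternCode(
      paste(sustained, collapse = ""), theta = theta,
      label = sprintf("up at %s>%s, sustained", tr$from[i], tr$to[i]))
    if (i <= nT - 2L) {
      transient <- sustained; transient[i + 1L] <- "D"
      codes[[length(codes) + 1L]] <- PatternCode(
        paste(transient, collapse = ""), theta = theta,
        label = sprintf("up at %s>%s, transient", tr$from[i], tr$to[i]))
    }
  }
  codes
}

#' Consecutive stage-transition differences
#'
#' @param trajectory numeric vector of per-stage values in design order,
#'   or a matrix with stages in columns.
#' @return vector (or matrix) of consecutive differences, one per stage
#'   transition: `diffs[i] = value[i + 1] - value[i]`.
#' @examples
#' transitionDiffs(c(0, 2, 2, 2, 2, 2))   # c(2, 0, 0, 0, 0)
#' @export
transitionDiffs <- function(trajectory) {
  if (is.matrix(trajectory)) {
    if (ncol(trajectory) < 2L) stop("trajectory needs at least two stages")
    d <- trajectory[, -1L, drop = FALSE] -
      trajectory[, -ncol(trajectory), drop = FALSE]
    colnames(d) <- paste(colnames(trajectory)[-ncol(trajectory)],
                         colnames(trajectory)[-1L], sep = ">")
    d
  } else {
    if (length(trajectory) < 2L) stop("trajectory needs at least two stages")
    diff(trajectory)
  }
}

#' Test a difference vector against a pattern code
#'
#' Position-wise semantics at the code's threshold theta: `U` requires the
#' step to be `>= theta`, `D` requires `<= -theta`, `F` requires
#' `|step| < theta`, and `*` always matches. The up/down comparisons are
#' inclusive, so a change of exactly theta counts as differential.
#'
#' @param diffs numeric vector of consecutive stage differences.
#' @param code a \linkS4class{PatternCode} of the same length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' matchesPattern(c(2, 0, 0, 0, 0), PatternCode("UFFFF"))   # TRUE
#' matchesPattern(c(1, 0, 0, 0, 0), PatternCode("UFFFF"))   # TRUE, boundary
#' matchesPattern(c(2, 0, 0, 0, 0), PatternCode("UDFFF"))   # FALSE
#' @export
matchesPattern <- function(diffs, code) {
  stopifnot(is(code, "PatternCode"))
  sym <- strsplit(code@code, "")[[1L]]
  if (length(diffs) != length(sym))
    stop("diff vector length ", length(diffs),
         " does not match code length ", length(sym))
  th <- code@theta
  all(vapply(seq_along(sym), function(i) switch(sym[i],
    U = diffs[i] >= th,
    D = diffs[i] <= -th,
    F = abs(diffs[i]) < th,
    `*` = TRUE), logical(1)))
}

#' Subtract the baseline-stage value from every sample
#'
#' Normalizes each gene to its embryonic stem cell (baseline) level by
#' subtracting, per gene, the value of the baseline-stage sample from all
#' samples; the baseline column becomes identically zero. Because values
#' are log2, this expresses every sample as a log2 fold over the baseline.
#'
#' @param em a \linkS4class{StageExpression}.
#' @param baselineStage stage label to use as baseline, default the first
#'   stage of the design.
#' @param baselineSample optional sample id designating which sample to
#'   subtract when the baseline stage has more than one.
#' @return a \linkS4class{DeltaExpression}.
#' @export
subtractBaseline <- function(em, baselineStage = NULL,
                             baselineSample = NULL) {
  des <- stageDesign(em)
  if (is.null(baselineStage)) baselineStage <- stageLabels(des)[1L]
  if (is.null(baselineSample)) {
    baselineSample <- sampleAt(em, baselineStage)
  } else if (!baselineSample %in% colnames(em)) {
    stop("designated baseline sample not present: ", baselineSample)
  }
  v <- log2Values(em)
  v <- v - v[, baselineSample]
  se <- StageExpression(v, stage = sampleStages(em),
                        population = samplePopulations(em), design = des)
  new("DeltaExpression", se, baselineStage = baselineStage)
}
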