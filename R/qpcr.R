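#' Construct a qPCR threshold-cycle table
#'
#' @param data data.frame with columns `gene`, `stage`, `population`,
#'   `replicate`, `ct` (one row per replicate measurement; the study
#'   design uses technical triplicates).
#' @param referenceGene reference gene symbol, default `"HPRT"`; must be
#'   measured in every condition where a target gene is.
#' @return a \linkS4class{CtTable}.
#' @export
CtTable <- function(data, referenceGene = "HPRT") {
  new("CtTable", data = as.data.frame(data), referenceGene = referenceGene)
}

#' @describeIn CtTable the underlying long-format data.frame.
#' @param x a CtTable.
#' @export
setMethod("ctData", "CtTable", function(x) x@data)

#' @describeIn CtTable the reference gene symbol.
#' @export
setMethod("referenceGene", "CtTable", function(x) x@referenceGene)

#' @export
setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat("CtTable:", length(unique(d$gene)), "genes x",
      nrow(unique(d[, c("stage", "population")])), "conditions, reference",
      object@referenceGene, "\n")
})

#' Replicate-averaged delta-Ct against the reference gene
#'
#' dCT = mean(replicate Ct of the gene) - mean(replicate Ct of the
#' reference) in the same (stage, population) condition.
#'
#' @param ct a \linkS4class{CtTable}.
#' @param gene,stage,population the condition to evaluate.
#' @return the dCT value (one number).
#' @examples
#' d <- data.frame(gene = rep(c("PAX6", "HPRT"), each = 3),
#'                 stage = "NE", population = "HES5+", replicate = 1:3,
#'                 ct = c(25, 25, 25, 20, 20, 20))
#' meanDeltaCt(CtTable(d), "PAX6", "NE", "HES5+")   # 5
#' @export
meanDeltaCt <- function(ct, gene, stage, population) {
  stopifnot(is(ct, "CtTable"))
  d <- ct@data
  pick <- function(g) d$ct[d$gene == g & d$stage == stage &
                             d$population == population]
  target <- pick(gene)
  ref <- pick(ct@referenceGene)
  if (length(target) == 0L)
    stop("gene ", gene, " not measured at (", stage, ", ", population, ")")
  if (length(ref) == 0L)
    stop("reference ", ct@referenceGene, " not measured at (", stage, ", ",
         population, ")")
  mean(target) - mean(ref)
}

#' Linear fold from a delta-Ct value
#'
#' The 2^-dCT conversion of a target-minus-reference threshold-cycle
#' difference to a linear expression level relative to the reference.
#'
#' @param deltaCt numeric dCT value(s).
#' @return 2^(-deltaCt).
#' @examples
#' ctFoldChange(5)    # 0.03125
#' ctFoldChange(0)    # 1
#' @export
ctFoldChange <- function(deltaCt) {
  stopifnot(all(is.finite(deltaCt)))
  2^(-deltaCt)
}

#' Delta-delta-Ct convenience wrapper
#'
#' ddCT relative quantification against a calibrator condition:
#' 2^-(dCT(condition) - dCT(calibrator)). Provided for completeness; the
#' package's own pipeline uses plain 2^-dCT.
#'
#' @param ct a \linkS4class{CtTable}.
#' @param gene target gene.
#' @param stage,population the condition of interest.
#' @param calibratorStage,calibratorPopulation the calibrator condition.
#' @return linear fold of the condition over the calibrator.
#' @export
deltaDeltaCt <- function(ct, gene, stage, population,
                         calibratorStage, calibratorPopulation) {
  d1 <- meanDeltaCt(ct, gene, stage, population)
  d0 <- meanDeltaCt(ct, gene, calibratorStage, calibratorPopulation)
  2^(-(d1 - d0))
}

#' All-condition fold table from a Ct table
#'
#' Applies [meanDeltaCt()] and [ctFoldChange()] to every measured target
#' (gene, stage, population) condition.
#'
#' @param ct a \linkS4class{CtTable}.
#' @return data.frame with columns gene, stage, population, delta_ct, fold.
#' @export
ctFoldTable <- function(ct) {
  stopifnot(is(ct, "CtTable"))
  d <- ct@data[ct@data$gene != ct@referenceGene, ]
  conds <- unique(d[, c("gene", "stage", "population")])
  conds$delta_ct <- mapply(function(g, s, p) meanDeltaCt(ct, g, s, p),
                           conds$gene, conds$stage, conds$population)
  conds$fold <- ctFoldChange(conds$delta_ct)
  rownames(conds) <- NULL
  conds
}

#' Double normalization to relative transcript abundance
#'
#' The two-step normalization behind the marker pie charts: step 1
#' normalizes each gene to 1 across all (stage, population) conditions —
#' by default jointly over both populations — so values reflect the
#' gene's relative expression across stages; step 2 normalizes each
#' condition column to 1 across genes, so values reflect each gene's
#' relative abundance within a stage. "Normalized to 1" is read as
#' sum-to-1 because the output feeds pie-chart fractions; `mode = "max1"`
#' offers peak-to-1 instead (step 2 stays sum-to-1).
#'
#' @param values non-negative numeric matrix, genes x conditions, with
#'   column names `"<stage>:<population>"` (as produced by pivoting
#'   [ctFoldTable()], see [foldMatrix()]).
#' @param perPopulation if `TRUE`, step 1 normalizes within each
#'   population separately instead of jointly.
#' @param mode step-1 normalization: `"sum1"` (default) or `"max1"`.
#' @return matrix of the same shape; every column sums to 1.
#' @examples
#' m <- matrix(c(3, 1), 1, dimnames = list("g", c("NE:HES5+", "E-RG:HES5+")))
#' relativeAbundance(m)   # step 1: 0.75 / 0.25; step 2: both 1
#' @export
relativeAbundance <- function(values, perPopulation = FALSE,
                              mode = c("sum1", "max1")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (any(values < 0)) stop("values must be non-negative")
  pops <- sub("^.*:", "", colnames(values))
  groups <- if (perPopulation) split(seq_len(ncol(values)), pops)
  else list(all = seq_len(ncol(values)))
  for (idx in groups) {
    denom <- if (mode == "sum1") rowSums(values[, idx, drop = FALSE])
    else apply(values[, idx, drop = FALSE], 1L, max)
    if (any(denom == 0))
      stop("gene(s) all zero across conditions: ",
           paste(rownames(values)[denom == 0], collapse = ", "))
    values[, idx] <- values[, idx, drop = FALSE] / denom
  }
  colSum <- colSums(values)
  if (any(colSum == 0))
    stop("condition column(s) all zero: ",
         paste(colnames(values)[colSum == 0], collapse = ", "))
  sweep(values, 2L, colSum, "/")
}

#' Pivot a long fold table into a gene x condition matrix
#'
#' @param folds data.frame with columns gene, stage, population, fold
#'   (see [ctFoldTable()]).
#' @return numeric matrix with columns named `"<stage>:<population>"`.
#' @export
foldMatrix <- function(folds) {
  cond <- paste(folds$stage, folds$population, sep = ":")
  genes <- unique(folds$gene); conds <- unique(cond)
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(folds$gene, genes), match(cond, conds))] <- folds$fold
  if (anyNA(m)) stop("fold table is not complete over gene x condition")
  m
}

#' Collapse normalized marker values into marker groups
#'
#' Sums the normalized per-gene fractions of each marker group (e.g. deep
#' layer TBR1/RELN and CTIP2/FEZF2 vs upper layer CUX1/CUX2/SATB2) per
#' condition, optionally renormalizing the groups to sum to 1 per
#' condition for pie-chart display.
#'
#' @param normalized gene x condition matrix (see [relativeAbundance()]).
#' @param groups named list of character vectors of member genes.
#' @param renormalize divide each condition column by its group total so
#'   fractions sum to 1, default `TRUE`.
#' @return group x condition matrix.
#' @export
collapseMarkerGroups <- function(normalized, groups, renormalize = TRUE) {
  stopifnot(is.list(groups), length(groups) > 0L,
            all(lengths(groups) > 0L))
  missing <- setdiff(unlist(groups), rownames(normalized))
  if (length(missing))
    stop("group member(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  out <- t(vapply(groups, function(g)
    colSums(normalized[g, , drop = FALSE]), numeric(ncol(normalized))))
  if (renormalize) out <- sweep(out, 2L, colSums(out), "/")
  out
}

#' Marker-panel relative expression heatmap matrix
#'
#' Per-gene row normalization of a marker panel over the stage course of
#' one population, as displayed in germinal-zone marker heatmaps:
#' `"max1"` divides each row by its maximum so every gene peaks at
#' exactly 1 (a gene with low absolute expression can still show a
#' saturated peak — relative, not absolute, levels); `"zscore"` centers
#' and scales each row to mean 0, sd 1.
#'
#' @param em a \linkS4class{StageExpression}.
#' @param panel character vector of marker genes (kept in this order,
#'   e.g. VZ to SVZ, neurogenic to gliogenic), or a data.frame with
#'   columns `gene` and `zone`.
#' @param population population whose per-stage samples are used; a stage
#'   with a single sample (the unsorted baseline) is used as-is.
#' @param mode `"max1"` (default) or `"zscore"`.
#' @return genes x stages matrix in panel order.
#' @export
relativeHeatmap <- function(em, panel, population = "HES5+",
                            mode = c("max1", "zscore")) {
  mode <- match.arg(mode)
  if (is.data.frame(panel)) panel <- panel$gene
  if (anyDuplicated(panel)) stop("panel genes must be unique")
  missing <- setdiff(panel, rownames(em))
  if (length(missing))
    stop("panel gene(s) absent: ", paste(missing, collapse = ", "))
  traj <- stageTrajectories(em, population)[panel, , drop = FALSE]
  if (mode == "max1") {
    mx <- apply(traj, 1L, max)
    if (any(mx <= 0))
      stop("non-positive row maximum for: ",
           paste(panel[mx <= 0], collapse = ", "))
    traj / mx
  } else {
    sds <- apply(traj, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant row(s) cannot be z-scored: ",
           paste(panel[sds == 0], collapse = ", "))
    t(scale(t(traj)))[, , drop = FALSE]
  }
}
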