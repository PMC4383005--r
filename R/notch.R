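#' Per-stage population fold ratios
#'
#' For every gene and every post-baseline stage, the linear fold between
#' the two sorted populations: fold = 2^(delta_plus - delta_minus) with
#' direction `"plus"` (HES5+ over HES5-), the elementwise reciprocal with
#' direction `"minus"`. Both populations are referenced to the same
#' unsorted baseline sample, so the baseline cancels in the ratio.
#'
#' @param delta a \linkS4class{DeltaExpression} carrying both populations
#'   at every post-baseline stage.
#' @param direction `"plus"` (default) or `"minus"`.
#' @return a \linkS4class{RatioMatrix} (genes x post-baseline stages).
#' @export
stageFoldRatios <- function(delta, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  stopifnot(is(delta, "DeltaExpression"))
  des <- stageDesign(delta)
  stages <- setdiff(stageLabels(des), delta@baselineStage)
  v <- log2Values(delta)
  fold <- vapply(stages, function(s) {
    pops <- stagePopulations(des, s)
    if (!all(c("HES5+", "HES5-") %in% pops))
      stop("stage ", s, " lacks an HES5+/HES5- population pair")
    dp <- v[, sampleAt(delta, s, "HES5+")]
    dm <- v[, sampleAt(delta, s, "HES5-")]
    2^(dp - dm)
  }, numeric(nrow(v)))
  if (direction == "minus") fold <- 1 / fold
  dimnames(fold) <- list(rownames(v), stages)
  new("RatioMatrix", fold = fold, direction = direction)
}

#' @describeIn stageFoldRatios the fold matrix of a RatioMatrix.
#' @param x a RatioMatrix.
#' @export
setMethod("foldValues", "RatioMatrix", function(x) x@fold)

#' @export
setMethod("show", "RatioMatrix", function(object) {
  cat("RatioMatrix (direction ", object@direction, "): ",
      nrow(object@fold), " genes x ", ncol(object@fold), " stages (",
      paste(colnames(object@fold), collapse = ", "), ")\n", sep = "")
})

#' Average fold profile of a gene cluster
#'
#' @param genes character vector of cluster member genes.
#' @param ratios a \linkS4class{RatioMatrix}.
#' @param averaging `"mean_of_log"` (default; geometric mean of the linear
#'   folds, i.e. 2^mean(log2 fold) — symmetric under direction reversal)
#'   or `"mean_of_linear"` (arithmetic mean of the linear folds).
#' @return named numeric vector, mean fold per stage.
#' @export
clusterFoldProfile <- function(genes, ratios,
                               averaging = c("mean_of_log",
                                             "mean_of_linear")) {
  averaging <- match.arg(averaging)
  stopifnot(is(ratios, "RatioMatrix"))
  if (length(genes) == 0L) stop("empty cluster")
  missing <- setdiff(genes, rownames(ratios@fold))
  if (length(missing))
    stop("genes absent from ratio matrix: ", paste(missing, collapse = ", "))
  f <- ratios@fold[genes, , drop = FALSE]
  if (averaging == "mean_of_log") 2^colMeans(log2(f)) else colMeans(f)
}

#' Select clusters with a stage-specific fold profile
#'
#' The dual-threshold criterion: a cluster is selected iff its mean fold
#' exceeds `hi` at exactly one stage while staying strictly below `lo` at
#' every remaining stage; it is then assigned to its hi stage. Both
#' comparisons are strict ("exceeding 1.4", "< 1.2"), so a profile hitting
#' 1.4 exactly is rejected, as is one with 1.2 exactly at another stage.
#'
#' @param profiles numeric matrix, clusters x stages, of mean folds (rows
#'   named by cluster id), or a single named profile vector.
#' @param hi upper threshold the specific stage must exceed, default 1.4.
#' @param lo ceiling the remaining stages must stay below, default 1.2.
#' @return data.frame with columns `cluster` and `stage`, one row per
#'   selected cluster.
#' @examples
#' p <- rbind(a = c(NE = 1.6, `E-RG` = 1.1, `M-RG` = 1.0),
#'            b = c(NE = 1.5, `E-RG` = 1.3, `M-RG` = 1.0))
#' selectSpecificClusters(p)   # only 'a', at stage NE
#' @export
selectSpecificClusters <- function(profiles, hi = 1.4, lo = 1.2) {
  stopifnot(hi > lo, lo > 1)
  if (!is.matrix(profiles)) profiles <- t(as.matrix(profiles))
  if (ncol(profiles) < 2L) stop("profiles need at least two stages")
  out <- lapply(rownames(profiles), function(cl) {
    p <- profiles[cl, ]
    hiIdx <- which(p > hi)
    if (length(hiIdx) == 1L && all(p[-hiIdx] < lo))
      data.frame(cluster = cl, stage = colnames(profiles)[hiIdx])
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(cluster = character(), stage = character())
  else out
}

#' Stage-specific Notch-active gene selection pipeline
#'
#' The full selection procedure: (1) k-means over the gene x all-sample
#' feature matrix of baseline-subtracted log2 values — one shared cluster
#' set serves both directions; (2) per-stage HES5+/HES5- fold ratios in
#' both directions; (3) per-cluster average fold profiles; (4) the
#' `hi`/`lo` dual-threshold selection in both directions. Genes of a
#' selected cluster are reported under the cluster's hi stage, so a gene
#' appears under at most one stage per direction.
#'
#' @param em a \linkS4class{StageExpression} with the unsorted baseline
#'   plus both populations at every later stage.
#' @param k number of clusters, default 100.
#' @param seed,nInit passed to [kmeansCluster()].
#' @param hi,lo selection thresholds, defaults 1.4 and 1.2.
#' @param averaging see [clusterFoldProfile()].
#' @param baselineStage baseline stage label, default the design's first.
#' @return a \linkS4class{NotchSelection}.
#' @export
runNotchPipeline <- function(em, k = 100L, seed = 0L, nInit = 10L,
                             hi = 1.4, lo = 1.2,
                             averaging = "mean_of_log",
                             baselineStage = NULL) {
  stopifnot(is(em, "StageExpression"))
  delta <- subtractBaseline(em, baselineStage)
  cr <- kmeansCluster(log2Values(delta), k = k, seed = seed, nInit = nInit)
  members <- split(names(cr@assignment), cr@assignment)
  ratios <- list(plus = stageFoldRatios(delta, "plus"),
                 minus = stageFoldRatios(delta, "minus"))
  genes <- list(); clusters <- list(); foldRows <- list()
  for (dir in c("plus", "minus")) {
    profiles <- t(vapply(members, clusterFoldProfile,
                         numeric(ncol(ratios[[dir]]@fold)),
                         ratios = ratios[[dir]], averaging = averaging))
    sel <- selectSpecificClusters(profiles, hi = hi, lo = lo)
    clusters[[dir]] <- setNames(sel$stage, sel$cluster)
    byStage <- lapply(colnames(profiles), function(s)
      sort(unlist(members[sel$cluster[sel$stage == s]], use.names = FALSE)))
    names(byStage) <- colnames(profiles)
    genes[[dir]] <- byStage[vapply(byStage, length, integer(1)) > 0L]
    foldRows[[dir]] <- data.frame(
      direction = dir,
      cluster = rep(rownames(profiles), ncol(profiles)),
      stage = rep(colnames(profiles), each = nrow(profiles)),
      fold = as.vector(profiles))
  }
  new("NotchSelection",
      genes = genes, clusters = clusters,
      foldTable = do.call(rbind, foldRows),
      params = list(hi = hi, lo = lo, k = as.integer(k),
                    seed = as.integer(seed), averaging = averaging),
      clusterResult = cr)
}

#' @describeIn runNotchPipeline selected genes of one direction as a named
#'   list stage -> gene vector.
#' @param x a NotchSelection.
#' @param direction `"plus"` or `"minus"`.
#' @export
setMethod("selectedGenes", "NotchSelection", function(x, direction = "plus") {
  x@genes[[match.arg(direction, c("plus", "minus"))]]
})

#' @export
setMethod("show", "NotchSelection", function(object) {
  cat("NotchSelection (hi >", object@params$hi, ", lo <", object@params$lo,
      ", k =", object@params$k, ")\n")
  for (dir in c("plus", "minus")) {
    g <- object@genes[[dir]]
    cat("  ", if (dir == "plus") "HES5+ enriched" else "HES5- enriched",
        ": ", sum(lengths(g)), " genes in ",
        length(object@clusters[[dir]]), " clusters",
        if (length(g)) paste0(" (",
          paste(sprintf("%s: %d", names(g), lengths(g)), collapse = ", "),
          ")"), "\n", sep = "")
  }
})
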