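#' Simulate a staged two-population expression matrix with planted truth
#'
#' Emulates the structure the analysis assumes: six ordered stages (by
#' default), an unsorted baseline sample, HES5+/HES5- samples at every
#' later stage, one replicate per condition, log2-scale intensities with
#' i.i.d. Gaussian noise. Three gene classes are planted on top of a
#' Gaussian baseline level:
#' \itemize{
#'   \item background genes — baseline plus noise only;
#'   \item pattern genes — the HES5+ trajectory steps by +/- `amplitude`
#'     at the transitions a \linkS4class{PatternCode} dictates, the HES5-
#'     trajectory mirroring it so pattern and Notch planting compose;
#'   \item Notch genes — an additional log2 `offset` on one population at
#'     exactly one stage, i.e. a stage-specific population fold of
#'     2^offset.
#' }
#' Planted genes get a baseline of at least `minPlantedBaseline` so that,
#' without noise, the variation filter retains them by construction.
#'
#' @param design a \linkS4class{StageDesign}.
#' @param nBackground number of background genes, default 400.
#' @param plantedPatterns `NULL` or data.frame with columns `code`, `n`,
#'   `amplitude` (log2 step size per coded transition).
#' @param plantedNotch `NULL` or data.frame with columns `stage`, `n`,
#'   `direction` (`"plus"`/`"minus"`), `offset` (log2).
#' @param noiseSd i.i.d. Gaussian noise sd on the log2 scale, default 0.1.
#' @param baselineMean,baselineSd baseline log2 level distribution,
#'   defaults 6 and 1.5.
#' @param minPlantedBaseline floor on planted genes' baseline, default 3.
#' @param seed integer seed; the run is fully reproducible.
#' @return list with `expression` (a \linkS4class{StageExpression}) and
#'   `truth` (data.frame gene, pattern, notch_stage, notch_direction).
#' @examples
#' sim <- simulateExpression(nBackground = 10,
#'   plantedPatterns = data.frame(code = "UFFFF", n = 2, amplitude = 2),
#'   noiseSd = 0, seed = 1)
#' subset(sim$truth, !is.na(pattern))
#' @export
simulateExpression <- function(design = StageDesign(), nBackground = 400L,
                               plantedPatterns = NULL, plantedNotch = NULL,
                               noiseSd = 0.1, baselineMean = 6,
                               baselineSd = 1.5, minPlantedBaseline = 3,
                               seed = 1L) {
  stopifnot(nBackground >= 0L, noiseSd >= 0, baselineSd >= 0)
  set.seed(as.integer(seed))
  stages <- stageLabels(design)
  conds <- designConditions(design)
  sampleIds <- paste(conds$stage, conds$population, sep = ":")

  nPat <- if (is.null(plantedPatterns)) 0L else sum(plantedPatterns$n)
  nNotch <- if (is.null(plantedNotch)) 0L else sum(plantedNotch$n)
  nGenes <- nBackground + nPat + nNotch
  if (nGenes == 0L) stop("no genes to simulate")
  genes <- sprintf("gene%04d", seq_len(nGenes))
  truth <- data.frame(gene = genes, pattern = NA_character_,
                      notch_stage = NA_character_,
                      notch_direction = NA_character_,
                      stringsAsFactors = FALSE)

  baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
  values <- matrix(rep(baseline, length(sampleIds)), nGenes,
                   length(sampleIds), dimnames = list(genes, sampleIds))
  g <- 0L

  if (nPat > 0L) {
    stopifnot(all(c("code", "n", "amplitude") %in% colnames(plantedPatterns)),
              all(plantedPatterns$amplitude > 0))
    for (r in seq_len(nrow(plantedPatterns))) {
      code <- strsplit(as.character(plantedPatterns$code[r]), "")[[1L]]
      if (length(code) != length(stages) - 1L)
        stop("pattern code length must match the number of transitions")
      if (any(!code %in% c("U", "F", "D")))
        stop("planted codes must be concrete (U/F/D only)")
      step <- c(0, cumsum((code == "U") * plantedPatterns$amplitude[r] -
                          (code == "D") * plantedPatterns$amplitude[r]))
      names(step) <- stages
      for (i in seq_len(plantedPatterns$n[r])) {
        g <- g + 1L
        baseline[g] <- max(baseline[g], minPlantedBaseline)
        values[g, ] <- baseline[g] + step[conds$stage]
        truth$pattern[g] <- plantedPatterns$code[r]
      }
    }
  }
  if (nNotch > 0L) {
    stopifnot(all(c("stage", "n", "direction", "offset") %in%
                    colnames(plantedNotch)))
    for (r in seq_len(nrow(plantedNotch))) {
      st <- as.character(plantedNotch$stage[r])
      dir <- match.arg(as.character(plantedNotch$direction[r]),
                       c("plus", "minus"))
      pop <- if (dir == "plus") "HES5+" else "HES5-"
      if (!pop %in% stagePopulations(design, st))
        stop("population ", pop, " not sampled at stage ", st)
      col <- which(conds$stage == st & conds$population == pop)
      for (i in seq_len(plantedNotch$n[r])) {
        g <- g + 1L
        baseline[g] <- max(baseline[g], minPlantedBaseline)
        values[g, ] <- baseline[g]
        values[g, col] <- values[g, col] + plantedNotch$offset[r]
        truth$notch_stage[g] <- st
        truth$notch_direction[g] <- dir
      }
    }
  }
  if (noiseSd > 0)
    values <- values + matrix(stats::rnorm(length(values), 0, noiseSd),
                              nrow(values))
  em <- StageExpression(values, stage = conds$stage,
                        population = conds$population, design = design)
  list(expression = em, truth = truth)
}

#' Expand a gene-level matrix into a probe-level table with a map
#'
#' Each gene becomes one "faithful" probe carrying the gene's exact row
#' plus optionally further jittered probes whose mean is strictly lower,
#' so collapsing with `max_mean_probe` inverts the expansion exactly.
#'
#' @param em a gene-level \linkS4class{StageExpression}.
#' @param probesPerGene integer vector of possible probe counts per gene,
#'   sampled uniformly; default `1:3`.
#' @param jitterSd per-cell jitter sd of the extra probes, default 0.2.
#' @param meanDropRange range of the mean deficit of the extra probes
#'   relative to the faithful probe, default `c(0.2, 1)` log2 units.
#' @param seed integer seed.
#' @return list with `probes` (probe-level \linkS4class{StageExpression})
#'   and `map` (named character probe -> gene).
#' @export
simulateProbeTable <- function(em, probesPerGene = 1:3, jitterSd = 0.2,
                               meanDropRange = c(0.2, 1), seed = 1L) {
  stopifnot(is(em, "StageExpression"), all(probesPerGene >= 1L))
  set.seed(as.integer(seed))
  v <- log2Values(em)
  rows <- list(); map <- character()
  for (gi in seq_len(nrow(v))) {
    gene <- rownames(v)[gi]
    n <- if (length(probesPerGene) == 1L) probesPerGene
    else sample(probesPerGene, 1L)
    probes <- matrix(NA_real_, n, ncol(v))
    probes[1L, ] <- v[gi, ]
    if (n > 1L) for (p in 2:n) {
      jit <- v[gi, ] + stats::rnorm(ncol(v), 0, jitterSd)
      drop <- stats::runif(1L, meanDropRange[1L], meanDropRange[2L])
      probes[p, ] <- jit - (mean(jit) - mean(v[gi, ])) - drop
    }
    rownames(probes) <- sprintf("%s_p%d", gene, seq_len(n))
    rows[[gi]] <- probes
    map <- c(map, setNames(rep(gene, n), rownames(probes)))
  }
  pv <- do.call(rbind, rows)
  colnames(pv) <- colnames(v)
  probesEm <- StageExpression(pv, stage = sampleStages(em),
                              population = samplePopulations(em),
                              design = stageDesign(em))
  list(probes = probesEm, map = map)
}

#' Simulate a replicate qPCR Ct table with planted folds
#'
#' The reference gene gets a constant Ct; each target's Ct is the
#' reference Ct minus log2 of the planted fold (so the 2^-dCT pipeline
#' recovers the fold exactly when noise is zero), plus Gaussian replicate
#' noise.
#'
#' @param folds data.frame with columns gene, stage, population, fold
#'   (planted linear fold relative to the reference).
#' @param referenceGene reference symbol, default `"HPRT"`.
#' @param referenceCt the reference gene's Ct level, default 20.
#' @param replicates replicates per condition, default 3.
#' @param noiseSd replicate Ct noise sd, default 0.
#' @param seed integer seed.
#' @return a \linkS4class{CtTable}.
#' @export
simulateCt <- function(folds, referenceGene = "HPRT", referenceCt = 20,
                       replicates = 3L, noiseSd = 0, seed = 1L) {
  stopifnot(all(c("gene", "stage", "population", "fold") %in%
                  colnames(folds)), all(folds$fold > 0), replicates >= 1L)
  set.seed(as.integer(seed))
  conds <- unique(folds[, c("stage", "population")])
  refRows <- data.frame(gene = referenceGene,
                        stage = rep(conds$stage, each = replicates),
                        population = rep(conds$population, each = replicates),
                        replicate = rep(seq_len(replicates), nrow(conds)),
                        ct = referenceCt)
  tgtRows <- do.call(rbind, lapply(seq_len(nrow(folds)), function(r)
    data.frame(gene = folds$gene[r], stage = folds$stage[r],
               population = folds$population[r],
               replicate = seq_len(replicates),
               ct = referenceCt - log2(folds$fold[r]) +
                 stats::rnorm(replicates, 0, noiseSd))))
  CtTable(rbind(refRows, tgtRows), referenceGene = referenceGene)
}
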