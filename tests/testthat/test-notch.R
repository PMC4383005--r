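notchSim <- function(seed = 0, direction = "plus") {
  simulateExpression(
    nBackground = 200,
    plantedNotch = data.frame(stage = "NE", n = 20, direction = direction,
                              offset = 1),
    noiseSd = 0.1, seed = seed)
}

test_that("fold ratios follow 2^(delta+ - delta-) with reciprocity", {
  sim <- simulateExpression(
    nBackground = 5,
    plantedNotch = data.frame(stage = "NE", n = 1, direction = "plus",
                              offset = 1),
    noiseSd = 0, seed = 1)
  delta <- subtractBaseline(sim$expression)
  plus <- stageFoldRatios(delta, "plus")
  minus <- stageFoldRatios(delta, "minus")
  planted <- sim$truth$gene[!is.na(sim$truth$notch_stage)]
  # offset 1 log2 at NE only => fold exactly 2 there, 1 elsewhere
  expect_equal(unname(foldValues(plus)[planted, "NE"]), 2)
  expect_equal(unname(foldValues(plus)[planted, "M-RG"]), 1)
  expect_equal(foldValues(minus), 1 / foldValues(plus))
})

test_that("identical populations give unit folds and empty selection", {
  v <- matrix(5, 4, 11)
  conds <- designConditions(fullDesign)
  dimnames(v) <- list(paste0("g", 1:4),
                      paste(conds$stage, conds$population, sep = ":"))
  em <- exprFromMatrix(v)
  ns <- runNotchPipeline(em, k = 2, seed = 0)
  expect_equal(unique(ns@foldTable$fold), 1)
  expect_length(selectedGenes(ns, "plus"), 0L)
  expect_length(selectedGenes(ns, "minus"), 0L)
})

test_that("cluster fold profiles average as geometric or arithmetic mean", {
  fold <- matrix(c(2, 0.5, 4, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("NE", "E-RG")))
  ratios <- new("RatioMatrix", fold = fold, direction = "plus")
  expect_equal(unname(clusterFoldProfile("a", ratios)), c(2, 4))
  expect_equal(unname(clusterFoldProfile(c("a", "b"), ratios)),
               c(1, 2))          # geometric mean
  expect_equal(unname(clusterFoldProfile(c("a", "b"), ratios,
                                         "mean_of_linear")),
               c(1.25, 2.5))     # arithmetic mean
  expect_error(clusterFoldProfile(character(), ratios), "empty cluster")
})

test_that("dual-threshold selection uses strict inequalities", {
  p <- rbind(
    ok = c(NE = 1.6, `E-RG` = 1.1, `M-RG` = 1.0, `L-RG` = 1.05, LNP = 1.1),
    secondHigh = c(NE = 1.5, `E-RG` = 1.3, `M-RG` = 1.0, `L-RG` = 1.0,
                   LNP = 1.0),
    boundaryHi = c(NE = 1.4, `E-RG` = 1.0, `M-RG` = 1.0, `L-RG` = 1.0,
                   LNP = 1.0),
    boundaryLo = c(NE = 1.6, `E-RG` = 1.2, `M-RG` = 1.0, `L-RG` = 1.0,
                   LNP = 1.0))
  sel <- selectSpecificClusters(p)
  expect_equal(sel$cluster, "ok")
  expect_equal(sel$stage, "NE")
})

test_that("planted stage-specific genes are recovered at the NE stage", {
  sim <- notchSim()
  ns <- runNotchPipeline(sim$expression, k = 50, seed = 0)
  found <- selectedGenes(ns, "plus")
  planted <- sim$truth$gene[!is.na(sim$truth$notch_stage)]
  foundGenes <- unlist(found, use.names = FALSE)
  expect_gte(mean(foundGenes %in% planted), 0.9)   # precision
  expect_gte(mean(planted %in% foundGenes), 0.9)   # recall
  expect_equal(names(found), "NE")

  # every selected cluster re-passes the hi/lo predicate independently
  delta <- subtractBaseline(sim$expression)
  ratios <- stageFoldRatios(delta, "plus")
  members <- split(names(clusterAssignment(ns@clusterResult)),
                   clusterAssignment(ns@clusterResult))
  for (cl in names(ns@clusters$plus)) {
    prof <- clusterFoldProfile(members[[cl]], ratios)
    hiIdx <- which(prof > 1.4)
    expect_length(hiIdx, 1L)
    expect_true(all(prof[-hiIdx] < 1.2))
    expect_equal(names(prof)[hiIdx], unname(ns@clusters$plus[[cl]]))
  }
})

test_that("swapping population labels swaps the selection directions", {
  sim <- notchSim()
  em <- sim$expression
  pops <- samplePopulations(em)
  swapped <- ifelse(pops == "HES5+", "HES5-",
                    ifelse(pops == "HES5-", "HES5+", pops))
  emSwap <- StageExpression(log2Values(em), stage = sampleStages(em),
                            population = swapped,
                            design = stageDesign(em))
  a <- runNotchPipeline(em, k = 50, seed = 0)
  b <- runNotchPipeline(emSwap, k = 50, seed = 0)
  expect_identical(a@genes$plus, b@genes$minus)
  expect_identical(a@genes$minus, b@genes$plus)
})
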