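test_that("noiseless planted patterns step exactly as coded", {
  sim <- simulateExpression(
    nBackground = 3,
    plantedPatterns = data.frame(code = "UFFFF", n = 1, amplitude = 2),
    noiseSd = 0, seed = 5)
  g <- sim$truth$gene[!is.na(sim$truth$pattern)]
  traj <- stageTrajectories(sim$expression)[g, ]
  expect_equal(unname(transitionDiffs(traj)), c(2, 0, 0, 0, 0))
  # the HES5- trajectory mirrors the HES5+ one
  trajM <- stageTrajectories(sim$expression, "HES5-")[g, ]
  expect_equal(traj, trajM)
})

test_that("noiseless notch planting gives the exact stage-specific fold", {
  sim <- simulateExpression(
    nBackground = 2,
    plantedNotch = data.frame(stage = "NE", n = 1, direction = "plus",
                              offset = 1),
    noiseSd = 0, seed = 5)
  g <- sim$truth$gene[!is.na(sim$truth$notch_stage)]
  fold <- foldValues(stageFoldRatios(subtractBaseline(sim$expression)))
  expect_equal(unname(fold[g, ]), c(2, 1, 1, 1, 1))
})

test_that("simulation is reproducible and validates its inputs", {
  args <- list(nBackground = 20, noiseSd = 0.2, seed = 42)
  a <- do.call(simulateExpression, args)
  b <- do.call(simulateExpression, args)
  expect_identical(log2Values(a$expression), log2Values(b$expression))
  expect_identical(a$truth, b$truth)
  expect_error(simulateExpression(
    nBackground = 0,
    plantedPatterns = data.frame(code = "UF", n = 1, amplitude = 1)),
    "transitions")
  expect_error(simulateExpression(
    nBackground = 0,
    plantedPatterns = data.frame(code = "U*FFF", n = 1, amplitude = 1)),
    "concrete")
})

test_that("the variation filter retains every noiseless planted gene", {
  sim <- simulateExpression(
    nBackground = 50,
    plantedPatterns = data.frame(code = c("UFFFF", "FFFFU"), n = 10,
                                 amplitude = 1),
    plantedNotch = data.frame(stage = "M-RG", n = 10, direction = "minus",
                              offset = 1),
    noiseSd = 0, seed = 3)
  kept <- rownames(variationFilter(sim$expression)$expression)
  planted <- sim$truth$gene[!is.na(sim$truth$pattern) |
                              !is.na(sim$truth$notch_stage)]
  expect_true(all(planted %in% kept))
})

test_that("probe expansion is inverted exactly by max-mean collapse", {
  sim <- simulateExpression(nBackground = 15, noiseSd = 0.1, seed = 9)
  pt <- simulateProbeTable(sim$expression, probesPerGene = 1:3, seed = 9)
  expect_equal(nrow(pt$probes), length(pt$map))
  back <- collapseProbes(pt$probes, pt$map)
  expect_equal(log2Values(back)[rownames(sim$expression), ],
               log2Values(sim$expression))

  # single probe per gene: expansion is the identity modulo probe names
  pt1 <- simulateProbeTable(sim$expression, probesPerGene = 1, seed = 9)
  expect_equal(unname(log2Values(pt1$probes)),
               unname(log2Values(sim$expression)))
})

test_that("simulated Ct tables encode the planted folds", {
  folds <- data.frame(gene = c("TBR1", "CUX1"), stage = "NE",
                      population = "HES5+", fold = c(1, 32))
  ct <- simulateCt(folds, noiseSd = 0, seed = 1)
  expect_equal(meanDeltaCt(ct, "TBR1", "NE", "HES5+"), 0)
  expect_equal(meanDeltaCt(ct, "CUX1", "NE", "HES5+"), -5)
  expect_equal(ctFoldChange(meanDeltaCt(ct, "CUX1", "NE", "HES5+")), 32)
  a <- simulateCt(folds, noiseSd = 0.3, seed = 2)
  b <- simulateCt(folds, noiseSd = 0.3, seed = 2)
  expect_identical(ctData(a), ctData(b))
  expect_equal(nrow(ctData(a)), 3L * 3L)  # reference + 2 targets, triplicate
})
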