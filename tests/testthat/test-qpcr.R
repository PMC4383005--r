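makeCt <- function() {
  CtTable(data.frame(
    gene = rep(c("PAX6", "HPRT"), each = 3),
    stage = "NE", population = "HES5+", replicate = 1:3,
    ct = c(24, 25, 26, 20, 20, 20)))
}

test_that("delta-Ct is the replicate-mean difference to the reference", {
  ct <- makeCt()
  expect_equal(meanDeltaCt(ct, "PAX6", "NE", "HES5+"), 5)
  expect_equal(meanDeltaCt(ct, "HPRT", "NE", "HES5+"), 0)
  expect_error(meanDeltaCt(ct, "SOX2", "NE", "HES5+"), "not measured")
  expect_error(meanDeltaCt(ct, "PAX6", "LNP", "HES5+"), "not measured")
})

test_that("Ct tables demand the reference wherever targets sit", {
  bad <- data.frame(gene = "PAX6", stage = "NE", population = "HES5+",
                    replicate = 1, ct = 25)
  expect_error(CtTable(bad), "reference gene HPRT not measured")
  expect_error(CtTable(rbind(bad, data.frame(gene = "HPRT", stage = "NE",
                                             population = "HES5+",
                                             replicate = 1, ct = -1))),
               "finite and positive")
})

test_that("2^-dCT conversion and the reference identity hold", {
  expect_equal(ctFoldChange(5), 0.03125)
  expect_equal(ctFoldChange(0), 1)
  expect_equal(ctFoldChange(-1), 2)
  ct <- makeCt()
  expect_equal(ctFoldChange(meanDeltaCt(ct, "HPRT", "NE", "HES5+")), 1)
  tab <- ctFoldTable(ct)
  expect_equal(tab$fold, 2^-5)
})

test_that("delta-delta-Ct calibrates against a chosen condition", {
  d <- rbind(
    data.frame(gene = rep(c("PAX6", "HPRT"), each = 3), stage = "NE",
               population = "HES5+", replicate = 1:3,
               ct = c(25, 25, 25, 20, 20, 20)),
    data.frame(gene = rep(c("PAX6", "HPRT"), each = 3), stage = "E-RG",
               population = "HES5+", replicate = 1:3,
               ct = c(23, 23, 23, 20, 20, 20)))
  ct <- CtTable(d)
  expect_equal(deltaDeltaCt(ct, "PAX6", "E-RG", "HES5+", "NE", "HES5+"), 4)
})

test_that("double normalization produces stage columns summing to one", {
  m <- matrix(c(3, 1), 1, dimnames = list("g", c("NE:HES5+", "E-RG:HES5+")))
  step <- relativeAbundance(m)
  expect_equal(unname(step), matrix(c(1, 1), 1))  # single gene: columns sum to 1

  m2 <- matrix(2, 2, 2, dimnames = list(c("a", "b"),
                                        c("NE:HES5+", "NE:HES5-")))
  expect_equal(unname(relativeAbundance(m2)), matrix(0.5, 2, 2))

  set.seed(8)
  m3 <- matrix(runif(24, 0.1, 5), 4, 6,
               dimnames = list(paste0("g", 1:4),
                               paste0(rep(c("NE", "E-RG", "M-RG"), 2), ":",
                                      rep(c("HES5+", "HES5-"), each = 3))))
  out <- relativeAbundance(m3)
  expect_equal(unname(colSums(out)), rep(1, 6), tolerance = 1e-12)
  # scale invariance per gene
  m4 <- m3; m4["g2", ] <- m3["g2", ] * 7.3
  expect_equal(relativeAbundance(m4), out, tolerance = 1e-12)
  # per-population mode still yields unit columns
  outP <- relativeAbundance(m3, perPopulation = TRUE)
  expect_equal(unname(colSums(outP)), rep(1, 6), tolerance = 1e-12)

  expect_error(relativeAbundance(rbind(m3, zero = 0)), "all zero")
})

test_that("marker groups collapse by summation and renormalize", {
  norm <- matrix(c(0.2, 0.3, 0.5), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("NE:HES5+", "NE:HES5-")))
  out <- collapseMarkerGroups(norm, list(A = c("g1", "g2"), B = "g3"),
                              renormalize = FALSE)
  expect_equal(unname(out[, 1]), c(0.5, 0.5))
  outR <- collapseMarkerGroups(norm, list(A = c("g1", "g2"), B = "g3"))
  expect_equal(unname(colSums(outR)), c(1, 1))
  # singleton groups are the identity (after renormalization of fractions)
  outS <- collapseMarkerGroups(norm, list(g1 = "g1", g2 = "g2", g3 = "g3"),
                               renormalize = FALSE)
  expect_equal(unname(outS), unname(norm))
  expect_error(collapseMarkerGroups(norm, list(A = "missing")), "absent")
})

test_that("marker heatmap rows normalize per mode", {
  sim <- simulateExpression(nBackground = 6, noiseSd = 0.3, seed = 2)
  em <- sim$expression
  panel <- rownames(em)[1:4]
  hm <- relativeHeatmap(em, panel, mode = "max1")
  expect_equal(rownames(hm), panel)
  expect_equal(colnames(hm), stageLabels(fullDesign))
  expect_equal(unname(apply(hm, 1, max)), rep(1, 4))
  hz <- relativeHeatmap(em, panel, mode = "zscore")
  expect_equal(unname(rowMeans(hz)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(hz, 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_error(relativeHeatmap(em, c(panel, "nope")), "absent")
  flat <- exprFromMatrix(matrix(5, 1, 11, dimnames = list(
    "f", paste(designConditions(fullDesign)$stage,
               designConditions(fullDesign)$population, sep = ":"))))
  expect_error(relativeHeatmap(flat, "f", mode = "zscore"), "z-scored")
  neg <- exprFromMatrix(matrix(-1, 1, 11, dimnames = list(
    "n", paste(designConditions(fullDesign)$stage,
               designConditions(fullDesign)$population, sep = ":"))))
  expect_error(relativeHeatmap(neg, "n", mode = "max1"), "non-positive")
})
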