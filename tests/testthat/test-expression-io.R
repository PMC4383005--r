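test_that("delimited tables parse with stage:population headers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tES:unsorted\tNE:HES5+\tNE:HES5-",
               "PAX6\t4.5\t6.25\t5.0",
               "SOX2\t7.0\t7.5\t7.25"), tsv)
  em <- readExpressionTable(tsv, design = miniDesign)
  expect_s4_class(em, "StageExpression")
  expect_equal(dim(em), c(2L, 3L))
  expect_equal(rownames(em), c("PAX6", "SOX2"))
  expect_equal(unname(sampleStages(em)), c("ES", "NE", "NE"))
  expect_equal(unname(samplePopulations(em)),
               c("unsorted", "HES5+", "HES5-"))
  expect_equal(log2Values(em)["PAX6", "NE:HES5+"], 6.25)
})

test_that("reader rejects malformed tables with informative errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tES:unsorted\tNE:HES5+",
               "PAX6\t4.5\t6.25", "PAX6\t1\t2"), tsv)
  expect_error(readExpressionTable(tsv, miniDesign), "duplicate gene")

  writeLines(c("gene\tES:unsorted\tNE:HES5+",
               "PAX6\t4.5\toops"), tsv)
  expect_error(readExpressionTable(tsv, miniDesign),
               "non-numeric value 'oops' at row 'PAX6', column 'NE:HES5\\+'")

  # population absent from the design
  writeLines(c("gene\tES:unsorted\tNE:HES5plus",
               "PAX6\t4.5\t6.25"), tsv)
  expect_error(readExpressionTable(tsv, miniDesign), "outside the design")
})

test_that("reader rejects duplicated ids under fuzzing", {
  for (seed in 1:5) {
    em <- randomExpression(6, seed)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(em, tsv)
    lines <- readLines(tsv)
    dupRow <- sample(2:length(lines), 1)
    writeLines(c(lines, lines[dupRow]), tsv)
    expect_error(readExpressionTable(tsv), "duplicate gene")
  }
})

test_that("write/read round trip preserves values exactly", {
  em <- randomExpression(20, seed = 42)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(em, tsv)
  back <- readExpressionTable(tsv)
  expect_identical(log2Values(back), log2Values(em))
  expect_identical(sampleStages(back), sampleStages(em))
})

test_that("sidecar annotation works for plain sample ids", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "PAX6\t4\t6"), tsv)
  ann <- data.frame(sample = c("s1", "s2"), stage = c("ES", "NE"),
                    population = c("unsorted", "HES5+"))
  em <- readExpressionTable(tsv, miniDesign, annotation = ann)
  expect_equal(unname(sampleStages(em)), c("ES", "NE"))
  expect_error(
    readExpressionTable(tsv, miniDesign, annotation = ann[1, ]),
    "missing from annotation")
})

test_that("GEO series matrix parsing matches the TSV reader", {
  em <- randomExpression(3, seed = 9)
  v <- log2Values(em)
  colnames(v) <- sprintf("GSM%04d", seq_len(ncol(v)))
  geo <- withr::local_tempfile(fileext = ".txt")
  writeGeoFixture(geo, v)
  map <- data.frame(sample = colnames(v),
                    stage = unname(sampleStages(em)),
                    population = unname(samplePopulations(em)))
  got <- readGeoSeriesMatrix(geo, sampleMap = map)
  expect_equal(unname(log2Values(got)), unname(log2Values(em)))
  expect_equal(unname(sampleStages(got)), unname(sampleStages(em)))

  # strict mode rejects unmapped samples; lenient mode drops them
  expect_error(readGeoSeriesMatrix(geo, sampleMap = map[-1, ]),
               "not in sampleMap")
  expect_message(
    lenient <- readGeoSeriesMatrix(geo, sampleMap = map[-1, ],
                                   strict = FALSE),
    "dropping 1 unmapped")
  expect_equal(ncol(lenient), ncol(em) - 1L)

  # malformed block
  writeLines(c("!Series_title\t\"x\"", "no table here"), geo)
  expect_error(readGeoSeriesMatrix(geo, sampleMap = map), "malformed")
})

test_that("probe collapse keeps the highest-mean probe per symbol", {
  conds <- designConditions(miniDesign)
  v <- rbind(p1 = c(3, 3, 3), p2 = c(5, 5, 5), p3 = c(1, 2, 3))
  colnames(v) <- paste(conds$stage, conds$population, sep = ":")
  probes <- exprFromMatrix(v, miniDesign)
  map <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- collapseProbes(probes, map)
  expect_equal(rownames(out), c("G", "H"))
  expect_equal(unname(log2Values(out)["G", ]), c(5, 5, 5))  # mean-5 probe wins

  # identity when one probe per gene (rows renamed only)
  one <- collapseProbes(probes, c(p1 = "A", p2 = "B", p3 = "C"))
  expect_equal(unname(log2Values(one)[c("A", "B", "C"), ]), unname(v))

  expect_error(collapseProbes(probes, character()), "empty probe map")
  expect_error(collapseProbes(probes, map, method = "nope"))
})

test_that("collapse gene count equals distinct mapped symbols, any method", {
  set.seed(11)
  for (rep in 1:10) {
    nProbes <- sample(5:25, 1)
    em <- randomExpression(nProbes, seed = rep)
    symbols <- paste0("S", sample.int(max(2L, nProbes %/% 2L), nProbes,
                                      replace = TRUE))
    keepMapped <- runif(nProbes) > 0.2   # some probes left unmapped
    map <- setNames(symbols[keepMapped], rownames(em)[keepMapped])
    if (!length(map)) next
    expected <- length(unique(map))
    for (m in c("max_mean_probe", "mean", "max_per_sample")) {
      out <- suppressMessages(collapseProbes(em, map, method = m))
      expect_equal(nrow(out), expected)
    }
  }
})

test_that("unmapped probes are dropped and counted", {
  em <- randomExpression(5, seed = 3)
  map <- setNames(c("A", "A", "B"), rownames(em)[1:3])
  expect_message(out <- collapseProbes(em, map), "2 unmapped")
  expect_equal(S4Vectors::metadata(out)$collapse$nUnmapped, 2L)
})
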