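# Shared fixtures, built in code.

fullDesign <- StageDesign()

# two-stage design with one sorted population, for small IO examples
miniDesign <- StageDesign(
  stages = c("ES", "NE"),
  populations = list(ES = "unsorted", NE = c("HES5+", "HES5-")))

# StageExpression from a plain matrix whose colnames are "stage:population"
exprFromMatrix <- function(values, design = fullDesign) {
  parts <- strsplit(colnames(values), ":", fixed = TRUE)
  StageExpression(values,
                  stage = vapply(parts, `[`, character(1), 1L),
                  population = vapply(parts, `[`, character(1), 2L),
                  design = design)
}

# random full-design matrix (11 samples) for fuzz/property tests
randomExpression <- function(nGenes, seed, lo = 0, hi = 8) {
  set.seed(seed)
  conds <- designConditions(fullDesign)
  v <- matrix(runif(nGenes * nrow(conds), lo, hi), nGenes, nrow(conds),
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              paste(conds$stage, conds$population,
                                    sep = ":")))
  exprFromMatrix(v)
}

# brute-force variation-filter oracle: checks every sample pair per gene
bruteForceFilter <- function(values, minRange = 1, minLevel = 3) {
  apply(values, 1L, function(x) {
    anyPair <- any(abs(outer(x, x, "-")) >= minRange)
    anyPair && any(x >= minLevel)
  })
}

# a minimal GEO series matrix file written on the fly
writeGeoFixture <- function(path, values) {
  header <- c("!Series_title\t\"minimal fixture\"",
              paste0("!Sample_geo_accession\t",
                     paste(sprintf("\"%s\"", colnames(values)),
                           collapse = "\t")),
              "!series_matrix_table_begin")
  tab <- c(paste(c("\"ID_REF\"",
                   sprintf("\"%s\"", colnames(values))), collapse = "\t"),
           vapply(seq_len(nrow(values)), function(i)
             paste(c(sprintf("\"%s\"", rownames(values)[i]),
                     format(values[i, ], digits = 17)), collapse = "\t"),
             character(1)))
  writeLines(c(header, tab, "!series_matrix_table_end"), path)
  path
}
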