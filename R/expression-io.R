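#' Read a delimited expression table
#'
#' Reads a genes-in-rows TSV/CSV whose first column holds gene (or probe)
#' ids. Sample annotation comes either from the header, with column names
#' encoded `"<stage>:<population>"`, or from a sidecar annotation table
#' with columns `sample`, `stage`, `population`.
#'
#' @param path path to the delimited table.
#' @param design a \linkS4class{StageDesign} the annotations must match.
#' @param annotation optional sidecar annotation: a data.frame or the path
#'   of a TSV with columns `sample`, `stage`, `population`. When given,
#'   header names are plain sample ids.
#' @param sep field separator, default tab.
#' @return a \linkS4class{StageExpression}; row and column order of the
#'   file are preserved.
#' @export
readExpressionTable <- function(path, design = StageDesign(),
                                annotation = NULL, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs id column plus samples")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene/probe ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sampleIds <- colnames(tab)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  values <- matrix(NA_real_, nrow(tab), length(sampleIds),
                   dimnames = list(ids, sampleIds))
  for (j in seq_along(sampleIds)) {
    raw <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !raw %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   raw[bad[1L]], ids[bad[1L]], sampleIds[j]))
    if (anyNA(num))
      stop(sprintf("missing value at row '%s', column '%s'",
                   ids[which(is.na(num))[1L]], sampleIds[j]))
    values[, j] <- num
  }
  meta <- .sampleMeta(sampleIds, design, annotation)
  StageExpression(values, stage = meta$stage, population = meta$population,
                  design = design)
}

.sampleMeta <- function(sampleIds, design, annotation) {
  if (is.null(annotation)) {
    parts <- strsplit(sampleIds, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("header names must be '<stage>:<population>' ",
           "(or pass a sidecar annotation); offending: ",
           paste(sampleIds[lengths(parts) != 2L], collapse = ", "))
    meta <- data.frame(stage = vapply(parts, `[`, character(1), 1L),
                       population = vapply(parts, `[`, character(1), 2L))
  } else {
    if (is.character(annotation))
      annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    need <- c("sample", "stage", "population")
    if (!all(need %in% colnames(annotation)))
      stop("annotation needs columns ", paste(need, collapse = ", "))
    idx <- match(sampleIds, annotation$sample)
    if (anyNA(idx))
      stop("samples missing from annotation: ",
           paste(sampleIds[is.na(idx)], collapse = ", "))
    meta <- annotation[idx, c("stage", "population")]
  }
  ok <- mapply(function(s, p)
    s %in% stageLabels(design) && p %in% stagePopulations(design, s),
    meta$stage, meta$population)
  if (!all(ok))
    stop("sample annotation outside the design: ",
         paste(sprintf("%s (%s:%s)", sampleIds[!ok], meta$stage[!ok],
                       meta$population[!ok]), collapse = ", "))
  meta
}

#' Write an expression table
#'
#' Writes the matrix as TSV with the header encoding each sample as
#' `"<stage>:<population>"`, the format [readExpressionTable()] parses, at
#' full double precision so a read/write round trip is value-identical.
#'
#' @param em a \linkS4class{StageExpression}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(em, path) {
  v <- log2Values(em)
  colnames(v) <- paste(sampleStages(em), samplePopulations(em), sep = ":")
  df <- data.frame(gene = rownames(v), format(v, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Parses the text dialect of a GEO Series Matrix (metadata lines prefixed
#' `!`, one table block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`) and annotates the samples through a
#' user-supplied map of GEO sample accession to (stage, population).
#' Values are passed through unchanged; the caller states whether they are
#' already log2-scale.
#'
#' @param path path to the (uncompressed) series matrix file.
#' @param design a \linkS4class{StageDesign}.
#' @param sampleMap data.frame with columns `sample`, `stage`,
#'   `population`, keyed by the GSM accessions of the file.
#' @param strict if `TRUE` (default) a file sample absent from `sampleMap`
#'   is an error; if `FALSE` such samples are dropped with a message.
#' @return a \linkS4class{StageExpression} keyed by GSM accession.
#' @export
readGeoSeriesMatrix <- function(path, design = StageDesign(), sampleMap,
                                strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("malformed series matrix: expected one table block between ",
         "!series_matrix_table_begin and !series_matrix_table_end")
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "ID_REF")
    stop("malformed series matrix: table block must start with ID_REF")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate probe ids in table block")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric values in table block")
  rownames(values) <- ids
  need <- c("sample", "stage", "population")
  if (!all(need %in% colnames(sampleMap)))
    stop("sampleMap needs columns ", paste(need, collapse = ", "))
  idx <- match(colnames(values), sampleMap$sample)
  if (anyNA(idx)) {
    missing <- colnames(values)[is.na(idx)]
    if (strict)
      stop("samples not in sampleMap: ", paste(missing, collapse = ", "))
    message("dropping ", length(missing), " unmapped sample(s): ",
            paste(missing, collapse = ", "))
    values <- values[, !is.na(idx), drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  StageExpression(values, stage = sampleMap$stage[idx],
                  population = sampleMap$population[idx], design = design)
}

#' Read a probe-to-gene map
#'
#' @param path two-column TSV (probe id, gene symbol), with or without a
#'   header line `probe<TAB>symbol`. Probes with an empty symbol are
#'   treated as unmapped.
#' @return named character vector probe -> symbol.
#' @export
readProbeMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("probe", "symbol") %in% colnames(tab)))
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character",
                             col.names = c("probe", "symbol"))
  map <- setNames(tab$symbol, tab$probe)
  map[!is.na(map) & nzchar(map)]
}

#' Collapse probe-level intensities onto gene symbols
#'
#' Reduces a probe-level matrix to one row per distinct mapped gene symbol.
#' The default, `max_mean_probe`, keeps for each symbol the single probe
#' row with the highest mean intensity across samples, so each gene keeps
#' the trajectory of a real probe. Probes without a map entry are dropped
#' and counted (see `metadata(out)$collapse`).
#'
#' @param probes a probe-level \linkS4class{StageExpression}.
#' @param map named character vector (or data.frame with columns `probe`,
#'   `symbol`) mapping probe id -> gene symbol.
#' @param method `"max_mean_probe"` (default), `"mean"` (mean of probe rows
#'   per symbol) or `"max_per_sample"` (per-sample maximum).
#' @return gene-level \linkS4class{StageExpression}; the distinct-symbol
#'   count is independent of `method`.
#' @export
collapseProbes <- function(probes, map,
                           method = c("max_mean_probe", "mean",
                                      "max_per_sample")) {
  method <- match.arg(method)
  if (is.data.frame(map)) map <- setNames(map$symbol, map$probe)
  if (length(map) == 0L) stop("empty probe map")
  v <- log2Values(probes)
  sym <- map[rownames(v)]
  unmapped <- is.na(sym) | !nzchar(sym)
  nUnmapped <- sum(unmapped)
  if (nUnmapped)
    message("dropping ", nUnmapped, " unmapped probe(s)")
  v <- v[!unmapped, , drop = FALSE]
  sym <- sym[!unmapped]
  if (nrow(v) == 0L) stop("no mapped probes left to collapse")
  out <- switch(method,
    max_mean_probe = {
      means <- rowMeans(v)
      keep <- vapply(split(seq_along(sym), sym),
                     function(i) i[which.max(means[i])], integer(1))
      m <- v[keep, , drop = FALSE]
      rownames(m) <- names(keep)
      m
    },
    mean = {
      m <- rowsum(v, sym) / as.vector(table(sym)[sort(unique(sym))])
      m
    },
    max_per_sample = {
      groups <- split(seq_along(sym), sym)
      m <- t(vapply(groups, function(i)
        apply(v[i, , drop = FALSE], 2L, max), numeric(ncol(v))))
      m
    })
  out <- out[sort(rownames(out)), , drop = FALSE]
  res <- StageExpression(out, stage = sampleStages(probes),
                         population = samplePopulations(probes),
                         design = stageDesign(probes))
  S4Vectors::metadata(res)$collapse <-
    list(method = method, nProbes = nrow(probes), nUnmapped = nUnmapped,
         nGenes = nrow(out))
  res
}
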