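# Plain-text readers/writers for the formats the pipeline exchanges:
# expression TSV (first column gene_id), GMT gene-set collections, regulon
# and edge TSVs, TF lists, and a YAML study manifest.

#' Read / write an expression matrix TSV
#'
#' Rows are genes, columns samples; the first column is `gene_id`.
#'
#' @param path file path.
#' @return `readExpressionMatrix`: numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionMatrix
#' @param expr gene-by-sample matrix.
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path file path.
#' @return `readGmt`: named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, gs)
    paste(c(nm, ds, gs), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a transcription-factor list (one ID per line)
#' @param path file path.
#' @return character vector.
#' @export
readTfList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write / read a per-cohort edge table
#'
#' The edge statistics go to a TSV (`tf`, `target`, `pcor`, `z`, `p`, `q`)
#' and the cohort metadata (cohort id, sample size, shrinkage lambda, null
#' scale sigma0) to a JSON side-car file `<path>.meta.json`.
#'
#' @param et an [EdgeTable-class].
#' @param path TSV file path.
#' @export
writeEdgeTable <- function(et, path) {
  stopifnot(is(et, "EdgeTable"))
  utils::write.table(edges(et), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(cohort = cohortName(et), n_samples = nSamples(et),
               lambda = shrinkageLambda(et), sigma0 = nullScale(et))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  methods::new("EdgeTable", edges = ed, cohort = meta$cohort,
               nSamples = as.integer(meta$n_samples),
               lambda = as.numeric(meta$lambda),
               sigma0 = as.numeric(meta$sigma0))
}

#' Write a regulon table TSV (`tf`, `target`, `mode`, `likelihood`)
#' @param regs a [RegulonSet-class].
#' @param path file path.
#' @export
writeRegulons <- function(regs, path) {
  utils::write.table(regulonTable(regs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a regulon table TSV into a [RegulonSet-class]
#' @param path file path.
#' @export
readRegulons <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  methods::new("RegulonSet", table = tb, tfIds = unique(tb$tf),
               params = list(source = path))
}

#' Write all components of a synthetic study to a directory
#'
#' Emits one expression TSV per cohort plus the perturbation matrix and
#' labels, clinical, mutation and truth TSVs, the TF list, the
#' stromal/immune GMT fixtures, and a YAML manifest recording the
#' simulation parameters and seeds.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (co in cohorts(study))
    writeExpressionMatrix(co$expr, file.path(dir, paste0(co$name, ".tsv")))
  pe <- perturbation(study)
  writeExpressionMatrix(pe$expr, file.path(dir, "perturbation.tsv"))
  utils::write.table(
    data.frame(array = colnames(pe$expr), condition = pe$condition),
    file.path(dir, "perturbation_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clinicalTable(study), file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mutationTable(study), file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truthTable(study), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tfIds(studyNetwork(study)), file.path(dir, "tfs.txt"))
  writeGmt(studyGeneSets(study), file.path(dir, "admixture_sets.gmt"))
  yaml::write_yaml(study@params, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
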