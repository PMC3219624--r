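# Table schemas: required columns per input file.
.schemas <- list(
  genes = c("gene_id", "replicon", "start", "end", "strand", "operon_id",
            "subrole", "hypothetical"),
  strains = c("strain_id", "pool", "tag_id", "plate", "well", "gene_id",
              "insertion_pos", "gene_fraction", "transposon"),
  experiments = c("experiment_id", "pool", "class", "condition_name", "group"),
  intensities = c("experiment_id", "tag_id", "probe_index", "log2_intensity"),
  truth = c("gene_id", "condition_name", "true_fitness"),
  labels = c("gene_id", "role", "subrole"),
  regulons = c("tf", "target"))

#' Read and write the pipeline's tab-delimited tables
#'
#' All tables are TSV with a header row, UTF-8, "." decimal separator and
#' "-" as the missing-value marker. Comment lines starting with "#" (the
#' provenance stamp) are skipped on read.
#'
#' @param path file path
#' @param df data.frame to write
#' @param comment optional character vector written as "#"-prefixed lines
#' @return \code{readTsv} returns a data.frame
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) validationError("file not found: %s", path)
  utils::read.delim(path, sep = "\t", na.strings = "-", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readTsv
#' @export
writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
  invisible(path)
}

# matrix <-> TSV with an id column first
writeMatrixTsv <- function(mat, path, idCol = "gene_id", comment = NULL) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  writeTsv(df, path, comment)
}

readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

checkSchema <- function(df, what, path = what) {
  miss <- setdiff(.schemas[[what]], colnames(df))
  if (length(miss))
    validationError("%s: missing column(s) %s", path,
                    paste(miss, collapse = ", "))
  invisible(df)
}

#' Validate a dataset's referential and range integrity
#'
#' Checks the gene, strain, experiment and intensity tables against their
#' schemas: coordinates ordered, ids unique, strain -> gene and
#' intensity -> experiment references resolvable, gene_fraction within
#' [0, 1], experiment classes known. Violations raise a validation error
#' naming the offending row.
#'
#' @param genes,strains,experiments,intensities the four core tables
#'   (intensities may be NULL to skip)
#' @return invisibly TRUE
#' @export
validateDataset <- function(genes, strains, experiments, intensities = NULL) {
  checkSchema(genes, "genes")
  checkSchema(strains, "strains")
  checkSchema(experiments, "experiments")
  if (anyDuplicated(genes$gene_id))
    validationError("genes: duplicated gene_id '%s'",
                    genes$gene_id[anyDuplicated(genes$gene_id)])
  bad <- which(genes$start > genes$end)
  if (length(bad))
    validationError("genes row %d: start > end", bad[1])
  bad <- which(!genes$replicon %in% c("chromosome", "megaplasmid"))
  if (length(bad))
    validationError("genes row %d: unknown replicon '%s'", bad[1],
                    genes$replicon[bad[1]])

  bad <- which(!is.na(strains$gene_id) & !strains$gene_id %in% genes$gene_id)
  if (length(bad))
    validationError("strains row %d: gene_id '%s' not in gene table",
                    bad[1], strains$gene_id[bad[1]])
  bad <- which(!is.na(strains$gene_fraction) &
                 (strains$gene_fraction < 0 | strains$gene_fraction > 1))
  if (length(bad))
    validationError("strains row %d: gene_fraction %.3f outside [0, 1]",
                    bad[1], strains$gene_fraction[bad[1]])
  if (anyDuplicated(strains$tag_id))
    validationError("strains: duplicated tag_id '%s'",
                    strains$tag_id[anyDuplicated(strains$tag_id)])

  bad <- which(!experiments$class %in% c("start", "control", "condition"))
  if (length(bad))
    validationError("experiments row %d: unknown class '%s'", bad[1],
                    experiments$class[bad[1]])

  if (!is.null(intensities)) {
    checkSchema(intensities, "intensities")
    bad <- which(!unique(intensities$experiment_id) %in%
                   experiments$experiment_id)
    if (length(bad)) {
      badId <- unique(intensities$experiment_id)[bad[1]]
      row <- which(intensities$experiment_id == badId)[1]
      validationError("intensities row %d: experiment_id '%s' not in metadata",
                      row, badId)
    }
  }
  invisible(TRUE)
}

#' Read a dataset directory
#'
#' Loads genes.tsv, strains.tsv, experiments.tsv and intensities.tsv
#' (plus, when present, truth.tsv, labels.tsv, expression.tsv and
#' regulons.tsv) from \code{dir} and validates them.
#'
#' @param dir directory holding the TSV tables
#' @return named list of tables/matrices
#' @export
readDataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  ds <- list(genome = readTsv(p("genes.tsv")),
             strains = readTsv(p("strains.tsv")),
             experiments = readTsv(p("experiments.tsv")),
             intensities = readTsv(p("intensities.tsv")))
  validateDataset(ds$genome, ds$strains, ds$experiments, ds$intensities)
  if (file.exists(p("truth.tsv"))) {
    tr <- checkSchema(readTsv(p("truth.tsv")), "truth")
    conds <- unique(tr$condition_name)
    m <- matrix(0, nrow(ds$genome), length(conds),
                dimnames = list(ds$genome$gene_id, conds))
    m[cbind(match(tr$gene_id, ds$genome$gene_id),
            match(tr$condition_name, conds))] <- tr$true_fitness
    ds$truth <- m
  }
  if (file.exists(p("labels.tsv")))
    ds$labels <- checkSchema(readTsv(p("labels.tsv")), "labels")
  if (file.exists(p("expression.tsv")))
    ds$expression <- readMatrixTsv(p("expression.tsv"))
  if (file.exists(p("regulons.tsv")))
    ds$regulons <- checkSchema(readTsv(p("regulons.tsv")), "regulons")
  ds
}

#' Write a simulated dataset to a directory
#'
#' Emits the generator's tables in the interchange TSV formats, each
#' stamped with the provided provenance comment.
#'
#' @param sim list from \code{\link{simulateDataset}}
#' @param dir output directory (created if needed)
#' @param comment provenance stamp for every file
#' @return invisibly \code{dir}
#' @export
writeDataset <- function(sim, dir, comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeTsv(sim$genome, p("genes.tsv"), comment)
  writeTsv(poolStrains(sim$pools), p("strains.tsv"), comment)
  writeTsv(sim$experiments, p("experiments.tsv"), comment)
  writeTsv(sim$intensities, p("intensities.tsv"), comment)
  eff <- trueEffects(sim$truth)
  idx <- which(!is.na(eff), arr.ind = TRUE)
  writeTsv(data.frame(gene_id = rownames(eff)[idx[, 1]],
                      condition_name = colnames(eff)[idx[, 2]],
                      true_fitness = eff[idx]),
           p("truth.tsv"), comment)
  if (!is.null(sim$expression))
    writeMatrixTsv(sim$expression, p("expression.tsv"), comment = comment)
  if (!is.null(sim$regulons))
    writeTsv(sim$regulons, p("regulons.tsv"), comment)
  if (!is.null(sim$labels))
    writeTsv(sim$labels, p("labels.tsv"), comment)
  invisible(dir)
}
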