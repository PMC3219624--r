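# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# A mid-sized simulated study reused across test files.
standardSim <- function() {
  getFixture("standardSim", function() {
    sim <- simulateDataset(nGenes = 150, nInsertions = 340, nConditions = 10,
                           nControls = 14, probeSd = 0.3, plateSd = 0.15,
                           seed = 42)
    sim$sf <- computeStrainFitness(sim$intensities, sim$experiments,
                                   poolStrains(sim$pools), sim$genome)
    sim$gs <- scoreAndCalibrate(sim$sf)
    sim
  })
}

# Minimal StrainFitness built by hand: `values` is a tag x hybridization
# matrix; `info` a data.frame with at least strain_id, pool, gene_id, good
# (retained defaults to TRUE); `experiments` needs experiment_id, pool,
# class, condition_name.
makeStrainFitness <- function(values, info, experiments) {
  info$retained <- if (is.null(info$retained)) TRUE else info$retained
  info$detected <- TRUE
  rownames(values) <- info$tag_id <- if (is.null(info$tag_id))
    sprintf("tag%03d", seq_len(nrow(info))) else info$tag_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fitness = values),
    rowData = S4Vectors::DataFrame(info, row.names = info$tag_id),
    colData = S4Vectors::DataFrame(experiments,
                                   row.names = experiments$experiment_id))
  new("StrainFitness", se)
}

# Minimal GeneScores built by hand from assay matrices.
makeGeneScores <- function(nMat, tMat = NULL, fitMat = NULL, zMat = NULL,
                           class = rep("condition", ncol(nMat)),
                           psi = 0.3) {
  assays <- list(fitness = if (is.null(fitMat)) nMat * NA_real_ else fitMat,
                 n = nMat,
                 sd = nMat * NA_real_,
                 t = if (is.null(tMat)) nMat * NA_real_ else tMat)
  if (!is.null(zMat)) assays$z <- zMat
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(gene_id = rownames(nMat),
                                   row.names = rownames(nMat)),
    colData = S4Vectors::DataFrame(condition_name = colnames(nMat),
                                   class = class,
                                   row.names = colnames(nMat)))
  gs <- new("GeneScores", se)
  S4Vectors::metadata(gs)$psi <- psi
  gs
}

# Brute-force gene fitness from a strain table and per-condition values:
# the good-insertion/all-insertion fallback recomputed with plain loops.
bruteGeneFitness <- function(sf) {
  fit <- fitnessMatrix(sf)
  rd <- strainInfo(sf)
  cd <- experimentInfo(sf)
  conds <- unique(cd$condition_name[!is.na(cd$condition_name)])
  genes <- sort(unique(rd$gene_id[!is.na(rd$gene_id) & rd$retained]))
  out <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  for (cn in conds) {
    cols <- which(cd$condition_name == cn)
    for (g in genes) {
      rows <- which(!is.na(rd$gene_id) & rd$gene_id == g)
      vals <- c(); goods <- c()
      for (r in rows) for (j in cols) {
        v <- fit[r, j]
        if (!is.na(v)) { vals <- c(vals, v); goods <- c(goods, rd$good[r]) }
      }
      if (!length(vals)) next
      out[g, cn] <- if (any(goods)) mean(vals[goods]) else mean(vals)
    }
  }
  out
}

# Brute-force polarity counts: explicit double loop.
brutePolarity <- function(fit, pairs, sick = -2, healthy = -1) {
  up <- 0L; down <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$up[i] %in% rownames(fit)) ||
        !(pairs$down[i] %in% rownames(fit))) next
    for (j in seq_len(ncol(fit))) {
      a <- fit[pairs$up[i], j]; b <- fit[pairs$down[i], j]
      if (is.na(a) || is.na(b)) next
      if (a < sick && b > healthy) up <- up + 1L
      if (b < sick && a > healthy) down <- down + 1L
    }
  }
  list(up_only = up, down_only = down)
}
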