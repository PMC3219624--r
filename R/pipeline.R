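# Subrole label table derived from a (simulated) genome: specific labels
# for annotated genes, plus deliberately unspecific records that the
# label filter must remove.
makeLabels <- function(genome) {
  lab <- genome[!is.na(genome$subrole), c("gene_id", "subrole")]
  lab$role <- "Cellular processes"
  unlab <- genome$gene_id[is.na(genome$subrole) & genome$hypothetical]
  if (length(unlab)) {
    extra <- data.frame(gene_id = unlab,
                        subrole = "Enzymes of unknown specificity",
                        role = "Unknown function", stringsAsFactors = FALSE)
    lab <- rbind(lab, extra)
  }
  lab[, c("gene_id", "role", "subrole")]
}

#' Run the analysis pipeline
#'
#' Executes the pipeline stages in order — simulate (optional), fitness,
#' zscores, phenotypes, cofitness, qc (including polarity), predict,
#' regulon — writing every output table to \code{outDir}, stamped with the
#' configuration hash and seed. A run log (run.log) records per-stage
#' counts. Identical configuration and seed produce byte-identical
#' outputs. A stage failure stops the run naming the stage.
#'
#' @param config config list from \code{\link{readPipelineConfig}} (or a
#'   path to a config file)
#' @param outDir output directory
#' @param seed optional override of the config seed
#' @param stages character vector of stages to run, or "run" for all
#' @param quiet suppress progress messages
#' @return invisibly, a list with the in-memory stage results
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        seed = NULL, stages = "run", quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  all <- c("simulate", "fitness", "zscores", "phenotypes", "cofitness",
           "qc", "predict", "regulon")
  if (identical(stages, "run")) {
    stages <- all
    if (!config$simulate) stages <- setdiff(stages, "simulate")
  }
  bad <- setdiff(stages, all)
  if (length(bad)) validationError("unknown stage(s): %s", paste(bad, collapse = ", "))

  stamp <- sprintf("poolfit config=%s seed=%d", configHash(config), config$seed)
  logLines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  state <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), poolfit_validation_error = function(e) stop(e),
             error = function(e) {
               stop(errorCondition(
                 sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = c("poolfit_stage_error", "poolfit_error")))
             })
  }

  loadData <- function() {
    if (!is.null(state$data)) return(state$data)
    dir <- if (config$simulate) outDir else config$input_dir
    state$data <- readDataset(dir)
    state$data
  }

  runStage("simulate", function() {
    sim <- simulateDataset(
      nGenes = config$n_genes, nInsertions = config$n_insertions,
      nConditions = config$n_conditions, nControls = config$n_controls,
      probeSd = config$probe_sd, plateSd = config$plate_sd,
      sparsity = config$sparsity, effectScale = config$effect_scale,
      operonShare = config$operon_share, subroleEffect = config$subrole_effect,
      withExpression = config$with_expression, seed = config$seed)
    sim$labels <- makeLabels(sim$genome)
    writeDataset(sim, outDir, comment = stamp)
    note("simulate: %d genes, %d strains, %d hybridizations",
         nrow(sim$genome), nrow(sim$library), nrow(sim$experiments))
    state$data <- list(genome = sim$genome,
                       strains = poolStrains(sim$pools),
                       experiments = sim$experiments,
                       intensities = sim$intensities,
                       truth = trueEffects(sim$truth),
                       labels = sim$labels, expression = sim$expression,
                       regulons = sim$regulons)
  })

  runStage("fitness", function() {
    d <- loadData()
    sf <- computeStrainFitness(
      d$intensities, d$experiments, d$strains, d$genome,
      detectMultiplier = config$detect_multiplier,
      lowStartFraction = config$low_start_fraction,
      repliconPass = config$replicon_pass, platePass = config$plate_pass)
    rd <- rowData(sf)
    note("fitness: %d/%d read-outs detected, %d retained after low-start filter",
         sum(rd$detected), nrow(sf), sum(rd$retained))
    writeMatrixTsv(fitnessMatrix(sf), file.path(outDir, "strain_fitness.tsv"),
                   idCol = "tag_id", comment = stamp)
    state$sf <- sf
  })

  getSF <- function() {
    if (is.null(state$sf)) {
      d <- loadData()
      state$sf <- computeStrainFitness(
        d$intensities, d$experiments, d$strains, d$genome,
        detectMultiplier = config$detect_multiplier,
        lowStartFraction = config$low_start_fraction,
        repliconPass = config$replicon_pass, platePass = config$plate_pass)
    }
    state$sf
  }

  getGS <- function() {
    if (is.null(state$gs))
      state$gs <- scoreAndCalibrate(getSF(), minStratum = config$min_stratum)
    state$gs
  }

  runStage("zscores", function() {
    gs <- getGS()
    note("zscores: %d genes scored over %d experiments, Psi = %.4f",
         nrow(gs), ncol(gs), psi(gs))
    writeMatrixTsv(fitnessMatrix(gs), file.path(outDir, "gene_fitness.tsv"),
                   comment = stamp)
    writeMatrixTsv(zMatrix(gs), file.path(outDir, "zscores.tsv"),
                   comment = stamp)
  })

  runStage("phenotypes", function() {
    gs <- getGS()
    tests <- phenotypeTest(gs, alpha = config$phenotype_alpha)
    nCond <- length(conditionColumns(gs))
    zStar <- bonferroniZThreshold(config$bonferroni_alpha, nCond)
    strong <- strongPatternGenes(tests, gs, zStar)
    tests$strong_pattern <- tests$gene_id %in% strong
    counts <- countSignificantChanges(gs, zGate = config$change_z_gate)
    tests <- merge(tests, counts, by = "gene_id", sort = TRUE)
    note("phenotypes: %d/%d genes significant at P<%g; %d strong patterns (z* = %.2f)",
         sum(tests$significant), nrow(tests), config$phenotype_alpha,
         sum(tests$strong_pattern), zStar)
    writeTsv(tests, file.path(outDir, "phenotypes.tsv"), comment = stamp)
    state$tests <- tests
  })

  runStage("cofitness", function() {
    gs <- getGS()
    fit <- fitnessMatrix(gs)[, conditionColumns(gs), drop = FALSE]
    cof <- cofitness(fit, minExperiments = config$min_experiments)
    prs <- cofitnessPairs(cof, threshold = config$cofitness_threshold)
    note("cofitness: %d pairs with |r| >= %.2f over %d genes",
         nrow(prs), config$cofitness_threshold, nrow(fit))
    writeTsv(prs, file.path(outDir, "cofitness.tsv"), comment = stamp)
    state$cofitness <- cof
  })

  runStage("qc", function() {
    d <- loadData()
    gs <- getGS()
    qc <- experimentQC(getSF(), gs, d$genome)
    writeTsv(qc, file.path(outDir, "qc.tsv"), comment = stamp)
    fit <- fitnessMatrix(gs)[, conditionColumns(gs), drop = FALSE]
    pol <- polarityCounts(fit, operonAdjacentPairs(d$genome),
                          sickThresh = config$sick_threshold,
                          healthyThresh = config$healthy_threshold)
    writeLines(c(paste0("# ", stamp),
                 sprintf("up_only\t%d", pol$up_only),
                 sprintf("down_only\t%d", pol$down_only),
                 sprintf("pvalue\t%.6g", pol$pvalue)),
               file.path(outDir, "polarity.txt"))
    note("qc: median r_same %.3f, median r_operon %.3f; polarity %d vs %d (P = %.3g)",
         safeMedian(qc$r_same[qc$class == "condition"]),
         safeMedian(qc$r_operon[qc$class == "condition"]),
         pol$up_only, pol$down_only, pol$pvalue)
    state$qc <- qc
    state$polarity <- pol
  })

  runStage("predict", function() {
    d <- loadData()
    if (is.null(d$labels)) {
      note("predict: no labels available, stage skipped")
      return(invisible(NULL))
    }
    gs <- getGS()
    fit <- fitnessMatrix(gs)[, conditionColumns(gs), drop = FALSE]
    feats <- switch(config$feature_source,
      fitness = prepareFeatures(fit),
      expression = prepareFeatures(d$expression),
      both = prepareFeatures(fit, d$expression),
      validationError("feature_source must be fitness, expression or both"))
    labs <- filterSubroles(d$labels)
    labVec <- stats::setNames(labs$subrole, labs$gene_id)
    operon <- stats::setNames(d$genome$operon_id, d$genome$gene_id)
    genes <- intersect(rownames(feats), d$genome$gene_id)
    folds <- operonwiseFolds(genes, operon[genes], k = config$k_folds,
                             seed = deriveSeed(config$seed, 11))
    preds <- predictSubroles(feats[genes, , drop = FALSE], labVec, folds,
                             nTrees = config$n_trees,
                             seed = deriveSeed(config$seed, 12))
    lb <- preds[!is.na(preds$correct), ]
    note("predict: %d labeled genes cross-validated, accuracy %.3f; %d unlabeled predicted",
         nrow(lb), mean(lb$correct), sum(is.na(preds$correct)))
    writeTsv(preds, file.path(outDir, "predictions.tsv"), comment = stamp)
    state$predictions <- preds
  })

  runStage("regulon", function() {
    d <- loadData()
    if (is.null(d$regulons) || is.null(d$expression)) {
      note("regulon: no regulon pairs/expression available, stage skipped")
      return(invisible(NULL))
    }
    rc <- regulonCorrelation(d$regulons, d$expression,
                             nShuffles = config$n_shuffles,
                             seed = deriveSeed(config$seed, 13))
    shufQ <- stats::ecdf(rc$shuffled)
    pairs <- rc$pairs
    pairs$r <- rc$observed
    pairs$shuffled_quantile <- shufQ(pairs$r)
    note("regulon: %d pairs, median shift over shuffled null %.3f",
         rc$n_pairs, rc$shift)
    writeTsv(pairs, file.path(outDir, "regulon.tsv"), comment = stamp)
    state$regulon <- rc
  })

  writeLines(c(paste0("# ", stamp), logLines), file.path(outDir, "run.log"))
  invisible(as.list(state))
}
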