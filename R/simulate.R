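#' Simulate a bacterial genome with operon structure
#'
#' Generates a gene table for a two-replicon genome (main chromosome plus a
#' small megaplasmid) with contiguous operons, strand per operon, optional
#' functional subrole labels shared within operons, and a hypothetical-gene
#' flag. Coordinates are 1-based inclusive; genes are laid out sequentially
#' with random lengths and intergenic gaps.
#'
#' @param nGenes total number of protein-coding genes (>= 10)
#' @param megaplasmidFraction fraction of genes on the megaplasmid
#' @param meanOperonSize mean operon size in genes (>= 1); operon sizes are
#'   1 + Geometric, giving the stated mean
#' @param nSubroles number of distinct functional subrole labels
#' @param subroleFraction fraction of operons carrying a subrole label
#'   (all member genes inherit it)
#' @param hypotheticalFraction fraction of unlabeled genes flagged
#'   hypothetical
#' @param seed integer random seed
#' @return data.frame with columns gene_id, replicon, start, end, strand,
#'   operon_id, subrole (NA when unlabeled), hypothetical
#' @export
simulateGenome <- function(nGenes, megaplasmidFraction = 0.035,
                           meanOperonSize = 2, nSubroles = 8,
                           subroleFraction = 0.3,
                           hypotheticalFraction = 0.37, seed = 1) {
  stopifnotScalarCount(nGenes, "nGenes", min = 10L)
  stopifnotProportion(megaplasmidFraction, "megaplasmidFraction")
  if (!is.numeric(meanOperonSize) || meanOperonSize < 1)
    parameterError("'meanOperonSize' must be >= 1")
  stopifnotScalarCount(nSubroles, "nSubroles", min = 1L)
  set.seed(seed)

  nMega <- round(nGenes * megaplasmidFraction)
  nChrom <- nGenes - nMega
  counts <- c(chromosome = nChrom, megaplasmid = nMega)
  counts <- counts[counts > 0]

  opCounter <- 0L
  pieces <- lapply(names(counts), function(rep) {
    m <- counts[[rep]]
    # operon sizes: 1 + geometric with success prob 1/mean, truncated to fill
    sizes <- integer(0)
    while (sum(sizes) < m)
      sizes <- c(sizes, 1L + stats::rgeom(max(m, 16L), prob = 1 / meanOperonSize))
    sizes <- sizes[cumsum(sizes) - sizes < m]
    excess <- sum(sizes) - m
    if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
    sizes <- sizes[sizes > 0]

    lens <- round(stats::runif(m, 300, 3000))
    gaps <- round(stats::runif(m, 50, 300))
    start <- cumsum(c(1, (lens + gaps)[-m]))
    opIdx <- rep(seq_along(sizes), sizes)
    strands <- sample(c("+", "-"), length(sizes), replace = TRUE)
    df <- data.frame(
      replicon = rep, start = start, end = start + lens - 1L,
      strand = strands[opIdx],
      operon_local = opIdx, stringsAsFactors = FALSE)
    df$operon_id <- sprintf("op%04d", opCounter + opIdx)
    opCounter <<- opCounter + length(sizes)
    df
  })
  genes <- do.call(rbind, pieces)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))

  # subroles assigned per operon so function is coherent within operons
  ops <- unique(genes$operon_id)
  labeled <- ops[stats::runif(length(ops)) < subroleFraction]
  palette <- sprintf("SR%02d", seq_len(nSubroles))
  opRole <- stats::setNames(sample(palette, length(labeled), replace = TRUE), labeled)
  genes$subrole <- unname(opRole[genes$operon_id])
  genes$hypothetical <- is.na(genes$subrole) &
    stats::runif(nrow(genes)) < hypotheticalFraction

  genes[, c("gene_id", "replicon", "start", "end", "strand", "operon_id",
            "subrole", "hypothetical")]
}

#' Simulate a transposon insertion library
#'
#' Draws insertion sites for a mutant collection. Genic insertions pick a
#' gene uniformly and a position uniform within it; the insertion's relative
#' position along the transcribed strand (gene_fraction, 0 = start codon
#' side) is recorded. Intergenic insertions carry no gene.
#'
#' @param genome gene table from \code{\link{simulateGenome}}
#' @param nInsertions number of mutant strains to draw
#' @param intergenicFraction fraction of insertions landing between genes
#' @param seed integer random seed
#' @return data.frame with columns strain_id, gene_id (NA if intergenic),
#'   insertion_pos, gene_fraction (NA if intergenic), transposon
#' @export
simulateInsertionLibrary <- function(genome, nInsertions,
                                     intergenicFraction = 0.1, seed = 1) {
  stopifnotScalarCount(nInsertions, "nInsertions")
  stopifnotProportion(intergenicFraction, "intergenicFraction")
  set.seed(seed)

  inter <- stats::runif(nInsertions) < intergenicFraction
  idx <- sample.int(nrow(genome), nInsertions, replace = TRUE)
  pos <- floor(stats::runif(nInsertions, genome$start[idx], genome$end[idx] + 1))
  len <- genome$end[idx] - genome$start[idx]
  frac <- ifelse(genome$strand[idx] == "+",
                 (pos - genome$start[idx]) / len,
                 (genome$end[idx] - pos) / len)
  gene <- genome$gene_id[idx]
  # intergenic sites: uniform over the chromosome span, no gene attribution
  chromEnd <- max(genome$end[genome$replicon == "chromosome"])
  pos[inter] <- floor(stats::runif(sum(inter), 1, chromEnd + 1))
  gene[inter] <- NA_character_
  frac[inter] <- NA_real_

  data.frame(strain_id = sprintf("S%05d", seq_len(nInsertions)),
             gene_id = gene, insertion_pos = pos, gene_fraction = frac,
             transposon = sample(c("Tn5", "mariner"), nInsertions, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Assemble tagged strains into two pools
#'
#' Assigns strains to the upPool and dnPool (a strain present in both pools
#' is read out with a distinct tag in each), gives each (strain, pool)
#' read-out a unique tag drawn from the pool's tag-module capacity, groups
#' strains into 96-well plates, and flags a fraction of read-outs as truly
#' undetectable (tag failures, tracking errors).
#'
#' @param strains insertion library from \code{\link{simulateInsertionLibrary}}
#' @param nTagModules tag capacity per pool; unused tags remain on the array
#'   and provide the background estimate
#' @param plateSize strains per plate group (default 96)
#' @param detectFailureRate fraction of read-outs flagged truly undetectable
#' @param poolOverlap probability a strain is placed in both pools
#' @param seed integer random seed
#' @return a \linkS4class{PoolSet}
#' @export
assemblePools <- function(strains, nTagModules, plateSize = 96L,
                          detectFailureRate = 0.02, poolOverlap = 0.43,
                          seed = 1) {
  stopifnotScalarCount(nTagModules, "nTagModules")
  stopifnotScalarCount(plateSize, "plateSize")
  stopifnotProportion(detectFailureRate, "detectFailureRate")
  stopifnotProportion(poolOverlap, "poolOverlap")
  set.seed(seed)

  n <- nrow(strains)
  both <- stats::runif(n) < poolOverlap
  solo <- sample(c("up", "dn"), n, replace = TRUE)
  plate <- sprintf("plate%03d", ceiling(seq_len(n) / plateSize))
  well <- ((seq_len(n) - 1L) %% plateSize) + 1L

  rows <- lapply(c("up", "dn"), function(p) {
    inPool <- both | solo == p
    if (sum(inPool) > nTagModules)
      stop(errorCondition(
        sprintf("pool '%s' needs %d tags but capacity is %d",
                p, sum(inPool), nTagModules),
        class = c("poolfit_capacity_error", "poolfit_error")))
    tagIdx <- sort(sample.int(nTagModules, sum(inPool)))
    data.frame(strain_id = strains$strain_id[inPool], pool = p,
               tag_id = sprintf("%s_tag%05d", p, tagIdx),
               plate = plate[inPool], well = well[inPool],
               gene_id = strains$gene_id[inPool],
               insertion_pos = strains$insertion_pos[inPool],
               gene_fraction = strains$gene_fraction[inPool],
               transposon = strains$transposon[inPool],
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, rows)
  undet <- st$tag_id[stats::runif(nrow(st)) < detectFailureRate]
  new("PoolSet", strains = st, nTagModules = as.integer(nTagModules),
      plateSize = as.integer(plateSize), undetectableTags = undet)
}

#' Simulate ground-truth fitness effects
#'
#' Draws a sparse gene-by-condition matrix of true log2 fitness effects.
#' Effects are mostly deleterious (negative), drawn around
#' \code{-effectScale}; with probability \code{operonShare} an effect is
#' copied to all operon mates, emulating shared pathway membership. The
#' seeding rate is deflated by the genome's expected operon amplification so
#' the realized nonzero fraction matches \code{sparsity}. Control conditions
#' are all-zero. Optionally, each functional subrole imprints a shared
#' signature on its member genes in a random subset of conditions, so that
#' subrole is learnable from the fitness pattern.
#'
#' @param genome gene table from \code{\link{simulateGenome}}
#' @param nConditions number of treatment conditions
#' @param nControls number of control conditions (>= 2)
#' @param sparsity target fraction of nonzero (gene, condition) effects
#' @param effectScale typical |log2| effect size of a fitness defect
#' @param operonShare probability an effect is copied to operon mates
#' @param subroleEffect if > 0, genes sharing a subrole get a common effect
#'   of about this magnitude in ~25\% of conditions
#' @param seed integer random seed
#' @return a \linkS4class{TrueFitness}
#' @export
simulateTruth <- function(genome, nConditions = 40, nControls = 14,
                          sparsity = 0.05, effectScale = 3,
                          operonShare = 0.8, subroleEffect = 0, seed = 1) {
  stopifnotScalarCount(nConditions, "nConditions")
  stopifnotScalarCount(nControls, "nControls", min = 2L)
  stopifnotProportion(sparsity, "sparsity")
  stopifnotProportion(operonShare, "operonShare")
  set.seed(seed)

  genes <- genome$gene_id
  conds <- sprintf("C%02d", seq_len(nConditions))
  ctrls <- sprintf("ctrl%02d", seq_len(nControls))
  eff <- matrix(0, nrow(genome), nConditions + nControls,
                dimnames = list(genes, c(conds, ctrls)))

  opSize <- table(genome$operon_id)
  mates <- as.numeric(opSize[genome$operon_id]) - 1
  amplification <- 1 + operonShare * mean(mates)
  seedRate <- min(1, sparsity / amplification)

  opMembers <- split(seq_len(nrow(genome)), genome$operon_id)
  for (j in seq_len(nConditions)) {
    hit <- which(stats::runif(nrow(genome)) < seedRate)
    if (!length(hit)) next
    val <- -abs(stats::rnorm(length(hit), effectScale, 1))
    flip <- stats::runif(length(hit)) < 0.1
    val[flip] <- -val[flip]
    eff[hit, j] <- val
    share <- hit[stats::runif(length(hit)) < operonShare]
    for (k in seq_along(share)) {
      g <- share[k]
      eff[opMembers[[genome$operon_id[g]]], j] <- eff[g, j]
    }
  }

  if (subroleEffect > 0) {
    for (sr in unique(stats::na.omit(genome$subrole))) {
      members <- which(genome$subrole %in% sr)
      active <- which(stats::runif(nConditions) < 0.25)
      for (j in active) {
        amp <- -subroleEffect * stats::runif(1, 0.5, 1.5)
        eff[members, j] <- eff[members, j] + amp +
          stats::rnorm(length(members), 0, 0.2)
      }
    }
  }

  new("TrueFitness", effects = eff,
      conditionClass = c(rep("condition", nConditions), rep("control", nControls)),
      edgeAttenuation = 0.5, operonShare = operonShare)
}

#' Simulate tag-array intensities
#'
#' Emits the probe-level log2 intensity table for all hybridizations of a
#' simulated study: one start array per pool, control arrays (independent
#' pool recoveries, zero true effect), and one array per pool per condition.
#' Each detectable read-out's start level is drawn from N(startMean,
#' startSd) with a low tail just above the detection threshold (exercising
#' the low-start filter); condition level = start level + true strain
#' fitness (attenuated for insertions outside the central 5--80\% of the
#' gene) + a per-(plate, array) batch effect + a per-array megaplasmid
#' shift + probe noise. Truly undetectable read-outs and unused tags sit at
#' background.
#'
#' @param poolset a \linkS4class{PoolSet}
#' @param truth a \linkS4class{TrueFitness}
#' @param genome gene table (for gene -> replicon/effect lookup)
#' @param probeSd per-probe noise SD (log2 units)
#' @param plateSd SD of per-(plate, array) batch effects (log2 units)
#' @param repliconShift SD of the per-array megaplasmid level shift
#' @param backgroundLevel log2 level of unused tags
#' @param startMean,startSd start-level distribution (log2)
#' @param lowTailFraction fraction of read-outs in the low start tail
#' @param nProbes replicate probes per tag per array
#' @param nStarts shared start hybridizations per pool (averaged for
#'   detection and the low-start filter, and used as the reference when no
#'   paired start exists)
#' @param pairedStarts when TRUE (the assay's primary design), every
#'   condition and control hybridization is accompanied by its own start
#'   hybridization of the same pool, recorded in the experiment table's
#'   \code{group} column; log ratios then carry no shared reference noise
#'   across experiments
#' @param detectMultiplier linear-scale detection threshold over background
#'   (used to place the low tail above detectability)
#' @param seed integer random seed
#' @return list with elements \code{intensities} (experiment_id, tag_id,
#'   probe_index, log2_intensity) and \code{experiments} (experiment_id,
#'   pool, class, condition_name, group)
#' @export
simulateIntensities <- function(poolset, truth, genome, probeSd = 0.3,
                                plateSd = 0.15, repliconShift = 0.1,
                                backgroundLevel = 3, startMean = 10,
                                startSd = 1, lowTailFraction = 0.03,
                                nProbes = 5L, nStarts = 2L,
                                pairedStarts = TRUE,
                                detectMultiplier = 5, seed = 1) {
  if (!is.numeric(probeSd) || probeSd <= 0)
    parameterError("'probeSd' must be > 0")
  stopifnotScalarCount(nProbes, "nProbes")
  set.seed(seed)

  st <- poolset@strains
  repliconOf <- stats::setNames(genome$replicon, genome$gene_id)
  strainReplicon <- ifelse(is.na(st$gene_id), "chromosome",
                           unname(repliconOf[st$gene_id]))
  good <- !is.na(st$gene_fraction) &
    st$gene_fraction >= 0.05 & st$gene_fraction <= 0.80
  attEdge <- ifelse(good | is.na(st$gene_id), 1, truth@edgeAttenuation)
  undet <- st$tag_id %in% poolset@undetectableTags

  # start levels per read-out
  thr <- log2(detectMultiplier) + backgroundLevel
  startLevel <- stats::rnorm(nrow(st), startMean, startSd)
  lowTail <- stats::runif(nrow(st)) < lowTailFraction
  startLevel[lowTail] <- stats::runif(sum(lowTail), thr + 0.2,
                                      max(thr + 0.4, startMean - 2 * startSd))
  startLevel[undet] <- backgroundLevel + stats::rnorm(sum(undet), 0, 0.2)

  condNames <- colnames(truth@effects)
  condClass <- truth@conditionClass
  pools <- sort(unique(st$pool))
  startIds <- as.vector(outer(sprintf("start%02d", seq_len(nStarts)),
                              pools, paste, sep = "_"))
  experiments <- rbind(
    if (nStarts > 0)
      data.frame(experiment_id = startIds,
                 pool = rep(pools, each = nStarts),
                 class = "start", condition_name = NA_character_,
                 group = NA_character_, stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(condNames), function(j) {
      data.frame(experiment_id = paste0(condNames[j], "_", pools), pool = pools,
                 class = condClass[j], condition_name = condNames[j],
                 group = if (pairedStarts)
                   paste0("start_", condNames[j], "_", pools)
                 else NA_character_,
                 stringsAsFactors = FALSE)
    })))
  if (pairedStarts) {
    paired <- data.frame(
      experiment_id = stats::na.omit(experiments$group),
      pool = experiments$pool[!is.na(experiments$group)],
      class = "start", condition_name = NA_character_,
      group = NA_character_, stringsAsFactors = FALSE)
    experiments <- rbind(experiments, paired)
  }
  if (!any(experiments$class == "start"))
    parameterError("need nStarts >= 1 when pairedStarts is FALSE")

  effIdx <- match(st$gene_id, rownames(truth@effects))

  chunks <- vector("list", nrow(experiments))
  for (e in seq_len(nrow(experiments))) {
    p <- experiments$pool[e]
    cls <- experiments$class[e]
    inPool <- st$pool == p
    lev <- startLevel[inPool]
    if (cls != "start") {
      rows <- which(inPool)
      delta <- numeric(length(rows))
      if (cls == "condition") {
        j <- match(experiments$condition_name[e], condNames)
        tf <- truth@effects[, j][effIdx[rows]]
        tf[is.na(tf)] <- 0
        delta <- delta + tf * attEdge[rows]
      }
      # plate batch effect, drawn once per (plate, array)
      pl <- factor(st$plate[rows])
      plEff <- stats::rnorm(nlevels(pl), 0, plateSd)
      delta <- delta + plEff[as.integer(pl)]
      # megaplasmid shift, one draw per array
      delta <- delta + ifelse(strainReplicon[rows] == "megaplasmid",
                              stats::rnorm(1, 0, repliconShift), 0)
      delta[undet[rows]] <- 0
      lev <- lev + delta
    }
    # unused tags at background
    usedIdx <- as.integer(sub("^.*_tag", "", st$tag_id[inPool]))
    unusedIdx <- setdiff(seq_len(poolset@nTagModules), usedIdx)
    tagIds <- c(st$tag_id[inPool], sprintf("%s_tag%05d", p, unusedIdx))
    levels <- c(lev, rep(backgroundLevel, length(unusedIdx)))
    nTags <- length(tagIds)
    chunks[[e]] <- data.frame(
      experiment_id = experiments$experiment_id[e],
      tag_id = rep(tagIds, each = nProbes),
      probe_index = rep(seq_len(nProbes), nTags),
      log2_intensity = rep(levels, each = nProbes) +
        stats::rnorm(nTags * nProbes, 0, probeSd),
      stringsAsFactors = FALSE)
  }

  list(intensities = do.call(rbind, chunks), experiments = experiments)
}

#' Simulate a gene expression compendium with regulon structure
#'
#' Generates gene-by-experiment expression log ratios where each
#' transcription factor's targets track the factor's expression with a
#' target correlation of \code{coupling}; unrelated genes are independent.
#'
#' @param genome gene table
#' @param regulons data.frame with columns tf, target (gene ids)
#' @param nExperiments number of expression experiments (>= 2)
#' @param coupling target TF--target expression correlation in [0, 1]
#' @param seed integer random seed
#' @return numeric matrix, genes x experiments
#' @export
simulateExpression <- function(genome, regulons, nExperiments, coupling = 0.7,
                               seed = 1) {
  if (!is.numeric(nExperiments) || nExperiments < 2)
    parameterError("'nExperiments' must be >= 2 (correlation undefined below)")
  stopifnotProportion(coupling, "coupling")
  bad <- setdiff(unique(c(regulons$tf, regulons$target)), genome$gene_id)
  if (length(bad))
    validationError("regulon gene ids absent from genome: %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  set.seed(seed)

  mat <- matrix(stats::rnorm(nrow(genome) * nExperiments), nrow(genome),
                dimnames = list(genome$gene_id,
                                sprintf("expr%03d", seq_len(nExperiments))))
  for (i in seq_len(nrow(regulons))) {
    tf <- regulons$tf[i]; tg <- regulons$target[i]
    if (tf == tg) next
    mat[tg, ] <- coupling * mat[tf, ] +
      sqrt(1 - coupling^2) * stats::rnorm(nExperiments)
  }
  mat
}

#' Draw random TF -> target regulons from a genome
#'
#' Convenience generator for regulon pair lists: picks TFs at random and
#' assigns each a random set of target genes (possibly including itself, to
#' exercise autoregulatory-pair exclusion downstream).
#'
#' @param genome gene table
#' @param nTFs number of transcription factors
#' @param targetsPerTF targets per TF
#' @param autoregFraction fraction of TFs that also list themselves
#' @param seed integer random seed
#' @return data.frame with columns tf, target
#' @export
simulateRegulons <- function(genome, nTFs = 10, targetsPerTF = 5,
                             autoregFraction = 0.1, seed = 1) {
  set.seed(seed)
  tfs <- sample(genome$gene_id, nTFs)
  do.call(rbind, lapply(tfs, function(tf) {
    tg <- sample(setdiff(genome$gene_id, tf), targetsPerTF)
    if (stats::runif(1) < autoregFraction) tg <- c(tg, tf)
    data.frame(tf = tf, target = tg, stringsAsFactors = FALSE)
  }))
}

#' Simulate a complete study dataset
#'
#' One-call generator tying the pieces together: genome, insertion library,
#' pools, ground-truth effects, tag intensities, and (optionally) an
#' expression compendium with regulons. All stage seeds derive
#' deterministically from \code{seed}.
#'
#' @param nGenes,nInsertions,nConditions,nControls scale parameters
#' @param probeSd,plateSd per-probe and per-plate noise SDs (log2)
#' @param sparsity,effectScale,operonShare truth parameters
#' @param subroleEffect see \code{\link{simulateTruth}}
#' @param withExpression also simulate expression and regulons
#' @param seed integer global seed
#' @param ... further arguments passed to \code{\link{simulateIntensities}}
#' @return named list: genome, library, pools, truth, intensities,
#'   experiments, and optionally expression, regulons
#' @export
simulateDataset <- function(nGenes = 400, nInsertions = 900, nConditions = 40,
                            nControls = 14, probeSd = 0.3, plateSd = 0.15,
                            sparsity = 0.05, effectScale = 3,
                            operonShare = 0.8, subroleEffect = 0,
                            withExpression = FALSE, seed = 1, ...) {
  genome <- simulateGenome(nGenes, seed = deriveSeed(seed, 1))
  lib <- simulateInsertionLibrary(genome, nInsertions,
                                  seed = deriveSeed(seed, 2))
  pools <- assemblePools(lib, nTagModules = ceiling(nInsertions * 0.9),
                         detectFailureRate = 0.02,
                         seed = deriveSeed(seed, 3))
  truth <- simulateTruth(genome, nConditions, nControls, sparsity,
                         effectScale, operonShare, subroleEffect,
                         seed = deriveSeed(seed, 4))
  sim <- simulateIntensities(pools, truth, genome, probeSd = probeSd,
                             plateSd = plateSd, seed = deriveSeed(seed, 5),
                             ...)
  out <- list(genome = genome, library = lib, pools = pools, truth = truth,
              intensities = sim$intensities, experiments = sim$experiments)
  if (withExpression) {
    out$regulons <- simulateRegulons(genome, seed = deriveSeed(seed, 6))
    out$expression <- simulateExpression(genome, out$regulons,
                                         nExperiments = 60, coupling = 0.7,
                                         seed = deriveSeed(seed, 7))
  }
  out
}
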