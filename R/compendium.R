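#' Cofitness: pairwise fitness correlation across the compendium
#'
#' Pearson correlation of every gene pair's fitness vectors over the
#' experiments where both genes are measured (pairwise-complete). Pairs
#' with fewer than \code{minExperiments} shared experiments, or with a
#' constant vector, are left undefined (NA).
#'
#' @param fit gene x experiment fitness matrix
#' @param minExperiments minimum shared experiments per pair
#' @return list with matrices \code{r} (correlations) and \code{n}
#'   (shared-experiment counts)
#' @export
cofitness <- function(fit, minExperiments = 10L) {
  if (ncol(fit) < minExperiments)
    validationError("matrix has %d experiments, fewer than minExperiments=%d",
                    ncol(fit), minExperiments)
  r <- suppressWarnings(stats::cor(t(fit), use = "pairwise.complete.obs"))
  obs <- !is.na(fit)
  n <- obs %*% t(obs)
  r[n < minExperiments] <- NA_real_
  list(r = r, n = n)
}

#' Correlation P-value via the t transform
#'
#' Two-sided P for a Pearson correlation r over n observations, from
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) with n - 2 degrees of freedom.
#' |r| = 1 gives P = 0 by convention; n < 3 gives NA.
#'
#' @param r correlation(s)
#' @param n number(s) of observations
#' @return two-sided P-value(s)
#' @export
cofitnessPvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1 & n >= 3
  p[exact] <- 0
  ok <- !is.na(r) & abs(r) < 1 & !is.na(n) & n >= 3
  t <- r[ok] * sqrt(n[ok] - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t), n[ok] - 2)
  if (is.matrix(r)) p <- matrix(p, nrow(r), dimnames = dimnames(r))
  p
}

#' Extract strong cofitness pairs
#'
#' @param cof result of \code{\link{cofitness}}
#' @param threshold minimum |r| to report
#' @return data.frame gene_a, gene_b, r, n, pvalue (upper triangle only)
#' @export
cofitnessPairs <- function(cof, threshold = 0.5) {
  r <- cof$r
  keep <- upper.tri(r) & !is.na(r) & abs(r) >= threshold
  idx <- which(keep, arr.ind = TRUE)
  n <- cof$n[keep]
  data.frame(gene_a = rownames(r)[idx[, 1]], gene_b = colnames(r)[idx[, 2]],
             r = r[keep], n = n, pvalue = cofitnessPvalue(r[keep], n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjacent co-operonic gene pairs
#'
#' For every operon with two or more genes, returns the adjacent gene
#' pairs ordered in the direction of transcription (the upstream gene is
#' transcribed first).
#'
#' @param genome gene table
#' @return data.frame with columns up, down, operon_id
#' @export
operonAdjacentPairs <- function(genome) {
  out <- lapply(split(seq_len(nrow(genome)), genome$operon_id), function(ix) {
    if (length(ix) < 2) return(NULL)
    ix <- ix[order(genome$start[ix])]
    if (genome$strand[ix[1]] == "-") ix <- rev(ix)
    data.frame(up = genome$gene_id[ix[-length(ix)]],
               down = genome$gene_id[ix[-1]],
               operon_id = genome$operon_id[ix[1]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(up = character(0), down = character(0),
                      operon_id = character(0))
  rownames(res) <- NULL
  res
}

#' Per-experiment quality control
#'
#' For each condition-level experiment: \code{r_same}, the fitness
#' correlation of identical mutant strains read out in both pools, and
#' \code{r_operon}, the fitness correlation of adjacent co-operonic gene
#' pairs. Either metric is NA (with a warning) when fewer than 3 pairs are
#' available.
#'
#' @param sf a \linkS4class{StrainFitness}
#' @param gs the matching \linkS4class{GeneScores}
#' @param genome gene table
#' @return data.frame experiment_id (condition name), class, r_same,
#'   n_same, r_operon, n_operon
#' @export
experimentQC <- function(sf, gs, genome) {
  fitS <- fitnessMatrix(sf)
  rd <- rowData(sf)
  cdS <- as.data.frame(colData(sf))
  fitG <- fitnessMatrix(gs)
  cdG <- as.data.frame(colData(gs))
  pairs <- operonAdjacentPairs(genome)
  pairs <- pairs[pairs$up %in% rownames(fitG) & pairs$down %in% rownames(fitG), ]

  # strains present in both pools, matched by strain_id
  upRows <- which(rd$pool == "up")
  dnRows <- which(rd$pool == "dn")
  common <- intersect(rd$strain_id[upRows], rd$strain_id[dnRows])
  upIdx <- upRows[match(common, rd$strain_id[upRows])]
  dnIdx <- dnRows[match(common, rd$strain_id[dnRows])]

  res <- lapply(seq_len(nrow(cdG)), function(ci) {
    cname <- cdG$condition_name[ci]
    cols <- which(cdS$condition_name == cname)
    v <- rowMeans(fitS[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    a <- v[upIdx]; b <- v[dnIdx]
    ok <- !is.na(a) & !is.na(b)
    rSame <- if (sum(ok) >= 3) stats::cor(a[ok], b[ok]) else {
      warning(sprintf("experiment %s: too few shared strains for r_same", cname))
      NA_real_
    }
    fa <- fitG[pairs$up, ci]; fb <- fitG[pairs$down, ci]
    okp <- !is.na(fa) & !is.na(fb)
    rOp <- if (sum(okp) >= 3) stats::cor(fa[okp], fb[okp]) else {
      warning(sprintf("experiment %s: too few operon pairs for r_operon", cname))
      NA_real_
    }
    data.frame(experiment_id = cname, class = cdG$class[ci],
               r_same = rSame, n_same = sum(ok),
               r_operon = rOp, n_operon = sum(okp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-sided binomial test of polarity asymmetry
#'
#' Tests whether upstream-only-sick events outnumber downstream-only-sick
#' events beyond chance, against a symmetric 50/50 null.
#'
#' @param upOnly,downOnly event counts
#' @return two-sided binomial P-value
#' @export
polarityTest <- function(upOnly, downOnly) {
  total <- upOnly + downOnly
  if (total == 0) return(1)
  stats::binom.test(upOnly, total, p = 0.5)$p.value
}

#' Polarity event counts across the compendium
#'
#' Over every (adjacent operon pair, experiment) cell, counts the events
#' where only the upstream gene has a strong defect (upstream fitness
#' below \code{sickThresh} while the downstream gene is above
#' \code{healthyThresh}) and the symmetric downstream-only events. Strong
#' polar artifacts would make downstream-only events rare.
#'
#' @param fit gene x experiment fitness matrix (condition experiments)
#' @param pairs ordered pairs from \code{\link{operonAdjacentPairs}}
#' @param sickThresh,healthyThresh fitness thresholds (default -2 / -1)
#' @return list with up_only, down_only, pvalue (two-sided binomial)
#' @export
polarityCounts <- function(fit, pairs, sickThresh = -2, healthyThresh = -1) {
  pairs <- pairs[pairs$up %in% rownames(fit) & pairs$down %in% rownames(fit), ]
  a <- fit[pairs$up, , drop = FALSE]
  b <- fit[pairs$down, , drop = FALSE]
  upOnly <- sum(a < sickThresh & b > healthyThresh, na.rm = TRUE)
  downOnly <- sum(b < sickThresh & a > healthyThresh, na.rm = TRUE)
  list(up_only = upOnly, down_only = downOnly,
       pvalue = polarityTest(upOnly, downOnly))
}

#' Concordance of predicted auxotrophs with fitness
#'
#' Fraction of a predicted auxotroph gene set with fitness at or below
#' \code{cutoff} in a minimal-media experiment versus a rich-media
#' experiment. Predicted genes absent from the matrix are excluded and
#' reported.
#'
#' @param fit gene x experiment fitness matrix
#' @param genes predicted auxotroph gene ids (non-empty)
#' @param minimalExp,richExp column names of the two experiments
#' @param cutoff fitness cutoff (default -2)
#' @return list with fraction_minimal, fraction_rich, n_used, excluded
#' @export
auxotrophConcordance <- function(fit, genes, minimalExp, richExp,
                                 cutoff = -2) {
  if (length(genes) == 0) parameterError("empty predicted gene set")
  if (!all(c(minimalExp, richExp) %in% colnames(fit)))
    validationError("experiments '%s' and/or '%s' absent from the matrix",
                    minimalExp, richExp)
  present <- intersect(genes, rownames(fit))
  excluded <- setdiff(genes, present)
  if (!length(present))
    validationError("none of the predicted genes are in the fitness matrix")
  frac <- function(e) mean(fit[present, e] <= cutoff, na.rm = TRUE)
  list(fraction_minimal = frac(minimalExp), fraction_rich = frac(richExp),
       n_used = length(present), excluded = excluded)
}

#' Per-gene correlation with co-operonic neighbors
#'
#' For each gene with at least one adjacent co-operonic neighbor, the mean
#' Pearson correlation (across experiments, pairwise-complete) between the
#' gene's fitness vector and each neighbor's.
#'
#' @param fit gene x experiment fitness matrix
#' @param genome gene table
#' @param minExperiments minimum shared experiments per pair
#' @return named numeric vector (genes without neighbors absent)
#' @export
operonNeighborCorrelation <- function(fit, genome, minExperiments = 10L) {
  pairs <- operonAdjacentPairs(genome)
  pairs <- pairs[pairs$up %in% rownames(fit) & pairs$down %in% rownames(fit), ]
  if (!nrow(pairs)) return(stats::setNames(numeric(0), character(0)))
  rs <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- fit[pairs$up[i], ]; b <- fit[pairs$down[i], ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < minExperiments) return(NA_real_)
    suppressWarnings(stats::cor(a[ok], b[ok]))
  }, numeric(1))
  long <- data.frame(gene = c(pairs$up, pairs$down), r = c(rs, rs))
  long <- long[!is.na(long$r), ]
  tapply(long$r, long$gene, mean)
}

#' Operon cofitness profiled by phenotype significance
#'
#' Splits genes into equal-count bins by their chi-squared phenotype
#' statistic and summarizes, per bin, the distribution of each gene's
#' correlation with its co-operonic neighbors. In informative data the bin
#' medians rise with chi-squared rank.
#'
#' @param tests data.frame from \code{\link{phenotypeTest}}
#' @param neighborCor named vector from
#'   \code{\link{operonNeighborCorrelation}}
#' @param nBins number of equal-count bins
#' @return data.frame bin, n, mean_chisq, q1, median_r, q3
#' @export
operonCofitnessBySignificance <- function(tests, neighborCor, nBins = 20L) {
  shared <- intersect(tests$gene_id, names(neighborCor))
  if (length(shared) < nBins)
    parameterError("nBins=%d exceeds the %d genes with operon neighbors",
                   nBins, length(shared))
  chisq <- tests$chisq[match(shared, tests$gene_id)]
  r <- neighborCor[shared]
  rnk <- rank(chisq, ties.method = "first")
  bin <- ceiling(rnk * nBins / length(shared))
  out <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    rb <- r[bin == b]
    q <- stats::quantile(rb, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(bin = b, n = length(rb),
               mean_chisq = mean(chisq[bin == b]),
               q1 = q[1], median_r = q[2], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' Compare relative fitness with relative expression
#'
#' Contrasts two conditions A and B: relative fitness is fitness(A) -
#' fitness(B) per gene; its Pearson correlation with the expression log
#' ratio (A vs B) measures how well transcriptional response predicts
#' mutant phenotype (a perfect correspondence gives r = -1, since genes
#' up-regulated where they matter have negative relative fitness there).
#' Genes are partitioned into sign quadrants, and genes that are sick in
#' the reference condition or measured only by edge insertions are flagged
#' for exclusion from interpretation.
#'
#' @param fit gene x experiment fitness matrix
#' @param condA,condB column names of the two conditions
#' @param expression named vector of gene expression log2 ratios (A vs B)
#' @param sickCutoff genes with fitness(B) below this are flagged
#' @param edgeOnly optional character vector of genes measured only by
#'   edge insertions
#' @return list with relative_fitness (named vector), correlation, n,
#'   quadrants (list of gene id vectors), flagged
#' @export
fitnessExpressionComparison <- function(fit, condA, condB, expression,
                                        sickCutoff = -1, edgeOnly = NULL) {
  if (!all(c(condA, condB) %in% colnames(fit)))
    validationError("conditions '%s'/'%s' absent from the matrix", condA, condB)
  shared <- intersect(rownames(fit), names(expression))
  rel <- fit[shared, condA] - fit[shared, condB]
  ex <- expression[shared]
  ok <- !is.na(rel) & !is.na(ex)
  if (sum(ok) < 10)
    validationError("only %d genes shared between fitness and expression",
                    sum(ok))
  rel <- rel[ok]; ex <- ex[ok]
  genes <- shared[ok]
  quadrants <- list(
    up_more_important = genes[ex > 0 & rel < 0],
    up_less_important = genes[ex > 0 & rel > 0],
    down_more_important = genes[ex < 0 & rel < 0],
    down_less_important = genes[ex < 0 & rel > 0])
  flagged <- genes[!is.na(fit[genes, condB]) & fit[genes, condB] < sickCutoff]
  flagged <- union(flagged, intersect(genes, edgeOnly))
  list(relative_fitness = stats::setNames(rel, genes),
       correlation = stats::cor(rel, ex), n = length(genes),
       quadrants = quadrants, flagged = flagged)
}
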