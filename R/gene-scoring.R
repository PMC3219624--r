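#' Flag good insertions
#'
#' An insertion is "good" when it falls within the central 5--80\% of the
#' gene along the transcribed strand (boundaries inclusive). Insertions
#' with no gene fraction (intergenic) are never good.
#'
#' @param geneFraction numeric vector of relative insertion positions in
#'   [0, 1] (NA allowed)
#' @param window lower/upper bounds of the good window
#' @return logical vector
#' @export
goodInsertions <- function(geneFraction, window = c(0.05, 0.80)) {
  !is.na(geneFraction) & geneFraction >= window[1] & geneFraction <= window[2]
}

#' Moderated t-like statistic
#'
#' T = mu * sqrt(n) / (Psi + s), where mu is the mean of a gene's
#' measurements, n their count, s their sample SD (taken as 0 when n = 1,
#' so a singleton gives T = x / Psi), and Psi a compendium-wide variance
#' floor. The absolute scale of T is immaterial downstream: the empirical
#' null calibration maps it to a standard normal Z.
#'
#' @param mu mean of the measurements
#' @param n number of measurements
#' @param s sample SD of the measurements (NA treated as 0)
#' @param psi variance floor, must be > 0
#' @return numeric vector of t-like statistics
#' @export
moderatedT <- function(mu, n, s, psi) {
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 0)
    calibrationError("'psi' must be a single positive number")
  s <- ifelse(is.na(s) | n < 2, 0, s)
  mu * sqrt(n) / (psi + s)
}

#' Compendium variance floor Psi
#'
#' The median, over all (gene, experiment) cells with two or more
#' measurements, of the sample standard deviation of the gene's
#' measurements. Even-count medians are the midpoint of the two central
#' values.
#'
#' @param s numeric vector or matrix of per-cell sample SDs
#' @param n matching measurement counts
#' @return Psi (scalar)
#' @export
computePsi <- function(s, n) {
  vals <- s[!is.na(s) & n >= 2]
  if (!length(vals))
    calibrationError("no genes with >= 2 measurements; Psi is undefined")
  stats::median(vals)
}

#' Score genes from strain fitness
#'
#' Aggregates strain fitness to gene level per condition (the up- and
#' down-pool hybridizations sharing a condition_name are combined, so a
#' strain present in both pools contributes two measurements). If a gene
#' has one or more good insertions among its measured strains in a
#' condition, only those good insertions are averaged; otherwise all its
#' strains are used. Computes per-cell measurement counts and SDs, the
#' compendium Psi, and the moderated t-like statistic.
#'
#' @param sf a \linkS4class{StrainFitness}
#' @return a \linkS4class{GeneScores} with assays fitness, n, sd, t and
#'   \code{metadata()$psi}
#' @export
scoreGenes <- function(sf) {
  fit <- fitnessMatrix(sf)
  rd <- rowData(sf)
  cd <- as.data.frame(colData(sf))
  gene <- rd$gene_id
  good <- rd$good

  conds <- unique(cd$condition_name[!is.na(cd$condition_name)])
  geneIds <- sort(unique(gene[!is.na(gene) & rd$retained]))
  shape <- function() matrix(NA_real_, length(geneIds), length(conds),
                             dimnames = list(geneIds, conds))
  mMean <- shape(); mN <- shape(); mSd <- shape()

  for (ci in seq_along(conds)) {
    cols <- which(cd$condition_name == conds[ci])
    v <- rowMeans(fit[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    used <- !is.na(v) & !is.na(gene)
    genesWithGood <- unique(gene[used & good])
    sel <- used & (good | !(gene %in% genesWithGood))
    if (!any(sel)) next
    f <- factor(gene[sel], levels = geneIds)
    x <- v[sel]
    n <- as.numeric(rowsum(rep(1, length(x)), f))
    sm <- as.numeric(rowsum(x, f))
    sq <- as.numeric(rowsum(x^2, f))
    mu <- sm / n
    ss <- pmax(sq - n * mu^2, 0)
    sdev <- ifelse(n >= 2, sqrt(ss / (n - 1)), NA_real_)
    present <- n > 0
    mMean[present, ci] <- mu[present]
    mN[present, ci] <- n[present]
    mSd[present, ci] <- sdev[present]
  }

  psiHat <- computePsi(mSd, mN)
  tMat <- moderatedT(mMean, mN, mSd, psiHat)

  condClass <- cd$class[match(conds, cd$condition_name)]
  se <- SummarizedExperiment(
    assays = list(fitness = mMean, n = mN, sd = mSd, t = tMat),
    rowData = DataFrame(gene_id = geneIds, row.names = geneIds),
    colData = DataFrame(condition_name = conds, class = condClass,
                        row.names = conds))
  gs <- new("GeneScores", se)
  metadata(gs)$psi <- psiHat
  gs
}

#' @describeIn scoreGenes compact display
#' @param object a \code{GeneScores}
#' @export
setMethod("show", "GeneScores", function(object) {
  cls <- table(colData(object)$class)
  cat(sprintf("GeneScores: %d genes x %d experiments (%s); Psi = %.4g%s\n",
              nrow(object), ncol(object),
              paste(sprintf("%d %s", cls, names(cls)), collapse = ", "),
              metadata(object)$psi,
              if ("z" %in% names(assays(object))) "; Z calibrated" else ""))
})

# condition-class (non-control) column indices of a GeneScores
conditionColumns <- function(gs) which(colData(gs)$class == "condition")

#' Chi-squared phenotype test
#'
#' Combines a gene's Z scores over all (non-control) condition experiments:
#' X2 = sum(Z^2) with degrees of freedom equal to the number of non-missing
#' Z; the upper-tail chi-squared probability tests consistency with "no
#' phenotype". Genes with no Z at all are excluded.
#'
#' @param gs a calibrated \linkS4class{GeneScores} (with a z assay)
#' @param alpha significance level for the significant flag
#' @return data.frame with gene_id, chisq, df, pvalue, significant
#' @export
phenotypeTest <- function(gs, alpha = 0.001) {
  if (!"z" %in% names(assays(gs)))
    calibrationError("GeneScores has no z assay; run calibrateNull/zTransform first")
  z <- zMatrix(gs)[, conditionColumns(gs), drop = FALSE]
  df <- rowSums(!is.na(z))
  chisq <- rowSums(z^2, na.rm = TRUE)
  keep <- df > 0
  p <- stats::pchisq(chisq[keep], df[keep], lower.tail = FALSE)
  data.frame(gene_id = rownames(z)[keep], chisq = chisq[keep], df = df[keep],
             pvalue = p, significant = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni-corrected one-sided Z threshold
#'
#' The lower-tail Z cutoff for a per-experiment significance level
#' \code{alpha} after Bonferroni correction over \code{nExperiments}
#' experiments: \code{qnorm(alpha / nExperiments)}. With alpha = 0.01 over
#' 195 experiments this is -3.88.
#'
#' @param alpha family significance level in (0, 1)
#' @param nExperiments number of experiments corrected over (>= 1)
#' @return the (negative) Z threshold
#' @export
bonferroniZThreshold <- function(alpha = 0.01, nExperiments) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    parameterError("'alpha' must lie in (0, 1)")
  stopifnotScalarCount(nExperiments, "nExperiments")
  stats::qnorm(alpha / nExperiments)
}

#' Genes with strong fitness patterns
#'
#' The union of (a) genes in the top third (by default) of chi-squared
#' values among all tested genes, ties at the boundary included, and (b)
#' genes with a highly significant defect in at least one condition
#' (minimum Z below the Bonferroni threshold \code{zStar}).
#'
#' @param tests data.frame from \code{\link{phenotypeTest}}
#' @param gs the calibrated \linkS4class{GeneScores}
#' @param zStar lower-tail Z cutoff, e.g. from
#'   \code{\link{bonferroniZThreshold}}
#' @param topFraction fraction of genes taken by chi-squared rank
#' @return character vector of gene ids
#' @export
strongPatternGenes <- function(tests, gs, zStar, topFraction = 1 / 3) {
  k <- ceiling(nrow(tests) * topFraction)
  cutoff <- sort(tests$chisq, decreasing = TRUE)[k]
  topSet <- tests$gene_id[tests$chisq >= cutoff]
  z <- zMatrix(gs)[, conditionColumns(gs), drop = FALSE]
  minZ <- suppressWarnings(apply(z, 1, min, na.rm = TRUE))
  extreme <- rownames(z)[is.finite(minZ) & minZ < zStar]
  sort(union(topSet, intersect(extreme, tests$gene_id)))
}

#' Count significant fitness changes per gene
#'
#' Classifies each (gene, condition) cell as a significant change when
#' |fitness| > 1 and |Z| > 2.5, and tallies per gene the nested defect
#' classes (fitness < -1, < -2, < -3) and the positive class
#' (fitness > 1).
#'
#' @param gs a calibrated \linkS4class{GeneScores}
#' @param zGate |Z| gate for a significant change
#' @return data.frame with gene_id, n_sick1, n_sick2, n_sick3, n_positive
#' @export
countSignificantChanges <- function(gs, zGate = 2.5) {
  cols <- conditionColumns(gs)
  fit <- fitnessMatrix(gs)[, cols, drop = FALSE]
  z <- zMatrix(gs)[, cols, drop = FALSE]
  gate <- !is.na(z) & abs(z) > zGate & !is.na(fit)
  data.frame(
    gene_id = rownames(fit),
    n_sick1 = rowSums(gate & fit < -1),
    n_sick2 = rowSums(gate & fit < -2),
    n_sick3 = rowSums(gate & fit < -3),
    n_positive = rowSums(gate & fit > 1),
    row.names = NULL, stringsAsFactors = FALSE)
}
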