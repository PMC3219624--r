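#' Average replicate probes into tag levels
#'
#' Collapses the probe-level intensity table to one value per (tag,
#' hybridization): the arithmetic mean of the log2 intensities of the
#' replicate probes. Combinations not measured are absent (NA), never zero.
#'
#' @param intensities data.frame with columns experiment_id, tag_id,
#'   probe_index, log2_intensity
#' @return numeric matrix, tags x hybridizations, NA where unmeasured
#' @export
summarizeTags <- function(intensities) {
  tagF <- factor(intensities$tag_id)
  expF <- factor(intensities$experiment_id)
  idx <- (as.integer(expF) - 1L) * nlevels(tagF) + as.integer(tagF)
  sums <- numeric(nlevels(tagF) * nlevels(expF))
  cnts <- numeric(length(sums))
  ok <- !is.na(intensities$log2_intensity)
  sums[sort(unique(idx))] <- rowsum(intensities$log2_intensity[ok], idx[ok])
  cnts[sort(unique(idx))] <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- sums / ifelse(cnts == 0, NA, cnts)
  matrix(out, nrow = nlevels(tagF), ncol = nlevels(expF),
         dimnames = list(levels(tagF), levels(expF)))
}

# Per-tag average start level: mean over the start arrays of the tag's own
# pool (a tag appears only on its pool's arrays, so a plain row mean over
# all start columns is that average).
averageStartLevels <- function(tagLevels, experiments) {
  startCols <- experiments$experiment_id[experiments$class == "start"]
  startCols <- intersect(startCols, colnames(tagLevels))
  if (!length(startCols))
    validationError("no start hybridizations found in the experiment table")
  rowMeans(tagLevels[, startCols, drop = FALSE], na.rm = TRUE)
}

#' Detect strains over array background
#'
#' A strain read-out is detected when its linear-scale start level is at
#' least \code{multiplier} times the pool's background, estimated as the
#' median linear level of the pool's unused tags (tag modules present on
#' the array but not assigned to any strain). The threshold is inclusive.
#'
#' @param tagLevels tag-level matrix from \code{\link{summarizeTags}}
#' @param experiments experiment metadata table
#' @param strains strain table (one row per (strain, pool) read-out)
#' @param multiplier linear detection threshold over background (default 5)
#' @return logical vector aligned with \code{strains} rows, named by tag_id
#' @export
detectStrains <- function(tagLevels, experiments, strains, multiplier = 5) {
  avgStart <- averageStartLevels(tagLevels, experiments)
  detected <- logical(nrow(strains))
  for (p in unique(strains$pool)) {
    startCols <- experiments$experiment_id[
      experiments$class == "start" & experiments$pool == p]
    onPool <- rownames(tagLevels)[
      rowSums(!is.na(tagLevels[, startCols, drop = FALSE])) > 0]
    unused <- setdiff(onPool, strains$tag_id)
    if (!length(unused))
      validationError(
        "pool '%s' has no unused tags; background cannot be estimated", p)
    bg <- stats::median(2^avgStart[unused])
    # inclusive threshold, compared in log space with an epsilon so the
    # exact 5x boundary counts as detected
    thr <- log2(multiplier * bg) - 1e-9
    rows <- which(strains$pool == p)
    detected[rows] <- !is.na(avgStart[strains$tag_id[rows]]) &
      avgStart[strains$tag_id[rows]] >= thr
  }
  names(detected) <- strains$tag_id
  detected
}

#' Remove strains with the lowest start levels
#'
#' Within each pool, removes the \code{floor(fraction * N)} detected
#' read-outs with the lowest average start level. Ties are broken by
#' strain_id (then tag_id) in lexicographic order so the filter is
#' deterministic.
#'
#' @param tagLevels tag-level matrix
#' @param experiments experiment metadata table
#' @param strains strain table
#' @param detected logical vector from \code{\link{detectStrains}}
#' @param fraction fraction of detected read-outs to remove, in [0, 1)
#' @return logical vector aligned with \code{strains} rows: TRUE when the
#'   read-out is detected and survives the filter
#' @export
filterLowStart <- function(tagLevels, experiments, strains, detected,
                           fraction = 0.02) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1)
    parameterError("'fraction' must lie in [0, 1)")
  if (!any(detected))
    validationError("no detected strains to filter")
  avgStart <- averageStartLevels(tagLevels, experiments)
  retained <- detected
  for (p in unique(strains$pool)) {
    rows <- which(strains$pool == p & detected)
    k <- floor(fraction * length(rows))
    if (k == 0) next
    lev <- avgStart[strains$tag_id[rows]]
    ord <- order(lev, strains$strain_id[rows], strains$tag_id[rows])
    retained[rows[ord[seq_len(k)]]] <- FALSE
  }
  retained
}

#' Raw strain fitness as condition/start log ratios
#'
#' For every non-start hybridization, fitness = tag level on the condition
#' array minus the tag's start reference (log2 units). When the experiment
#' table's \code{group} column names a paired start hybridization, that
#' array is the reference; otherwise the average of the pool's start
#' arrays is substituted. Tags missing from an array stay NA.
#'
#' @param tagLevels tag-level matrix
#' @param experiments experiment metadata table
#' @return numeric matrix, tags x non-start hybridizations
#' @export
strainLogRatios <- function(tagLevels, experiments) {
  avgStart <- averageStartLevels(tagLevels, experiments)
  keep <- which(experiments$class != "start" &
                  experiments$experiment_id %in% colnames(tagLevels))
  out <- tagLevels[, experiments$experiment_id[keep], drop = FALSE]
  for (i in seq_along(keep)) {
    grp <- experiments$group[keep[i]]
    ref <- if (!is.null(grp) && !is.na(grp) && grp %in% colnames(tagLevels))
      tagLevels[, grp] else avgStart
    out[, i] <- out[, i] - ref
  }
  out
}

#' Normalize strain fitness by pool, replicon, and plate
#'
#' Per hybridization, subtracts the median fitness within each
#' (pool, replicon) group, then within each 96-well plate group, and
#' repeats the two passes until every group median is zero to within
#' \code{tol} (the passes interact slightly, so a short median-polish
#' iteration is used; the first iteration is exactly the stated order).
#' The result is idempotent and leaves all group medians at zero.
#'
#' @param ratios raw fitness matrix from \code{\link{strainLogRatios}}
#' @param provenance data.frame aligned with rows of \code{ratios} holding
#'   pool, replicon, plate
#' @param repliconPass,platePass switch either pass off (for ablation)
#' @param tol convergence tolerance on group medians
#' @param maxIter maximum polish iterations
#' @return normalized fitness matrix of the same shape
#' @export
normalizeStrainFitness <- function(ratios, provenance, repliconPass = TRUE,
                                   platePass = TRUE, tol = 1e-10,
                                   maxIter = 100L) {
  stopifnot(nrow(provenance) == nrow(ratios))
  gRep <- interaction(provenance$pool, provenance$replicon, drop = TRUE)
  gPlate <- interaction(provenance$pool, provenance$plate, drop = TRUE)
  subtractGroupMedians <- function(v, g) {
    med <- stats::ave(v, g, FUN = function(z)
      if (all(is.na(z))) NA_real_ else stats::median(z, na.rm = TRUE))
    out <- v - med
    out[is.na(med)] <- v[is.na(med)]
    out
  }
  maxGroupMedian <- function(v, g) {
    m <- tapply(v, g, function(z)
      if (all(is.na(z))) 0 else stats::median(z, na.rm = TRUE))
    max(abs(unlist(m)), 0)
  }
  out <- ratios
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    for (it in seq_len(maxIter)) {
      if (repliconPass) v <- subtractGroupMedians(v, gRep)
      if (platePass) v <- subtractGroupMedians(v, gPlate)
      dev <- max(if (repliconPass) maxGroupMedian(v, gRep) else 0,
                 if (platePass) maxGroupMedian(v, gPlate) else 0)
      if (dev < tol) break
    }
    out[, j] <- v
  }
  out
}

#' Compute the normalized strain fitness matrix
#'
#' Pipeline driver for the strain stage: probe averaging, background-based
#' detection, the low-start filter, condition/start log ratios, and
#' pool/replicon/plate median normalization. Undetected or filtered
#' read-outs carry no fitness values (all NA) but remain as rows so the
#' result stays aligned with the strain table.
#'
#' @param intensities probe-level intensity table
#' @param experiments experiment metadata table
#' @param strains strain table
#' @param genome gene table (for replicon lookup; intergenic insertions are
#'   treated as main-chromosome)
#' @param detectMultiplier linear detection threshold over background
#' @param lowStartFraction fraction removed by the low-start filter
#' @param repliconPass,platePass normalization switches
#' @return a \linkS4class{StrainFitness}
#' @export
computeStrainFitness <- function(intensities, experiments, strains, genome,
                                 detectMultiplier = 5, lowStartFraction = 0.02,
                                 repliconPass = TRUE, platePass = TRUE) {
  tagLevels <- summarizeTags(intensities)
  detected <- detectStrains(tagLevels, experiments, strains, detectMultiplier)
  retained <- filterLowStart(tagLevels, experiments, strains, detected,
                             lowStartFraction)

  ratios <- strainLogRatios(tagLevels, experiments)
  ratios <- ratios[match(strains$tag_id, rownames(ratios)), , drop = FALSE]
  rownames(ratios) <- strains$tag_id
  ratios[!retained, ] <- NA_real_

  repliconOf <- stats::setNames(genome$replicon, genome$gene_id)
  prov <- strains
  prov$replicon <- ifelse(is.na(strains$gene_id), "chromosome",
                          unname(repliconOf[strains$gene_id]))
  prov$good <- !is.na(strains$gene_fraction) &
    strains$gene_fraction >= 0.05 & strains$gene_fraction <= 0.80
  prov$detected <- unname(detected)
  prov$retained <- unname(retained)

  norm <- normalizeStrainFitness(ratios, prov, repliconPass, platePass)

  expKeep <- experiments[match(colnames(norm), experiments$experiment_id), ]
  se <- SummarizedExperiment(
    assays = list(fitness = norm),
    rowData = DataFrame(prov, row.names = strains$tag_id),
    colData = DataFrame(expKeep, row.names = expKeep$experiment_id))
  new("StrainFitness", se)
}

#' @describeIn computeStrainFitness compact display
#' @param object a \code{StrainFitness}
#' @export
setMethod("show", "StrainFitness", function(object) {
  rd <- rowData(object)
  cat(sprintf(paste0("StrainFitness: %d (strain, pool) read-outs x %d ",
                     "hybridizations\n  detected %d, retained after ",
                     "low-start filter %d\n"),
              nrow(object), ncol(object), sum(rd$detected), sum(rd$retained)))
})
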