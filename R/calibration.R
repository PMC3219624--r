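#' Calibrate the empirical null from control experiments
#'
#' Collects the t-like statistics observed in the control experiments
#' (independent pool recoveries, no treatment) and builds, separately for
#' genes with 1, 2, 3 or >= 4 measurements, an empirical quantile map that
#' sends a statistic to a standard normal Z. Strata with fewer than
#' \code{minStratum} control values are merged upward into the next
#' stratum (the top stratum merges downward) with a warning, so every
#' measurement count is covered.
#'
#' @param gs a \linkS4class{GeneScores}
#' @param minStratum minimum control values per stratum before merging
#' @return a \linkS4class{NullCalibration}
#' @export
calibrateNull <- function(gs, minStratum = 50L) {
  cd <- colData(gs)
  ctrl <- which(cd$class == "control")
  if (length(ctrl) < 2)
    calibrationError("need >= 2 control experiments, got %d", length(ctrl))
  tMat <- tMatrix(gs)[, ctrl, drop = FALSE]
  nMat <- assay(gs, "n")[, ctrl, drop = FALSE]

  strat <- ifelse(nMat >= 4, 4L, nMat)
  pools <- lapply(1:4, function(k) tMat[!is.na(strat) & strat == k & !is.na(tMat)])
  nms <- c("1", "2", "3", "4plus")
  dest <- 1:4

  for (k in 1:3) {
    if (length(pools[[k]]) > 0 && length(pools[[k]]) < minStratum) {
      warning(sprintf(
        "null stratum n=%s has %d control values (< %d); merged upward",
        nms[k], length(pools[[k]]), minStratum))
      pools[[k + 1]] <- c(pools[[k + 1]], pools[[k]])
      pools[[k]] <- numeric(0)
      dest[dest == k] <- k + 1L
    } else if (length(pools[[k]]) == 0) {
      dest[dest == k] <- k + 1L
    }
  }
  if (length(pools[[4]]) < minStratum) {
    lower <- rev(which(vapply(pools[1:3], length, 1L) >= minStratum))
    if (length(lower)) {
      if (length(pools[[4]]) > 0)
        warning(sprintf(
          "null stratum n>=4 has %d control values (< %d); merged downward",
          length(pools[[4]]), minStratum))
      j <- lower[1]
      pools[[j]] <- c(pools[[j]], pools[[4]])
      pools[[4]] <- numeric(0)
      dest[dest == 4L] <- j
    }
  }
  if (all(vapply(pools, length, 1L) == 0))
    calibrationError("no control t statistics available for calibration")

  strata <- stats::setNames(lapply(1:4, function(k) {
    v <- sort(pools[[dest[k]]])
    ctr <- stats::median(v)
    sc <- stats::mad(v, center = ctr)
    if (!is.finite(sc) || sc <= 0) sc <- max(stats::sd(v), 1e-6)
    list(values = v, center = ctr, scale = sc, source = nms[dest[k]])
  }), nms)

  new("NullCalibration", psi = metadata(gs)$psi, strata = strata,
      nControls = length(ctrl))
}

# Map t statistics to Z within one stratum: qnorm of the mid-rank ECDF
# inside the observed control range; outside it, continue linearly from the
# boundary Z with slope 1/scale so the map stays monotone and finite.
stratumZ <- function(t, stratum) {
  v <- stratum$values
  N <- length(v)
  p <- (seq_len(N) - 0.5) / N
  z <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  if (!any(ok)) return(z)
  tt <- t[ok]
  zz <- numeric(length(tt))
  lo <- tt < v[1]
  hi <- tt > v[N]
  mid <- !lo & !hi
  if (any(mid)) {
    Fm <- if (N == 1) rep(0.5, sum(mid))
          else stats::approx(v, p, xout = tt[mid], ties = mean)$y
    zz[mid] <- stats::qnorm(Fm)
  }
  if (any(lo)) zz[lo] <- stats::qnorm(0.5 / N) + (tt[lo] - v[1]) / stratum$scale
  if (any(hi)) zz[hi] <- stats::qnorm((N - 0.5) / N) + (tt[hi] - v[N]) / stratum$scale
  z[ok] <- zz
  z
}

#' Transform t-like statistics to calibrated Z scores
#'
#' Applies the empirical-null quantile map of the stratum matching each
#' cell's measurement count. On held-out control experiments the resulting
#' Z scores are approximately standard normal; in treatment experiments
#' |Z| measures significance against that null.
#'
#' @param gs a \linkS4class{GeneScores}
#' @param calibration a \linkS4class{NullCalibration}
#' @return \code{gs} with a z assay added and the calibration stored in
#'   \code{metadata()}
#' @export
zTransform <- function(gs, calibration) {
  stopifnot(is(calibration, "NullCalibration"))
  tMat <- tMatrix(gs)
  nMat <- assay(gs, "n")
  z <- tMat
  z[] <- NA_real_
  strat <- ifelse(nMat >= 4, "4plus", as.character(nMat))
  for (nm in names(calibration@strata)) {
    sel <- !is.na(strat) & strat == nm & !is.na(tMat)
    if (any(sel)) z[sel] <- stratumZ(tMat[sel], calibration@strata[[nm]])
  }
  assays(gs)$z <- z
  metadata(gs)$calibration <- calibration
  gs
}

#' Score, calibrate and Z-transform in one call
#'
#' Convenience wrapper: \code{\link{scoreGenes}}, then
#' \code{\link{calibrateNull}} on the control experiments, then
#' \code{\link{zTransform}}.
#'
#' @param sf a \linkS4class{StrainFitness}
#' @param minStratum see \code{\link{calibrateNull}}
#' @return a calibrated \linkS4class{GeneScores}
#' @export
scoreAndCalibrate <- function(sf, minStratum = 50L) {
  gs <- scoreGenes(sf)
  zTransform(gs, calibrateNull(gs, minStratum))
}
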