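#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom SummarizedExperiment assays<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Pooled strain collection
#'
#' Holds the strain-by-pool assignment of a tagged transposon mutant
#' collection: one row per (strain, pool) read-out, each with its own tag,
#' 96-well plate group, and insertion annotation. A strain archived with a
#' TagModule can be present in both pools (its uptag is read in the upPool,
#' its downtag in the dnPool), giving two independent measurements of the
#' same mutant.
#'
#' @slot strains data.frame with columns \code{strain_id}, \code{pool},
#'   \code{tag_id}, \code{plate}, \code{well}, \code{gene_id},
#'   \code{insertion_pos}, \code{gene_fraction}, \code{transposon}.
#' @slot nTagModules integer, tag capacity per pool; tags beyond the
#'   assigned ones remain unused and support background estimation.
#' @slot plateSize integer, strains per plate group (96 in the assay design).
#' @slot undetectableTags character, tag_ids of strains that are truly
#'   undetectable (emitted near background by the simulator).
#' @exportClass PoolSet
setClass("PoolSet",
  representation(strains = "data.frame",
                 nTagModules = "integer",
                 plateSize = "integer",
                 undetectableTags = "character"))

setValidity("PoolSet", function(object) {
  st <- object@strains
  need <- c("strain_id", "pool", "tag_id", "plate", "well", "gene_id",
            "insertion_pos", "gene_fraction", "transposon")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    return(sprintf("strains table lacks columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(st$tag_id))
    return("tag_ids must be unique across pools (tags are pool-prefixed)")
  for (p in unique(st$pool)) {
    if (sum(st$pool == p) > object@nTagModules)
      return(sprintf("pool '%s' exceeds tag capacity %d", p, object@nTagModules))
  }
  TRUE
})

#' True fitness matrix with generation parameters
#'
#' Ground-truth gene-by-condition log2 fitness effects used by the synthetic
#' data generator. Control conditions are all-zero columns by construction.
#'
#' @slot effects numeric matrix, genes x conditions (control columns zero).
#' @slot conditionClass character vector parallel to columns,
#'   \code{"control"} or \code{"condition"}.
#' @slot edgeAttenuation numeric multiplier applied to the effect carried by
#'   insertions outside the central 5--80\% of a gene.
#' @slot operonShare numeric, probability that an effect is copied to operon
#'   mates.
#' @exportClass TrueFitness
setClass("TrueFitness",
  representation(effects = "matrix",
                 conditionClass = "character",
                 edgeAttenuation = "numeric",
                 operonShare = "numeric"))

setValidity("TrueFitness", function(object) {
  if (length(object@conditionClass) != ncol(object@effects))
    return("conditionClass must have one entry per column")
  ctrl <- object@conditionClass == "control"
  if (any(ctrl) && any(object@effects[, ctrl, drop = FALSE] != 0))
    return("control conditions must have all-zero true effects")
  TRUE
})

#' Per-strain fitness container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are (strain, pool)
#' read-outs (named by tag_id) and whose columns are hybridizations. The
#' \code{"fitness"} assay holds normalized log2 condition/start ratios.
#' Row metadata records provenance (pool, replicon, plate group, insertion
#' location, detection and low-start filter status); column metadata is the
#' experiment table.
#'
#' @exportClass StrainFitness
setClass("StrainFitness", contains = "SummarizedExperiment")

#' Gene-level scores container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are genes and whose
#' columns are condition-level experiments (the up- and down-pool
#' hybridizations of one condition combined). Assays: \code{fitness} (mean
#' strain fitness under the good-insertion rule), \code{n} (measurement
#' count), \code{sd} (sample SD, NA when n < 2), \code{t} (moderated t-like
#' statistic) and, after calibration, \code{z}. \code{metadata()} carries
#' the \linkS4class{NullCalibration} used, if any.
#'
#' @exportClass GeneScores
setClass("GeneScores", contains = "SummarizedExperiment")

#' Empirical null calibration
#'
#' Stores the variance floor Psi and, per measurement-count stratum
#' (n = 1, 2, 3, >=4), the sorted t-like statistics observed in control
#' experiments together with a robust center/scale used to extrapolate
#' beyond the observed control range. The Z transform maps a statistic to
#' \code{qnorm(mid-rank ECDF)} inside the control range and continues
#' linearly (anchored at the boundary, slope 1/scale) outside it, so Z stays
#' finite and monotone.
#'
#' @slot psi numeric, median over multi-measurement (gene, experiment) cells
#'   of the sample SD of the gene's measurements.
#' @slot strata named list (\code{"1"}, \code{"2"}, \code{"3"},
#'   \code{"4plus"}); each element has \code{values} (sorted control t),
#'   \code{center}, \code{scale}, and \code{source} (the stratum whose
#'   values are used, after small strata are merged).
#' @slot nControls integer, number of control experiments used.
#' @exportClass NullCalibration
setClass("NullCalibration",
  representation(psi = "numeric",
                 strata = "list",
                 nControls = "integer"))

setValidity("NullCalibration", function(object) {
  if (!is.finite(object@psi) || object@psi <= 0)
    return("psi must be a positive finite number")
  if (!all(c("1", "2", "3", "4plus") %in% names(object@strata)))
    return("strata must cover measurement counts 1, 2, 3 and >=4")
  for (s in object@strata) {
    if (is.unsorted(s$values)) return("stratum values must be sorted")
    if (!is.finite(s$scale) || s$scale <= 0) return("stratum scale must be positive")
  }
  TRUE
})

#' @describeIn PoolSet-class number of (strain, pool) read-outs
#' @param object a \code{PoolSet}
#' @export
setMethod("show", "PoolSet", function(object) {
  st <- object@strains
  cat(sprintf("PoolSet: %d (strain, pool) read-outs, %d unique strains\n",
              nrow(st), length(unique(st$strain_id))))
  for (p in sort(unique(st$pool)))
    cat(sprintf("  pool %s: %d strains over %d plates (capacity %d tags)\n",
                p, sum(st$pool == p), length(unique(st$plate[st$pool == p])),
                object@nTagModules))
  if (length(object@undetectableTags))
    cat(sprintf("  %d read-outs flagged truly undetectable\n",
                length(object@undetectableTags)))
})

setMethod("show", "TrueFitness", function(object) {
  cls <- table(object@conditionClass)
  cat(sprintf("TrueFitness: %d genes x %d columns (%s); %d nonzero effects\n",
              nrow(object@effects), ncol(object@effects),
              paste(sprintf("%d %s", cls, names(cls)), collapse = ", "),
              sum(object@effects != 0)))
})

setMethod("show", "NullCalibration", function(object) {
  cat(sprintf("NullCalibration from %d control experiments; Psi = %.4g\n",
              object@nControls, object@psi))
  for (nm in names(object@strata)) {
    s <- object@strata[[nm]]
    cat(sprintf("  stratum n=%s: %d control values (source %s), center %.3g, scale %.3g\n",
                nm, length(s$values), s$source, s$center, s$scale))
  }
})

#' Accessors for fitness containers
#'
#' \code{fitnessMatrix} returns the fitness assay; \code{strainInfo} and
#' \code{experimentInfo} return row and column metadata as plain data
#' frames; \code{psi} extracts the variance floor from a calibration or a
#' calibrated \code{GeneScores}; \code{zMatrix} and \code{tMatrix} return
#' the calibrated Z and t-like assays.
#'
#' @param x a \code{StrainFitness}, \code{GeneScores} or
#'   \code{NullCalibration} object
#' @return a matrix, data.frame, or numeric scalar as appropriate
#' @name accessors
NULL

#' @rdname accessors
#' @export
fitnessMatrix <- function(x) assay(x, "fitness")

#' @rdname accessors
#' @export
strainInfo <- function(x) as.data.frame(rowData(x))

#' @rdname accessors
#' @export
experimentInfo <- function(x) as.data.frame(colData(x))

#' @rdname accessors
#' @export
tMatrix <- function(x) assay(x, "t")

#' @rdname accessors
#' @export
zMatrix <- function(x) assay(x, "z")

#' @rdname accessors
#' @export
setGeneric("psi", function(x) standardGeneric("psi"))

#' @rdname accessors
#' @export
setMethod("psi", "NullCalibration", function(x) x@psi)

#' @rdname accessors
#' @export
setMethod("psi", "GeneScores", function(x) {
  cal <- metadata(x)$calibration
  if (is.null(cal)) metadata(x)$psi else cal@psi
})

#' @rdname accessors
#' @export
poolStrains <- function(x) {
  stopifnot(is(x, "PoolSet"))
  x@strains
}

#' @rdname accessors
#' @export
trueEffects <- function(x) {
  stopifnot(is(x, "TrueFitness"))
  x@effects
}
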