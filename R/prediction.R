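#' Prepare classifier features from data matrices
#'
#' Centers each experiment (column) on the mean of its observed values,
#' then replaces missing values with zero — so an unmeasured gene sits at
#' the experiment average. Several matrices (e.g. fitness and expression)
#' are concatenated column-wise after alignment on their shared gene set.
#' Experiments with no observed values are dropped with a warning.
#'
#' @param ... one or more gene x experiment matrices with gene rownames
#' @return numeric feature matrix, genes x concatenated experiments
#' @export
prepareFeatures <- function(...) {
  mats <- list(...)
  if (!length(mats)) parameterError("at least one matrix is required")
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) validationError("matrices share no genes")
  pieces <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]][genes, , drop = FALSE]
    empty <- colSums(!is.na(m)) == 0
    if (any(empty)) {
      warning(sprintf("dropping %d all-missing experiment(s) from matrix %d",
                      sum(empty), i))
      m <- m[, !empty, drop = FALSE]
    }
    ctr <- sweep(m, 2, colMeans(m, na.rm = TRUE))
    ctr[is.na(ctr)] <- 0
    colnames(ctr) <- paste0("m", i, ".", colnames(ctr))
    ctr
  })
  do.call(cbind, pieces)
}

#' Filter functional subrole labels
#'
#' Keeps only specific functional assignments: records lacking a subrole,
#' or whose role or subrole contains "unknown" or "other"
#' (case-insensitive substring), are removed. When a gene retains several
#' assignments, the first record is kept so each gene carries one label.
#'
#' @param labels data.frame with columns gene_id, role, subrole
#' @return filtered data.frame, one row per gene
#' @export
filterSubroles <- function(labels) {
  sub <- labels$subrole
  bad <- is.na(sub) | sub == "" | sub == "-" |
    grepl("unknown|other", labels$role, ignore.case = TRUE) |
    grepl("unknown|other", sub, ignore.case = TRUE)
  kept <- labels[!bad, , drop = FALSE]
  kept <- kept[!duplicated(kept$gene_id), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Operon-wise cross-validation folds
#'
#' Partitions operons (never individual genes) into k folds so that a test
#' gene never shares an operon with a training gene. Operons are taken in
#' random order and each is assigned to the currently smallest fold, which
#' bounds the gene-count imbalance by the largest operon size. The same
#' seed always yields the same folds.
#'
#' @param geneIds character vector of gene ids
#' @param operonIds parallel vector of operon ids
#' @param k number of folds (>= 2)
#' @param seed integer random seed
#' @return named integer vector: fold per gene
#' @export
operonwiseFolds <- function(geneIds, operonIds, k = 10L, seed = 1) {
  stopifnotScalarCount(k, "k", min = 2L)
  if (any(is.na(operonIds)))
    validationError("every gene needs an operon_id for operon-wise folds")
  ops <- split(geneIds, operonIds)
  if (length(ops) < k)
    parameterError("only %d operons for k=%d folds", length(ops), k)
  set.seed(seed)
  ord <- sample(length(ops))
  load <- integer(k)
  fold <- integer(length(geneIds))
  names(fold) <- geneIds
  for (i in ord) {
    f <- which.min(load)
    fold[ops[[i]]] <- f
    load[f] <- load[f] + length(ops[[i]])
  }
  fold
}

#' Predict functional subroles with a random forest
#'
#' Trains, for each cross-validation fold, a random forest on the labeled
#' genes outside the fold and predicts the labeled genes inside it; the
#' prediction confidence is the fraction of trees voting for the winning
#' class. Unlabeled genes are predicted by a final forest trained on all
#' labeled genes (their fold is NA). Classes absent from a training split
#' trigger a warning and cannot be predicted in that fold.
#'
#' @param features feature matrix from \code{\link{prepareFeatures}}
#' @param labels named character vector: subrole per labeled gene
#' @param folds fold assignment from \code{\link{operonwiseFolds}}
#'   (must cover all labeled genes)
#' @param nTrees trees per forest
#' @param seed integer random seed
#' @return data.frame gene_id, predicted, confidence, fold, truth, correct
#' @export
predictSubroles <- function(features, labels, folds, nTrees = 500L, seed = 1) {
  labeled <- intersect(names(labels), rownames(features))
  labeled <- intersect(labeled, names(folds))
  if (length(labeled) < 10)
    validationError("only %d labeled genes with features and folds",
                    length(labeled))
  y <- factor(labels[labeled])
  if (nlevels(y) < 2) validationError("need >= 2 subrole classes")
  set.seed(seed)

  rows <- list()
  for (f in sort(unique(folds[labeled]))) {
    test <- labeled[folds[labeled] == f]
    train <- labeled[folds[labeled] != f]
    yTrain <- droplevels(y[match(train, labeled)])
    missing <- setdiff(levels(y), levels(yTrain))
    if (length(missing))
      warning(sprintf("fold %d: class(es) %s absent from training split",
                      f, paste(missing, collapse = ", ")))
    rf <- randomForest::randomForest(features[train, , drop = FALSE], yTrain,
                                     ntree = nTrees)
    votes <- stats::predict(rf, features[test, , drop = FALSE], type = "vote",
                            norm.votes = TRUE)
    pred <- colnames(votes)[max.col(votes, ties.method = "first")]
    conf <- votes[cbind(seq_len(nrow(votes)), max.col(votes, "first"))]
    truth <- as.character(y[match(test, labeled)])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = test, predicted = pred, confidence = conf, fold = f,
      truth = truth, correct = pred == truth, stringsAsFactors = FALSE)
  }

  unlabeled <- setdiff(rownames(features), labeled)
  if (length(unlabeled)) {
    rfAll <- randomForest::randomForest(features[labeled, , drop = FALSE], y,
                                        ntree = nTrees)
    votes <- stats::predict(rfAll, features[unlabeled, , drop = FALSE],
                            type = "vote", norm.votes = TRUE)
    pred <- colnames(votes)[max.col(votes, ties.method = "first")]
    conf <- votes[cbind(seq_len(nrow(votes)), max.col(votes, "first"))]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = unlabeled, predicted = pred, confidence = conf,
      fold = NA_integer_, truth = NA_character_, correct = NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate prediction confidence
#'
#' Compares the confidence of correct versus incorrect cross-validated
#' predictions with a two-sample Kolmogorov-Smirnov test and tabulates
#' precision at confidence thresholds 0.1 ... 0.9. Well-calibrated
#' confidences give higher precision at higher thresholds.
#'
#' @param predictions data.frame from \code{\link{predictSubroles}}
#'   (labeled genes only are used)
#' @return list with D, pvalue, and a calibration data.frame (threshold,
#'   n, precision)
#' @export
evaluateConfidence <- function(predictions) {
  p <- predictions[!is.na(predictions$correct), ]
  if (!any(p$correct) || !any(!p$correct))
    validationError("need at least one correct and one incorrect prediction")
  ks <- suppressWarnings(
    stats::ks.test(p$confidence[p$correct], p$confidence[!p$correct]))
  thresholds <- seq(0.1, 0.9, by = 0.1)
  calib <- do.call(rbind, lapply(thresholds, function(th) {
    sel <- p$confidence >= th
    data.frame(threshold = th, n = sum(sel),
               precision = if (any(sel)) mean(p$correct[sel]) else NA_real_)
  }))
  list(D = unname(ks$statistic), pvalue = ks$p.value, calibration = calib)
}

#' Regulon pair correlations against a shuffled null
#'
#' Computes the (pairwise-complete) Pearson correlation for every
#' non-autoregulatory TF -> target pair over a gene x experiment matrix,
#' and builds a null by shuffling the target assignments across pairs
#' \code{nShuffles} times, re-excluding autoregulatory draws. Pairs whose
#' genes are missing from the matrix are excluded and counted.
#'
#' @param pairs data.frame with columns tf, target
#' @param mat gene x experiment matrix (fitness or expression)
#' @param nShuffles number of target permutations for the null
#' @param seed integer random seed
#' @return list with observed and shuffled correlation vectors,
#'   shift (median observed - median shuffled), n_pairs, n_excluded
#' @export
regulonCorrelation <- function(pairs, mat, nShuffles = 100L, seed = 1) {
  auto <- pairs$tf == pairs$target
  pairs <- pairs[!auto, , drop = FALSE]
  present <- pairs$tf %in% rownames(mat) & pairs$target %in% rownames(mat)
  excluded <- sum(!present) + sum(auto)
  pairs <- pairs[present, , drop = FALSE]
  if (!nrow(pairs)) validationError("no usable regulon pairs")
  pairCor <- function(a, b) {
    vapply(seq_along(a), function(i) {
      x <- mat[a[i], ]; y <- mat[b[i], ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(x[ok], y[ok]))
    }, numeric(1))
  }
  observed <- pairCor(pairs$tf, pairs$target)
  set.seed(seed)
  shuffled <- unlist(lapply(seq_len(nShuffles), function(s) {
    tg <- sample(pairs$target)
    keep <- tg != pairs$tf
    pairCor(pairs$tf[keep], tg[keep])
  }))
  list(observed = observed, pairs = pairs,
       shuffled = shuffled[!is.na(shuffled)],
       shift = stats::median(observed, na.rm = TRUE) -
         stats::median(shuffled, na.rm = TRUE),
       n_pairs = nrow(pairs), n_excluded = excluded)
}
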