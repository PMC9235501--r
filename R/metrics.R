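# CAFA-style evaluation: protein-centric Fmax / Smin / AUPR, class-centric
# ROC AUC, per-annotation-size AUC bins, and the mean information content
# of predictions at the Fmax-optimal threshold.

.checkPredLabels <- function(pred, labels) {
  if (!identical(dim(pred), dim(labels)))
    stop("prediction and label matrices must have identical shape")
  if (!is.null(colnames(pred)) && !is.null(colnames(labels)) &&
      !identical(colnames(pred), colnames(labels)))
    stop("prediction and label matrices must have identical class columns")
}

#' Protein-centric Fmax
#'
#' The CAFA protein-centric measure: at each threshold t the predicted set
#' of a protein is every class scoring at least t (closed under ancestors
#' when a closure map is supplied); precision is averaged over proteins with
#' at least one prediction, recall over all annotated proteins, and Fmax is
#' the maximum over t of their harmonic mean.
#'
#' @param pred score matrix (proteins x classes), values in `[0, 1]`
#' @param labels binary label matrix of identical shape (propagated)
#' @param thresholds threshold grid (default 0 to 1 in steps of 0.01)
#' @param closure optional ancestor map; when given, predicted sets are
#'   closed under ancestors via [propagateScores()] before thresholding
#' @return List with `fmax`, the argmax `threshold`, and the precision /
#'   recall curves over the grid.
#' @export
computeFmax <- function(pred, labels, thresholds = seq(0, 1, by = 0.01),
                        closure = NULL) {
  .checkPredLabels(pred, labels)
  if (!is.null(closure)) pred <- propagateScores(pred, closure)
  trueCount <- rowSums(labels)
  annotated <- trueCount > 0
  if (!any(annotated)) stop("no annotated protein in the evaluation set")
  nAnn <- sum(annotated)
  pr <- rc <- fs <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    B <- pred >= t
    tp <- rowSums(B & (labels > 0))
    predCount <- rowSums(B)
    hasPred <- predCount > 0
    p <- if (any(hasPred)) sum(tp[hasPred] / predCount[hasPred]) / sum(hasPred)
    else NA_real_
    r <- sum((tp / pmax(trueCount, 1))[annotated]) / nAnn
    pr[i] <- p; rc[i] <- r
    fs[i] <- if (!is.na(p) && (p + r) > 0) 2 * p * r / (p + r) else 0
  }
  best <- which.max(fs)
  list(fmax = fs[best], threshold = thresholds[best],
       precision = pr, recall = rc, thresholds = thresholds)
}

#' Protein-centric Smin
#'
#' Minimum over thresholds of the semantic distance
#' `sqrt(ru(t)^2 + mi(t)^2)` where remaining uncertainty `ru` is the mean
#' (over proteins) summed information content of false-negative classes and
#' misinformation `mi` that of false-positive classes.
#'
#' @inheritParams computeFmax
#' @param ic named IC vector covering every class column
#' @return List with `smin`, the argmin `threshold`, and the ru / mi curves.
#' @export
computeSmin <- function(pred, labels, ic, thresholds = seq(0, 1, by = 0.01),
                        closure = NULL) {
  .checkPredLabels(pred, labels)
  if (!is.null(closure)) pred <- propagateScores(pred, closure)
  cls <- colnames(pred)
  miss <- setdiff(cls, names(ic))
  if (length(miss))
    stop("missing information content for class(es): ",
         paste(miss, collapse = ", "))
  w <- ic[cls]
  L <- labels > 0
  ru <- mi <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    B <- pred >= thresholds[i]
    fn <- L & !B
    fp <- B & !L
    ru[i] <- mean(fn %*% w)
    mi[i] <- mean(fp %*% w)
  }
  s <- sqrt(ru^2 + mi^2)
  best <- which.min(s)
  list(smin = s[best], threshold = thresholds[best], ru = ru, mi = mi,
       thresholds = thresholds)
}

#' Area under the pooled precision-recall curve
#'
#' Pools all (protein, class) pairs, ranks them by score and integrates the
#' precision-recall curve step-wise over distinct score thresholds.
#'
#' @inheritParams computeFmax
#' @return Scalar AUPR in `[0, 1]`.
#' @export
computeAUPR <- function(pred, labels) {
  .checkPredLabels(pred, labels)
  s <- as.vector(pred); y <- as.vector(labels) > 0
  npos <- sum(y)
  if (npos == 0) stop("no positive (protein, class) pair")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  cumTP <- cumsum(y)
  n <- length(s)
  last <- c(which(s[-n] != s[-1]), n)   # last index of each tie group
  tp <- cumTP[last]
  prec <- tp / last
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' ROC AUC by the rank-sum formulation
#'
#' Ties receive half credit (average ranks).  Returns `NA` when either class
#' is empty.
#'
#' @param scores numeric vector
#' @param labels binary vector (0/1 or logical)
#' @return AUC in `[0, 1]`, or `NA_real_` for a degenerate split.
#' @export
rocAUC <- function(scores, labels) {
  y <- as.logical(labels > 0)
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Class-centric average AUC
#'
#' Per-class ROC AUC over proteins, macro-averaged over classes with at
#' least one positive and one negative protein.  Degenerate classes are
#' excluded and counted in a message.
#'
#' @inheritParams computeFmax
#' @return List with `auc` (named per-class vector over qualifying classes),
#'   `macro` and `excluded` (count of degenerate classes).
#' @export
classCentricAUC <- function(pred, labels) {
  .checkPredLabels(pred, labels)
  auc <- vapply(seq_len(ncol(pred)), function(j)
    rocAUC(pred[, j], labels[, j]), 0)
  names(auc) <- colnames(pred)
  excluded <- sum(is.na(auc))
  if (excluded > 0)
    message("classCentricAUC: excluded ", excluded,
            " degenerate class(es) (all-positive or all-negative)")
  auc <- auc[!is.na(auc)]
  list(auc = auc, macro = if (length(auc)) mean(auc) else NA_real_,
       excluded = excluded)
}

#' Macro AUC grouped by annotation count
#'
#' Groups classes by their number of annotations in the (propagated)
#' training corpus and reports the mean per-class AUC per bin -- the
#' specificity profile comparing how methods fare on rarely vs frequently
#' annotated classes.
#'
#' @param classAUC named per-class AUC vector (e.g. from
#'   [classCentricAUC()])
#' @param counts named annotation counts per class
#' @param edges bin edges (right-closed); defaults to 0-10-50-100-500-Inf
#' @return data.frame with bin, nClasses, meanAUC (`NA` for empty bins).
#' @export
aucByAnnotationBin <- function(classAUC, counts,
                               edges = c(0, 10, 50, 100, 500, Inf)) {
  cls <- intersect(names(classAUC), names(counts))
  bin <- cut(counts[cls], breaks = edges, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin))
  out$nClasses <- as.vector(table(bin))
  out$meanAUC <- vapply(levels(bin), function(b) {
    v <- classAUC[cls][!is.na(bin) & bin == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  out
}

#' Mean information content of predictions at a threshold
#'
#' The mean IC over all predicted (protein, class) pairs at the given
#' threshold -- typically the Fmax-optimal threshold, measuring how specific
#' a method's best-operating-point predictions are.
#'
#' @param pred score matrix
#' @param ic named IC vector
#' @param threshold score cutoff
#' @return Scalar mean IC.
#' @export
meanICOfPredictions <- function(pred, ic, threshold) {
  miss <- setdiff(colnames(pred), names(ic))
  if (length(miss))
    stop("missing information content for class(es): ",
         paste(miss, collapse = ", "))
  B <- pred >= threshold
  nPred <- colSums(B)
  if (sum(nPred) == 0) stop("no prediction at threshold ", threshold)
  sum(nPred * ic[colnames(pred)]) / sum(nPred)
}

#' Full evaluation report
#'
#' Computes Fmax, Smin (when IC is available), AUPR, class-centric macro
#' AUC, coverage (fraction of proteins with at least one prediction at the
#' Fmax threshold) and the mean IC of predictions at that threshold.
#' Sub-ontology root classes are trivially predicted by propagation and can
#' be excluded via `roots`.
#'
#' @inheritParams computeFmax
#' @param ic optional named IC vector (enables Smin and mean-IC reporting)
#' @param roots class ids excluded from evaluation targets
#' @return List of class `EvaluationResult`.
#' @export
evaluatePredictions <- function(pred, labels, ic = NULL,
                                thresholds = seq(0, 1, by = 0.01),
                                closure = NULL, roots = character()) {
  keep <- setdiff(colnames(pred), roots)
  pred <- pred[, keep, drop = FALSE]
  labels <- labels[, keep, drop = FALSE]
  if (!is.null(closure)) {
    pred <- propagateScores(pred, closure)
    closure <- NULL
  }
  fm <- computeFmax(pred, labels, thresholds)
  ca <- classCentricAUC(pred, labels)
  res <- list(fmax = fm$fmax, fmaxThreshold = fm$threshold,
              aupr = computeAUPR(pred, labels),
              classAUC = ca$auc, macroAUC = ca$macro,
              excludedClasses = ca$excluded,
              coverage = mean(rowSums(pred >= fm$threshold) > 0))
  if (!is.null(ic)) {
    res$smin <- computeSmin(pred, labels, ic, thresholds)$smin
    res$meanIC <- tryCatch(
      meanICOfPredictions(pred, ic, fm$threshold),
      error = function(e) NA_real_)
  }
  class(res) <- "EvaluationResult"
  res
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat("EvaluationResult\n")
  cat(sprintf("  Fmax      %.4f (threshold %.2f, coverage %.2f)\n",
              x$fmax, x$fmaxThreshold, x$coverage))
  if (!is.null(x$smin)) cat(sprintf("  Smin      %.4f\n", x$smin))
  cat(sprintf("  AUPR      %.4f\n", x$aupr))
  cat(sprintf("  macro AUC %.4f over %d classes (%d excluded)\n",
              x$macroAUC, length(x$classAUC), x$excludedClasses))
  if (!is.null(x$meanIC) && !is.na(x$meanIC))
    cat(sprintf("  mean IC of predictions at Fmax threshold: %.4f\n",
                x$meanIC))
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON (full result) and TSV (one row per scalar metric).
#' @param result an `EvaluationResult`
#' @param jsonPath,tsvPath output paths (`NULL` to skip either)
#' @return `result`, invisibly.
#' @export
writeEvaluation <- function(result, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(unclass(result), jsonPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(tsvPath)) {
    scalars <- result[vapply(result, function(v)
      is.numeric(v) && length(v) == 1, TRUE)]
    utils::write.table(
      data.frame(metric = names(scalars), value = unlist(scalars)),
      tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
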