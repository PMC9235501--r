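# Sequence-similarity annotation transfer (normalized-bitscore DiamondScore),
# convex combination of model and similarity scores, and leakage-controlled
# similarity-group dataset splitting.

#' Read an all-vs-all similarity hit table
#'
#' The 12-column tabular output dialect of local aligners: qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param path TSV path (no header)
#' @return data.frame with those columns.
#' @export
readHitTable <- function(path) {
  utils::read.delim(path, header = FALSE, col.names = c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"))
}

#' @rdname readHitTable
#' @param hits hit data.frame
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.filterHits <- function(query, hits, trainIds, evalueMax) {
  h <- hits[hits$qseqid == query & hits$sseqid != query &
              hits$evalue <= evalueMax & hits$sseqid %in% trainIds, ,
            drop = FALSE]
  h
}

#' Annotation transfer by normalized bitscore
#'
#' `S(q, f) = sum_s bitscore(q, s) I(f in T_s) / sum_s bitscore(q, s)` over
#' the query's similar training sequences (e-value filtered, self-hits
#' excluded), where `T_s` is the annotation set of subject s.  A query with
#' no qualifying hit scores 0 for every class and is flagged with the
#' `noHits` attribute.
#'
#' @param query query protein id
#' @param hits hit table (as from [readHitTable()])
#' @param trainAnnotations propagated annotation set of the training
#'   proteins (its names define the training set)
#' @param classId class id f (vectorized)
#' @param evalueMax e-value cutoff (default 0.001)
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
diamondScore <- function(query, hits, trainAnnotations, classId,
                         evalueMax = 0.001) {
  h <- .filterHits(query, hits, names(trainAnnotations), evalueMax)
  if (!nrow(h)) {
    out <- stats::setNames(rep(0, length(classId)), classId)
    attr(out, "noHits") <- TRUE
    return(out)
  }
  bs <- tapply(h$bitscore, h$sseqid, max)     # best hit per subject
  if (all(bs == 0)) stop("all-zero bitscores for query ", query)
  tot <- sum(bs)
  out <- vapply(classId, function(f) {
    has <- vapply(names(bs), function(s) f %in% trainAnnotations[[s]], TRUE)
    sum(bs[has]) / tot
  }, 0)
  names(out) <- classId
  out
}

#' DiamondScore prediction matrix
#'
#' @param queries query protein ids (rows)
#' @param classIds class ids (columns)
#' @inheritParams diamondScore
#' @return Score matrix (queries x classes) in `[0, 1]`.
#' @export
diamondScoreMatrix <- function(queries, hits, trainAnnotations, classIds,
                               evalueMax = 0.001) {
  S <- matrix(0, length(queries), length(classIds),
              dimnames = list(queries, classIds))
  for (q in queries)
    S[q, ] <- diamondScore(q, hits, trainAnnotations, classIds, evalueMax)
  S
}

.alignMatrix <- function(x, template) {
  out <- matrix(0, nrow(template), ncol(template),
                dimnames = dimnames(template))
  rows <- intersect(rownames(x), rownames(out))
  cols <- intersect(colnames(x), colnames(out))
  out[rows, cols] <- x[rows, cols]
  out
}

#' Convex combination of model and similarity scores
#'
#' `alpha * model + (1 - alpha) * diamond`, elementwise.  When `alpha` is
#' `NULL` it is selected on a validation triple (model scores, diamond
#' scores, labels) by maximizing Fmax over a grid.  Missing diamond entries
#' (rows/columns absent from the diamond matrix) are treated as 0.
#'
#' @param model score matrix (proteins x classes)
#' @param diamond DiamondScore matrix
#' @param alpha mixing weight in `[0, 1]`, or `NULL` to tune
#' @param valid optional list(model=, diamond=, labels=) used to tune alpha
#' @param grid candidate alphas (default 0 to 1 in steps of 0.01)
#' @return Combined score matrix; the chosen `alpha` is attached as an
#'   attribute.
#' @export
combineScores <- function(model, diamond, alpha = NULL, valid = NULL,
                          grid = seq(0, 1, by = 0.01)) {
  if (is.null(dimnames(model)))
    stop("model score matrix must carry dimnames")
  diamond <- .alignMatrix(diamond, model)
  if (is.null(alpha)) {
    if (is.null(valid))
      stop("either alpha or a validation triple must be supplied")
    vd <- .alignMatrix(valid$diamond, valid$model)
    f <- vapply(grid, function(a)
      computeFmax(a * valid$model + (1 - a) * vd, valid$labels)$fmax, 0)
    alpha <- grid[which.max(f)]
  }
  stopifnot(alpha >= 0, alpha <= 1)
  out <- alpha * model + (1 - alpha) * diamond
  attr(out, "alpha") <- alpha
  out
}

#' Similarity-group dataset split
#'
#' Proteins whose sequence identity exceeds the threshold are placed in the
#' same group (connected components of the identity graph); whole groups are
#' then shuffled and assigned to train / validation / test by cumulative
#' fraction of groups.  No test protein exceeds the identity threshold with
#' any training protein, the leakage-control property of similarity-aware
#' splitting.  Fractions apply to groups, not proteins, so protein-level
#' fractions can deviate.
#'
#' @param proteins character vector of protein ids
#' @param hits hit table with qseqid, sseqid, pident columns (symmetrized
#'   internally)
#' @param identityThreshold percent identity above which two proteins share
#'   a group (default 50)
#' @param fractions named numeric (train, valid, test), summing to 1
#' @param seed integer seed for the group shuffle
#' @return List with `split` (named factor-like character vector:
#'   protein -> train/valid/test) and `group` (named integer vector).
#' @export
similaritySplit <- function(proteins, hits, identityThreshold = 50,
                            fractions = c(train = 0.81, valid = 0.09,
                                          test = 0.10),
                            seed = 1L) {
  if (!length(proteins)) stop("empty protein set")
  stopifnot(identityThreshold > 0, identityThreshold < 100,
            abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "valid", "test") %in% names(fractions)))
  ed <- hits[hits$pident > identityThreshold &
               hits$qseqid %in% proteins & hits$sseqid %in% proteins &
               hits$qseqid != hits$sseqid, c("qseqid", "sseqid"), drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = proteins))
  comp <- igraph::components(g)
  group <- stats::setNames(as.integer(comp$membership), proteins)

  nGroups <- comp$no
  withr_seed <- function(expr) {          # local RNG so callers stay unaffected
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  ord <- withr_seed(sample.int(nGroups))
  nTrain <- round(fractions["train"] * nGroups)
  nValid <- round(fractions["valid"] * nGroups)
  splitOfGroup <- rep("test", nGroups)
  splitOfGroup[ord[seq_len(nTrain)]] <- "train"
  if (nValid > 0 && nTrain < nGroups)
    splitOfGroup[ord[(nTrain + 1):min(nTrain + nValid, nGroups)]] <- "valid"
  split <- stats::setNames(splitOfGroup[group], proteins)
  list(split = split, group = group)
}
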