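# Desk-scale fixture generator: a toy ontology exercising all four normal
# forms (including definition axioms) and proteins whose binary features
# carry a planted, recoverable feature -> function signal.
#
# Generative model, in brief: leaf classes of a random subclass DAG carry
# disjoint characteristic feature sets; each protein draws a few leaves,
# emits their characteristic features at a high inclusion rate over a low
# background rate, and is annotated with the drawn leaves plus every defined
# class C = D and (R some E) whose genus D and filler E it carries -- so the
# planted definitions are honest and zero-shot recovery of a held-out
# defined class is information-theoretically possible.

#' Synthetic dataset specification
#'
#' @param nClasses total ontology classes (plain hierarchy + defined)
#' @param nDefinitions number of definition (equivalence) axioms
#' @param nRelations number of object relations besides hasFunction
#' @param nExistential number of plain existential subclass axioms
#' @param maxDepth maximum depth of the subclass DAG
#' @param extraParentProb probability of a second parent (DAG-ness)
#' @param nProteins number of proteins
#' @param vocabSize feature vocabulary size V
#' @param featuresPerLeaf characteristic features per leaf class
#' @param inclusionProb probability that a positive protein carries each
#'   characteristic feature of its leaves (set equal to `backgroundRate`
#'   to remove the signal)
#' @param backgroundRate background Bernoulli rate for every feature
#' @param leavesPerProteinMax each protein draws 1..this many leaves
#' @param definitionCooccur probability that a protein carrying the filler
#'   leaf of a definition also draws a leaf under its genus -- compound
#'   regulator-style classes co-occur with their genus in real corpora,
#'   and this gives the planted defined classes realistic support
#' @param seed integer seed fixing every draw
#' @return A list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nClasses = 60L, nDefinitions = 8L,
                          nRelations = 2L, nExistential = 6L,
                          maxDepth = 4L, extraParentProb = 0.1,
                          nProteins = 300L, vocabSize = 200L,
                          featuresPerLeaf = 4L, inclusionProb = 0.9,
                          backgroundRate = 0.05,
                          leavesPerProteinMax = 3L,
                          definitionCooccur = 0.7, seed = 1L) {
  spec <- list(nClasses = as.integer(nClasses),
               nDefinitions = as.integer(nDefinitions),
               nRelations = as.integer(nRelations),
               nExistential = as.integer(nExistential),
               maxDepth = as.integer(maxDepth),
               extraParentProb = extraParentProb,
               nProteins = as.integer(nProteins),
               vocabSize = as.integer(vocabSize),
               featuresPerLeaf = as.integer(featuresPerLeaf),
               inclusionProb = inclusionProb,
               backgroundRate = backgroundRate,
               leavesPerProteinMax = as.integer(leavesPerProteinMax),
               definitionCooccur = definitionCooccur,
               seed = as.integer(seed))
  if (spec$nDefinitions >= spec$nClasses)
    stop("nDefinitions must be smaller than nClasses")
  if (spec$nClasses - spec$nDefinitions < 5)
    stop("infeasible spec: fewer than 5 plain hierarchy classes")
  stopifnot(spec$inclusionProb >= 0, spec$inclusionProb <= 1,
            spec$backgroundRate >= 0, spec$backgroundRate <= 1,
            spec$nProteins > 0)
  class(spec) <- "syntheticSpec"
  spec
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the toy ontology
#'
#' A rooted random subclass DAG over the plain classes, a few existential
#' subclass axioms, and `nDefinitions` equivalence axioms
#' `C = D and (R some E)` whose genus D is an internal class and whose
#' filler E is a leaf outside D's subtree -- guaranteeing non-empty NF1-NF4
#' lists after normalization.  Deterministic in `spec$seed`.
#'
#' @param spec a [syntheticSpec()]
#' @return An [Ontology-class].
#' @export
generateOntology <- function(spec) .withSeed(spec$seed, {
  nPlain <- spec$nClasses - spec$nDefinitions
  plain <- sprintf("SYN:%07d", seq_len(nPlain))
  depth <- integer(nPlain); depth[1] <- 0L
  ax <- list()
  addAx <- function(form, c, d, r = NA_character_, e = NA_character_)
    ax[[length(ax) + 1L]] <<- data.frame(form = form, c = c, d = d,
                                         r = r, e = e)
  for (i in 2:nPlain) {
    eligible <- which(depth[seq_len(i - 1)] < spec$maxDepth)
    p <- eligible[sample.int(length(eligible), 1)]
    depth[i] <- depth[p] + 1L
    addAx("subclass", plain[i], plain[p])
    if (stats::runif(1) < spec$extraParentProb && i > 2) {
      q <- sample.int(i - 1, 1)
      if (q != p) addAx("subclass", plain[i], plain[q])
    }
  }
  rels <- if (spec$nRelations > 0) sprintf("REL:%07d", seq_len(spec$nRelations))
  else character()

  isParent <- unique(unlist(lapply(ax, function(a) a$d)))
  leaves <- setdiff(plain, isParent)
  internal <- intersect(plain[-1], isParent)
  if (!length(internal)) internal <- plain[1]

  for (j in seq_len(spec$nExistential)) {
    cd <- sample(plain[-1], 2)
    addAx("existential_subclass", cd[1], cd[2], r = sample(rels, 1))
  }

  # descendant sets for filler placement
  parentsOf <- lapply(stats::setNames(plain, plain), function(x) character())
  for (a in ax) if (a$form == "subclass")
    parentsOf[[a$c]] <- c(parentsOf[[a$c]], a$d)
  ancestorsOf <- function(x) {
    seen <- character(); queue <- x
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (p in parentsOf[[q]]) if (!p %in% seen) {
        seen <- c(seen, p); queue <- c(queue, p)
      }
    }
    seen
  }

  leavesUnder <- lapply(stats::setNames(internal, internal), function(D)
    leaves[vapply(leaves, function(l) D %in% ancestorsOf(l), TRUE)])
  genusPool <- internal[lengths(leavesUnder) >= 2]
  if (!length(genusPool)) genusPool <- internal

  defined <- sprintf("SYND:%07d", seq_len(spec$nDefinitions))
  for (j in seq_len(spec$nDefinitions)) {
    D <- genusPool[sample.int(length(genusPool), 1)]
    outside <- setdiff(leaves, leavesUnder[[D]])
    if (!length(outside)) outside <- leaves
    E <- outside[sample.int(length(outside), 1)]
    R <- sample(rels, 1)
    addAx("intersection_equivalence", defined[j], D, r = R, e = E)
  }
  axioms <- do.call(rbind, ax)
  axioms <- axioms[axioms$form != "subclass" |
                     !duplicated(paste(axioms$form, axioms$c, axioms$d)), ,
                   drop = FALSE]
  classes <- data.frame(
    id = c(plain, defined),
    name = c(sprintf("synthetic class %d", seq_len(nPlain)),
             sprintf("synthetic defined class %d",
                     seq_len(spec$nDefinitions))),
    namespace = "synthetic",
    obsolete = FALSE)
  Ontology(classes,
           relations = data.frame(id = rels, name = paste("relation", rels)),
           axioms = axioms)
})

.syntheticLeaves <- function(ontology) {
  ax <- ontology@axioms
  plain <- grep("^SYN:", ontology@classes$id, value = TRUE)
  setdiff(plain, ax$d[ax$form == "subclass"])
}

.syntheticDefinitions <- function(ontology) {
  ax <- ontology@axioms
  ax[ax$form == "intersection_equivalence", c("c", "d", "r", "e"),
     drop = FALSE]
}

#' Generate proteins with a planted feature-to-function signal
#'
#' See the file-level description of the generative model.  Also emits a
#' synthetic all-vs-all similarity hit table in which proteins sharing leaf
#' classes receive high percent identity and bitscore, enabling
#' DiamondScore and split-leakage tests without running an aligner.
#'
#' @param spec a [syntheticSpec()]
#' @param ontology the matching [generateOntology()] result
#' @return List: `features` (binary matrix proteins x V), `direct`
#'   (unpropagated annotation set: drawn leaves plus satisfied defined
#'   classes), `annotations` (propagated), `hits` (12-column hit table),
#'   `leafFeatures` (list leaf -> characteristic feature columns),
#'   `proteinLeaves` (list protein -> drawn leaves).
#' @export
generateProteins <- function(spec, ontology) .withSeed(spec$seed + 1L, {
  if (spec$nProteins <= 0) stop("zero proteins requested")
  leaves <- .syntheticLeaves(ontology)
  defs <- .syntheticDefinitions(ontology)
  nf <- normalizeAxioms(ontology)
  closure <- subclassClosure(nf, classes = classIds(ontology))

  V <- spec$vocabSize
  featNames <- sprintf("F%04d", seq_len(V))
  need <- length(leaves) * spec$featuresPerLeaf
  pool <- if (need <= V) sample.int(V, need)
  else ((seq_len(need) - 1L) %% V) + 1L      # overlap when vocabulary is tight
  leafFeatures <- split(pool, rep(seq_along(leaves),
                                  each = spec$featuresPerLeaf))
  names(leafFeatures) <- leaves

  prot <- sprintf("SYNP:%05d", seq_len(spec$nProteins))
  X <- matrix(0L, spec$nProteins, V, dimnames = list(prot, featNames))
  proteinLeaves <- vector("list", spec$nProteins)
  names(proteinLeaves) <- prot
  direct <- vector("list", spec$nProteins)
  names(direct) <- prot

  leavesUnder <- lapply(stats::setNames(unique(defs$d), unique(defs$d)),
                        function(D) leaves[vapply(leaves, function(l)
                          D %in% closure[[l]], TRUE)])
  for (i in seq_len(spec$nProteins)) {
    k <- sample.int(spec$leavesPerProteinMax, 1)
    ls <- sample(leaves, k)
    # genus/filler co-occurrence of the planted compound classes
    for (j in seq_len(nrow(defs))) {
      cand <- leavesUnder[[defs$d[j]]]
      if (defs$e[j] %in% ls && !any(cand %in% ls) && length(cand) &&
          stats::runif(1) < spec$definitionCooccur)
        ls <- c(ls, cand[sample.int(length(cand), 1)])
    }
    proteinLeaves[[i]] <- ls
    x <- stats::rbinom(V, 1, spec$backgroundRate)
    for (l in ls) {
      f <- leafFeatures[[l]]
      x[f] <- pmax(x[f], stats::rbinom(length(f), 1, spec$inclusionProb))
    }
    X[i, ] <- x
    anc <- unique(unlist(closure[ls], use.names = FALSE))
    hasDef <- defs$c[defs$d %in% anc & defs$e %in% anc]
    direct[[i]] <- c(ls, hasDef)
  }
  directSet <- annotationSet(direct, propagated = FALSE)
  annotations <- propagateAnnotations(directSet, closure)

  # similarity hits: high identity within leaf-sharing pairs
  hi <- list()
  byLeaf <- lapply(stats::setNames(leaves, leaves), function(l)
    prot[vapply(proteinLeaves, function(v) l %in% v, TRUE)])
  pairKey <- character()
  for (l in leaves) {
    ps <- byLeaf[[l]]
    if (length(ps) < 2) next
    cmb <- utils::combn(ps, 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j])
      if (key %in% pairKey) next
      pairKey <- c(pairKey, key)
      la <- proteinLeaves[[cmb[1, j]]]; lb <- proteinLeaves[[cmb[2, j]]]
      ov <- length(intersect(la, lb)) / length(union(la, lb))
      same <- setequal(la, lb)
      # ortholog-style: only proteins with identical leaf profiles exceed
      # the 50% identity grouping threshold; partial overlap stays below it
      hi[[length(hi) + 1L]] <- data.frame(
        q = cmb[1, j], s = cmb[2, j],
        pident = if (same) stats::runif(1, 80, 95)
                 else stats::runif(1, 30, 48),
        bitscore = 50 + 350 * ov,
        evalue = 1e-10)
    }
  }
  nLow <- spec$nProteins
  lowQ <- sample(prot, nLow, replace = TRUE)
  lowS <- sample(prot, nLow, replace = TRUE)
  keep <- lowQ != lowS
  lo <- data.frame(q = lowQ[keep], s = lowS[keep],
                   pident = stats::runif(sum(keep), 10, 40),
                   bitscore = stats::runif(sum(keep), 20, 40),
                   evalue = 10^stats::runif(sum(keep), -6, -3))
  hh <- rbind(do.call(rbind, hi), lo)
  mkHits <- function(q, s, pident, bitscore, evalue) data.frame(
    qseqid = q, sseqid = s, pident = round(pident, 1),
    length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, evalue = evalue,
    bitscore = round(bitscore, 1))
  hits <- rbind(mkHits(hh$q, hh$s, hh$pident, hh$bitscore, hh$evalue),
                mkHits(hh$s, hh$q, hh$pident, hh$bitscore, hh$evalue))
  rownames(hits) <- NULL

  list(features = X, direct = directSet, annotations = annotations,
       hits = hits, leafFeatures = leafFeatures,
       proteinLeaves = proteinLeaves)
})

#' Write a complete synthetic dataset to disk
#'
#' Emits the exact file formats the rest of the package consumes: OBO
#' ontology, annotation TSV (direct annotations, evidence code EXP),
#' feature TSV (long format protein_id, feature_id) and the 12-column hit
#' table.
#'
#' @param spec a [syntheticSpec()]
#' @param outdir output directory (created)
#' @return Named list of file paths plus the in-memory dataset, invisibly.
#' @export
simulateDataset <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ont <- generateOntology(spec)
  data <- generateProteins(spec, ont)
  paths <- list(
    obo = file.path(outdir, "ontology.obo"),
    annotations = file.path(outdir, "annotations.tsv"),
    features = file.path(outdir, "features.tsv"),
    hits = file.path(outdir, "hits.tsv"))
  writeOBO(ont, paths$obo)
  writeAnnotations(data$direct, paths$annotations, evidence = "EXP")
  writeFeatureTable(data$features, paths$features)
  writeHitTable(data$hits, paths$hits)
  invisible(c(paths, list(ontology = ont, data = data)))
}

#' Read / write the long-format protein feature table
#'
#' Two tab-separated columns, protein_id and feature_id; [readFeatureTable()]
#' reconstructs the binary matrix (optionally against a fixed vocabulary so
#' column order is reproducible).
#'
#' @param features binary matrix (proteins x features)
#' @param path TSV path
#' @param vocab optional feature vocabulary (column order) for reading
#' @return `path` (write) or the binary matrix (read).
#' @export
writeFeatureTable <- function(features, path) {
  idx <- which(features > 0, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(features)[idx[, 1]],
                   feature_id = colnames(features)[idx[, 2]])
  df <- df[order(df$protein_id, df$feature_id, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path, vocab = NULL) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("protein_id", "feature_id"),
                          colClasses = "character")
  if (is.null(vocab)) vocab <- sort(unique(df$feature_id), method = "radix")
  prot <- sort(unique(df$protein_id), method = "radix")
  X <- matrix(0L, length(prot), length(vocab),
              dimnames = list(prot, vocab))
  X[cbind(match(df$protein_id, prot), match(df$feature_id, vocab))] <- 1L
  X
}
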