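# The EL n-ball geometry: class balls, relation translations, the four
# normal-form hinge losses and the protein -> class prediction score.
# Losses are implemented once with optional analytic gradients; the trainer
# consumes the gradients, the exported functions the forward values.

#' Construct an embedding space
#'
#' @param centers numeric matrix, one row per class, rownames = class ids
#' @param radii named non-negative numeric vector (actual radii; stored via
#'   the inverse softplus so that [classRadii()] reproduces them)
#' @param relations numeric matrix, one row per relation.  A zero
#'   `hasFunction` row is added when absent.
#' @param gamma hinge margin (default 0.1)
#' @return An [EmbeddingSpace-class].
#' @export
embeddingSpace <- function(centers, radii, relations = NULL, gamma = 0.1) {
  centers <- as.matrix(centers)
  if (is.null(rownames(centers))) stop("centers must have class-id rownames")
  if (is.null(names(radii))) names(radii) <- rownames(centers)
  if (any(radii < 0)) stop("radii must be non-negative")
  if (is.null(relations)) {
    relations <- matrix(0, 1, ncol(centers),
                        dimnames = list("hasFunction", NULL))
  } else {
    relations <- as.matrix(relations)
    if (!"hasFunction" %in% rownames(relations))
      relations <- rbind(relations,
                         hasFunction = numeric(ncol(relations)))
  }
  new("EmbeddingSpace", dim = ncol(centers), centers = centers,
      radiiRaw = softplusInv(pmax(radii, 1e-12)),
      relations = relations, gamma = gamma)
}

#' Inverse softplus
#'
#' `log(exp(y) - 1)` for `y > 0`; maps an actual radius to the unconstrained
#' value stored in the space.
#' @param y positive numeric
#' @export
softplusInv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-300))))

#' Randomly initialized embedding space for a normalized axiom set
#'
#' Centers and relation vectors are drawn i.i.d. uniform on
#' `[-sqrt(3/n), sqrt(3/n)]` (unit-variance-scaled) and unconstrained radii
#' start at `softplusInv(initRadius)`.  Uses the current RNG state, so seed
#' control lives with the caller.
#'
#' @param nf a [NormalizedAxioms-class] (all mentioned classes, including
#'   fresh ones, are embedded)
#' @param relations character vector of relation ids ("hasFunction" is added)
#' @param n embedding dimension (default 1024)
#' @param gamma hinge margin
#' @param classes optional extra class ids to embed
#' @param initRadius initial actual radius for every class
#' @return An [EmbeddingSpace-class].
#' @export
initEmbeddingSpace <- function(nf, relations = character(), n = 1024L,
                               gamma = 0.1, classes = NULL,
                               initRadius = 0.1) {
  ids <- unique(c(normalizedClassIds(nf), classes))
  rels <- unique(c(relations, "hasFunction",
                   nf@nf3$r, nf@nf4$r))
  lim <- sqrt(3 / n)
  centers <- matrix(stats::runif(length(ids) * n, -lim, lim),
                    nrow = length(ids), dimnames = list(ids, NULL))
  relmat <- matrix(stats::runif(length(rels) * n, -lim, lim),
                   nrow = length(rels), dimnames = list(rels, NULL))
  embeddingSpace(centers, stats::setNames(rep(initRadius, length(ids)), ids),
                 relmat, gamma = gamma)
}

# --- internal loss kernels ----------------------------------------------

.rowNorm <- function(M) sqrt(rowSums(M * M))

.accumRows <- function(acc, idx, contrib) {
  # acc: matrix accumulating gradients; idx: rownames for each contrib row
  if (!nrow(contrib)) return(acc)
  s <- rowsum(contrib, group = idx)
  acc[rownames(s), ] <- acc[rownames(s), , drop = FALSE] + s
  acc
}

.accumVec <- function(acc, idx, contrib) {
  if (!length(contrib)) return(acc)
  s <- rowsum(contrib, group = idx)
  acc[rownames(s)] <- acc[rownames(s)] + s[, 1]
  acc
}

.checkEmbedded <- function(centers, ids) {
  miss <- setdiff(ids, rownames(centers))
  if (length(miss))
    stop("class id(s) not embedded: ", paste(miss, collapse = ", "))
}

# Each kernel returns list(loss, dC, dR, dRel) where dC/dRel are gradient
# matrices aligned with `centers`/`relVecs` and dR is the gradient w.r.t.
# the *actual* radii (softplus chain is applied by the caller).
.nf1Kernel <- function(centers, radii, df, gamma, grad = FALSE) {
  k <- nrow(df)
  zero <- list(loss = 0,
               dC = if (grad) centers * 0, dR = if (grad) radii * 0,
               dRel = NULL)
  if (!k) return(zero)
  .checkEmbedded(centers, c(df$c, df$d))
  diff <- centers[df$c, , drop = FALSE] - centers[df$d, , drop = FALSE]
  dist <- .rowNorm(diff)
  slack <- dist + radii[df$c] - radii[df$d] - gamma
  act <- slack > 0
  loss <- sum(pmax(slack, 0)) / k
  if (!grad) return(list(loss = loss))
  dC <- centers * 0; dR <- radii * 0
  if (any(act)) {
    u <- diff[act, , drop = FALSE] / pmax(dist[act], 1e-12) / k
    dC <- .accumRows(dC, df$c[act], u)
    dC <- .accumRows(dC, df$d[act], -u)
    dR <- .accumVec(dR, df$c[act], rep(1 / k, sum(act)))
    dR <- .accumVec(dR, df$d[act], rep(-1 / k, sum(act)))
  }
  list(loss = loss, dC = dC, dR = dR, dRel = NULL)
}

.nf2Kernel <- function(centers, radii, df, gamma, grad = FALSE) {
  k <- nrow(df)
  if (!k) return(list(loss = 0, dC = if (grad) centers * 0,
                      dR = if (grad) radii * 0, dRel = NULL))
  .checkEmbedded(centers, c(df$c, df$d, df$e))
  Cc <- centers[df$c, , drop = FALSE]
  Cd <- centers[df$d, , drop = FALSE]
  Ce <- centers[df$e, , drop = FALSE]
  rc <- radii[df$c]; rd <- radii[df$d]; re <- radii[df$e]
  d_cd <- Cc - Cd; n_cd <- .rowNorm(d_cd)
  d_ce <- Cc - Ce; n_ce <- .rowNorm(d_ce)
  d_de <- Cd - Ce; n_de <- .rowNorm(d_de)
  s1 <- n_cd - rc - rd - gamma
  s2 <- n_ce - rc - gamma
  s3 <- n_de - rc - gamma        # radius of c, as the published formula prints
  s4 <- pmin(rc, rd) - re - gamma
  loss <- sum(pmax(s1, 0) + pmax(s2, 0) + pmax(s3, 0) + pmax(s4, 0)) / k
  if (!grad) return(list(loss = loss))
  dC <- centers * 0; dR <- radii * 0
  addTerm <- function(act, diff, dist, i1, i2) {
    if (!any(act)) return()
    u <- diff[act, , drop = FALSE] / pmax(dist[act], 1e-12) / k
    dC <<- .accumRows(dC, i1[act], u)
    dC <<- .accumRows(dC, i2[act], -u)
  }
  a1 <- s1 > 0; a2 <- s2 > 0; a3 <- s3 > 0; a4 <- s4 > 0
  addTerm(a1, d_cd, n_cd, df$c, df$d)
  addTerm(a2, d_ce, n_ce, df$c, df$e)
  addTerm(a3, d_de, n_de, df$d, df$e)
  if (any(a1)) {
    dR <- .accumVec(dR, df$c[a1], rep(-1 / k, sum(a1)))
    dR <- .accumVec(dR, df$d[a1], rep(-1 / k, sum(a1)))
  }
  if (any(a2)) dR <- .accumVec(dR, df$c[a2], rep(-1 / k, sum(a2)))
  if (any(a3)) dR <- .accumVec(dR, df$c[a3], rep(-1 / k, sum(a3)))
  if (any(a4)) {
    cSmaller <- rc <= rd      # ties differentiate through rc
    iMin <- ifelse(cSmaller, df$c, df$d)
    dR <- .accumVec(dR, iMin[a4], rep(1 / k, sum(a4)))
    dR <- .accumVec(dR, df$e[a4], rep(-1 / k, sum(a4)))
  }
  list(loss = loss, dC = dC, dR = dR, dRel = NULL)
}

.nf34Kernel <- function(centers, radii, relVecs, df, gamma, sign,
                        grad = FALSE) {
  # sign = -1: NF3  max(0, ||c - r - d|| - rc - rd - gamma)
  # sign = +1: NF4  max(0, ||c + r - d|| + rc - rd - gamma)
  k <- nrow(df)
  if (!k) return(list(loss = 0, dC = if (grad) centers * 0,
                      dR = if (grad) radii * 0,
                      dRel = if (grad) relVecs * 0))
  .checkEmbedded(centers, c(df$c, df$d))
  missR <- setdiff(df$r, rownames(relVecs))
  if (length(missR))
    stop("relation id(s) not embedded: ", paste(missR, collapse = ", "))
  diff <- centers[df$c, , drop = FALSE] +
    sign * relVecs[df$r, , drop = FALSE] - centers[df$d, , drop = FALSE]
  dist <- .rowNorm(diff)
  slack <- if (sign < 0) dist - radii[df$c] - radii[df$d] - gamma
  else dist + radii[df$c] - radii[df$d] - gamma
  act <- slack > 0
  loss <- sum(pmax(slack, 0)) / k
  if (!grad) return(list(loss = loss))
  dC <- centers * 0; dR <- radii * 0; dRel <- relVecs * 0
  if (any(act)) {
    u <- diff[act, , drop = FALSE] / pmax(dist[act], 1e-12) / k
    dC <- .accumRows(dC, df$c[act], u)
    dC <- .accumRows(dC, df$d[act], -u)
    dRel <- .accumRows(dRel, df$r[act], sign * u)
    rcSign <- if (sign < 0) -1 else 1
    dR <- .accumVec(dR, df$c[act], rep(rcSign / k, sum(act)))
    dR <- .accumVec(dR, df$d[act], rep(-1 / k, sum(act)))
  }
  list(loss = loss, dC = dC, dR = dR, dRel = dRel)
}

# --- exported forward losses --------------------------------------------

#' Normal-form geometric losses
#'
#' Mean hinge losses over the axioms of each normal form, computed on the
#' n-ball embedding.  Writing `f(x)` for the center of class/relation `x`
#' and `r(x)` for a class radius, with margin `gamma`:
#' \itemize{
#'   \item NF1 (`C SubClassOf D`):
#'     `max(0, ||f(c)-f(d)|| + r(c) - r(d) - gamma)` -- zero when ball c
#'     lies inside ball d with slack gamma.
#'   \item NF2 (`C and D SubClassOf E`): four hinge terms drawing the
#'     intersection of balls c and d into ball e:
#'     `max(0, ||f(c)-f(d)|| - r(c) - r(d) - gamma) +
#'      max(0, ||f(c)-f(e)|| - r(c) - gamma) +
#'      max(0, ||f(d)-f(e)|| - r(c) - gamma) +
#'      max(0, min(r(c), r(d)) - r(e) - gamma)`.
#'   \item NF3 (`C SubClassOf R some D`):
#'     `max(0, ||f(c)-f(r)-f(d)|| - r(c) - r(d) - gamma)`.
#'   \item NF4 (`R some C SubClassOf D`):
#'     `max(0, ||f(c)+f(r)-f(d)|| + r(c) - r(d) - gamma)` -- the
#'     R-translated ball c must lie inside ball d.
#' }
#'
#' @param space an [EmbeddingSpace-class]
#' @param pairs,triples data.frame of axioms (columns as in the
#'   corresponding [NormalizedAxioms-class] slot)
#' @return Non-negative scalar (0 for an empty axiom list).
#' @export
nf1Loss <- function(space, pairs) {
  .nf1Kernel(space@centers, classRadii(space), pairs, space@gamma)$loss
}

#' @rdname nf1Loss
#' @export
nf2Loss <- function(space, triples) {
  .nf2Kernel(space@centers, classRadii(space), triples, space@gamma)$loss
}

#' @rdname nf1Loss
#' @export
nf3Loss <- function(space, triples) {
  .nf34Kernel(space@centers, classRadii(space), space@relations, triples,
              space@gamma, sign = -1)$loss
}

#' @rdname nf1Loss
#' @export
nf4Loss <- function(space, triples) {
  .nf34Kernel(space@centers, classRadii(space), space@relations, triples,
              space@gamma, sign = +1)$loss
}

#' All four normal-form losses on a normalized axiom set
#'
#' @param space an [EmbeddingSpace-class]
#' @param nf a [NormalizedAxioms-class]
#' @return Named list nf1..nf4 plus their sum `total`.
#' @export
nfLosses <- function(space, nf) {
  out <- list(nf1 = nf1Loss(space, nf@nf1), nf2 = nf2Loss(space, nf@nf2),
              nf3 = nf3Loss(space, nf@nf3), nf4 = nf4Loss(space, nf@nf4))
  out$total <- sum(unlist(out))
  out
}

#' Prediction score of a protein for a class
#'
#' The membership score of protein embedding p in the hasFunction-translated
#' ball of class c: `sigmoid(p . (f(hasFunction) + f(c)) + r(c))`.  Strictly
#' inside (0, 1) and monotone increasing in the class radius.
#'
#' @param space an [EmbeddingSpace-class]
#' @param proteinEmbedding numeric vector of length `embeddingDim(space)`,
#'   or a matrix with one protein per row
#' @param classId single class id, or a character vector of class ids
#' @return Matrix of scores (proteins x classes); a scalar when both inputs
#'   are single.
#' @export
predictScore <- function(space, proteinEmbedding, classId) {
  E <- if (is.matrix(proteinEmbedding)) proteinEmbedding
  else matrix(proteinEmbedding, nrow = 1)
  if (ncol(E) != space@dim)
    stop("protein embedding has length ", ncol(E),
         " but the space has dimension ", space@dim)
  .checkEmbedded(space@centers, classId)
  scores <- .scoreKernel(E, space@centers[classId, , drop = FALSE],
                         classRadii(space)[classId],
                         space@relations["hasFunction", ])
  colnames(scores) <- classId
  if (nrow(scores) == 1 && ncol(scores) == 1) unname(scores[1, 1]) else scores
}

.scoreKernel <- function(E, C, r, hF) {
  # logits_ij = E_i . (hF + C_j) + r_j
  logits <- E %*% t(C) + drop(E %*% hF) + rep(r, each = nrow(E))
  sigmoid(logits)
}

#' Logistic sigmoid
#' @param x numeric
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Export / import an embedding space as TSV
#'
#' One row per class (`id`, `radius`, `v1..vn`) and per relation (radius
#' column empty).
#' @param space an [EmbeddingSpace-class]
#' @param path TSV path
#' @param gamma margin to attach on import
#' @return `path` (write) or an [EmbeddingSpace-class] (read).
#' @export
writeEmbeddings <- function(space, path) {
  r <- classRadii(space)
  dfC <- data.frame(id = rownames(space@centers), radius = r[rownames(space@centers)],
                    space@centers, check.names = FALSE)
  dfR <- data.frame(id = rownames(space@relations), radius = NA_real_,
                    space@relations, check.names = FALSE)
  names(dfC) <- names(dfR) <- c("id", "radius", paste0("v", seq_len(space@dim)))
  utils::write.table(rbind(dfC, dfR), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path, gamma = 0.1) {
  df <- utils::read.delim(path, check.names = FALSE)
  isRel <- is.na(df$radius)
  vec <- as.matrix(df[, -(1:2), drop = FALSE])
  colnames(vec) <- NULL
  centers <- vec[!isRel, , drop = FALSE]
  rownames(centers) <- df$id[!isRel]
  rels <- vec[isRel, , drop = FALSE]
  rownames(rels) <- df$id[isRel]
  embeddingSpace(centers, stats::setNames(df$radius[!isRel], df$id[!isRel]),
                 rels, gamma = gamma)
}
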