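# Protein encoder (two residual MLP blocks), joint training of the encoder
# and the class n-ball space against BCE + normal-form losses, and
# supervised / zero-shot prediction.  Backpropagation (including the
# batch-norm backward pass) and Adam are implemented directly in matrix
# code; gradient correctness is checked against finite differences in the
# test suite.

#' Training configuration
#'
#' @param lr Adam learning rate
#' @param batch minibatch size (proteins per step)
#' @param epochs maximum number of epochs
#' @param patience early-stopping patience (epochs without improvement of
#'   the monitored validation quantity)
#' @param dropout dropout rate of the MLP blocks
#' @param seed integer seed fixing every stochastic component of a run
#' @param gamma hinge margin of the normal-form losses
#' @param n embedding dimension (protein embedding and class balls)
#' @param checkpoint `"fmax"` (keep the epoch with best validation Fmax) or
#'   `"loss"` (lowest validation BCE)
#' @param minAnnotated minimum number of training annotations for a class to
#'   enter the supervised loss
#' @param nfBatch axioms sampled per normal form per step (capped at the
#'   list size); the reported per-epoch loss breakdown always uses the full
#'   lists
#' @param bnMomentum running-statistics momentum of the batch-norm layers
#' @return A list of class `trainConfig`.
#' @export
trainConfig <- function(lr = 1e-3, batch = 64L, epochs = 100L,
                        patience = 10L, dropout = 0.5, seed = 1L,
                        gamma = 0.1, n = 1024L,
                        checkpoint = c("fmax", "loss"),
                        minAnnotated = 1L, nfBatch = 256L,
                        bnMomentum = 0.1) {
  checkpoint <- match.arg(checkpoint)
  cfg <- list(lr = lr, batch = as.integer(batch), epochs = as.integer(epochs),
              patience = as.integer(patience), dropout = dropout,
              seed = as.integer(seed), gamma = gamma, n = as.integer(n),
              checkpoint = checkpoint, minAnnotated = as.integer(minAnnotated),
              nfBatch = as.integer(nfBatch), bnMomentum = bnMomentum)
  stopifnot(cfg$lr > 0, cfg$batch > 0, cfg$epochs > 0, cfg$n > 0,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "trainConfig"
  cfg
}

# --- batch normalization ------------------------------------------------

.BN_EPS <- 1e-5

.bnForward <- function(bn, z, training) {
  B <- nrow(z)
  if (training && B > 0) {
    mu <- colMeans(z)
    v <- colMeans(z * z) - mu * mu
    v <- pmax(v, 0)
  } else {
    mu <- bn$mean; v <- bn$var
  }
  istd <- 1 / sqrt(v + .BN_EPS)
  xhat <- (z - rep(mu, each = B)) * rep(istd, each = B)
  out <- xhat * rep(bn$g, each = B) + rep(bn$beta, each = B)
  list(out = out, xhat = xhat, istd = istd, mu = mu, v = v)
}

.bnBackward <- function(bn, cache, dout) {
  B <- nrow(dout)
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(bn$g, each = B)
  mdx <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * xhat)
  dz <- (dxhat - rep(mdx, each = B) - xhat * rep(mdxx, each = B)) *
    rep(cache$istd, each = B)
  list(dz = dz, dg = dg, dbeta = dbeta)
}

.bnUpdate <- function(bn, cache, momentum) {
  bn$mean <- (1 - momentum) * bn$mean + momentum * cache$mu
  bn$var <- (1 - momentum) * bn$var + momentum * cache$v
  bn
}

.bnInit <- function(n) list(g = rep(1, n), beta = rep(0, n),
                            mean = rep(0, n), var = rep(1, n))

# --- MLP block ----------------------------------------------------------

#' One MLP block: affine, ReLU, batch normalization, dropout
#'
#' `MLPBlock(x) = DropOut(BatchNorm(ReLU(W x + b)))`, applied row-wise to a
#' batch.  In evaluation mode dropout is the identity and normalization uses
#' the stored running statistics.
#'
#' @param params list with `W` (out x in), `b`, `bn` (list g, beta, mean,
#'   var) and `dropout` rate
#' @param x input matrix (batch x in) or vector
#' @param training logical; training mode uses batch statistics and samples
#'   a dropout mask from the current RNG
#' @return Output matrix (batch x out); a vector input returns a vector.
#' @export
mlpBlock <- function(params, x, training = FALSE) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(X) != ncol(params$W))
    stop("input has ", ncol(X), " features but W expects ", ncol(params$W))
  a <- X %*% t(params$W) + rep(params$b, each = nrow(X))
  z <- pmax(a, 0)
  out <- .bnForward(params$bn, z, training)$out
  p <- if (is.null(params$dropout)) 0 else params$dropout
  if (training && p > 0) {
    mask <- matrix(stats::runif(length(out)) >= p, nrow(out), ncol(out))
    out <- out * mask / (1 - p)
  }
  if (vec) drop(out) else out
}

.encoderInit <- function(V, n, dropout) {
  lim1 <- sqrt(6 / (V + n)); lim2 <- sqrt(6 / (n + n))
  list(W1 = matrix(stats::runif(n * V, -lim1, lim1), n, V),
       b1 = rep(0, n), bn1 = .bnInit(n),
       W2 = matrix(stats::runif(n * n, -lim2, lim2), n, n),
       b2 = rep(0, n), bn2 = .bnInit(n),
       dropout = dropout)
}

# Forward through both blocks with residual connection; caches for backward.
.encoderForward <- function(enc, X, training) {
  B <- nrow(X)
  p <- enc$dropout
  a1 <- X %*% t(enc$W1) + rep(enc$b1, each = B)
  z1 <- pmax(a1, 0)
  c1 <- .bnForward(enc$bn1, z1, training)
  if (training && p > 0) {
    m1 <- matrix(stats::runif(length(c1$out)) >= p, B, ncol(c1$out))
    h <- c1$out * m1 / (1 - p)
  } else { m1 <- NULL; h <- c1$out }
  a2 <- h %*% t(enc$W2) + rep(enc$b2, each = B)
  z2 <- pmax(a2, 0)
  c2 <- .bnForward(enc$bn2, z2, training)
  if (training && p > 0) {
    m2 <- matrix(stats::runif(length(c2$out)) >= p, B, ncol(c2$out))
    d2 <- c2$out * m2 / (1 - p)
  } else { m2 <- NULL; d2 <- c2$out }
  e <- h + d2
  list(e = e, X = X, a1 = a1, c1 = c1, m1 = m1, h = h,
       a2 = a2, c2 = c2, m2 = m2)
}

.encoderBackward <- function(enc, cache, de) {
  p <- enc$dropout
  dh <- de
  dd2 <- de
  dbn2out <- if (!is.null(cache$m2)) dd2 * cache$m2 / (1 - p) else dd2
  bb2 <- .bnBackward(enc$bn2, cache$c2, dbn2out)
  da2 <- bb2$dz * (cache$a2 > 0)
  dW2 <- crossprod(da2, cache$h)
  db2 <- colSums(da2)
  dh <- dh + da2 %*% enc$W2
  dbn1out <- if (!is.null(cache$m1)) dh * cache$m1 / (1 - p) else dh
  bb1 <- .bnBackward(enc$bn1, cache$c1, dbn1out)
  da1 <- bb1$dz * (cache$a1 > 0)
  dW1 <- crossprod(da1, cache$X)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, g1 = bb1$dg, beta1 = bb1$dbeta,
       W2 = dW2, b2 = db2, g2 = bb2$dg, beta2 = bb2$dbeta)
}

#' Encode proteins into the embedding space
#'
#' `h = MLPBlock1(x); e = h + MLPBlock2(h)` (evaluation mode: running
#' batch-norm statistics, no dropout).
#'
#' @param model a [GOZeroModel-class] (or a bare encoder parameter list)
#' @param x binary feature matrix (proteins x V) or single feature vector
#' @return Embedding matrix (proteins x n) or vector.
#' @export
encodeProtein <- function(model, x) {
  enc <- if (is(model, "GOZeroModel")) model@encoder else model
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(X) != ncol(enc$W1))
    stop("feature vector length ", ncol(X), " != expected ", ncol(enc$W1))
  e <- .encoderForward(enc, X, training = FALSE)$e
  rownames(e) <- rownames(X)
  if (vec) drop(e) else e
}

# --- losses -------------------------------------------------------------

.bceFromLogits <- function(logits, Y) {
  # elementwise stable BCE; mean over all entries
  mean(pmax(logits, 0) - logits * Y + log1p(exp(-abs(logits))))
}

#' Joint loss breakdown
#'
#' Mean binary cross-entropy of the geometric scores against the label
#' matrix, plus the four normal-form losses over the full axiom set,
#' evaluated with frozen statistics (no dropout).  `total` is the sum of all
#' five components.
#'
#' @param model a trained or freshly initialized [GOZeroModel-class]
#' @param x feature matrix (proteins x V)
#' @param y binary label matrix, columns named by class id (defaults to the
#'   model's target classes)
#' @param nf a [NormalizedAxioms-class]
#' @return Named list: bce, nf1, nf2, nf3, nf4, total.
#' @export
jointLoss <- function(model, x, y, nf) {
  if (is.null(colnames(y))) stop("label matrix must have class-id colnames")
  E <- encodeProtein(model, x)
  cls <- colnames(y)
  space <- model@space
  if (model@method == "gozero") {
    .checkEmbedded(space@centers, cls)
    logits <- E %*% t(space@centers[cls, , drop = FALSE]) +
      drop(E %*% space@relations["hasFunction", ]) +
      rep(classRadii(space)[cls], each = nrow(E))
  } else {
    idx <- match(cls, model@targetClasses)
    if (anyNA(idx)) stop("MLP baseline can only score its target classes")
    logits <- E %*% t(model@encoder$Wc[idx, , drop = FALSE]) +
      rep(model@encoder$bc[idx], each = nrow(E))
  }
  out <- list(bce = .bceFromLogits(logits, y))
  # the MLP baseline has no geometric space; its NF components are zero
  nfl <- if (model@method == "gozero") nfLosses(space, nf)
  else list(nf1 = 0, nf2 = 0, nf3 = 0, nf4 = 0)
  out <- c(out, nfl[c("nf1", "nf2", "nf3", "nf4")])
  out$total <- sum(unlist(out))
  if (any(!is.finite(unlist(out))))
    stop("non-finite loss component (training divergence)")
  out
}

# --- Adam ---------------------------------------------------------------

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# --- training -----------------------------------------------------------

.labelMatrix <- function(annotations, proteinIds, classIds) {
  Y <- matrix(0, length(proteinIds), length(classIds),
              dimnames = list(proteinIds, classIds))
  for (p in proteinIds) {
    hit <- intersect(annotations[[p]], classIds)
    if (length(hit)) Y[p, hit] <- 1
  }
  Y
}

#' Build the binary label matrix for a set of proteins and classes
#'
#' @param annotations propagated annotation set
#' @param proteinIds row ids
#' @param classIds column ids
#' @return Binary matrix with dimnames.
#' @export
labelMatrix <- function(annotations, proteinIds, classIds)
  .labelMatrix(annotations, proteinIds, classIds)

.sampleNF <- function(df, size) {
  if (nrow(df) <= size) return(df)
  df[sample.int(nrow(df), size), , drop = FALSE]
}

#' Train the joint geometric model or the MLP baseline
#'
#' Trains the protein encoder jointly with the class n-ball embedding
#' against `BCE + NF1 + NF2 + NF3 + NF4` (method `"gozero"`), or the plain
#' residual-MLP multi-label classifier against BCE alone (method `"mlp"`).
#' Supervised targets are the classes with at least `minAnnotated` training
#' annotations; all classes of the normalized axiom set (including classes
#' with no training annotation and fresh normalization classes) are embedded
#' and constrained by the normal-form losses, which is what makes zero-shot
#' scoring of unseen classes possible.  The run is deterministic given
#' `config$seed`.
#'
#' @param features binary feature matrix (proteins x V), rownames = ids
#' @param annotations propagated annotation set providing the labels
#' @param nf a [NormalizedAxioms-class]
#' @param trainIds,validIds disjoint protein id vectors
#' @param config a [trainConfig()]
#' @param method `"gozero"` or `"mlp"`
#' @param targetClasses optional explicit supervised-target class ids
#' @param verbose print per-epoch progress
#' @return A [GOZeroModel-class] with the best-checkpoint parameters.
#' @export
trainModel <- function(features, annotations, nf, trainIds, validIds,
                       config = trainConfig(), method = c("gozero", "mlp"),
                       targetClasses = NULL, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(!anyDuplicated(c(trainIds, validIds)))
  if (!isPropagated(annotations))
    stop("annotations must be propagated before training")
  set.seed(config$seed)

  fresh <- nf@freshClasses
  if (is.null(targetClasses)) {
    counts <- table(unlist(annotations[trainIds], use.names = FALSE))
    targetClasses <- setdiff(names(counts)[counts >= config$minAnnotated],
                             fresh)
  }
  targetClasses <- sort(targetClasses, method = "radix")
  if (!length(targetClasses)) stop("empty supervised target class set")

  allClasses <- sort(unique(c(normalizedClassIds(nf), targetClasses)),
                     method = "radix")
  rels <- sort(unique(c("hasFunction", nf@nf3$r, nf@nf4$r)),
               method = "radix")
  V <- ncol(features); n <- config$n; K <- length(allClasses)

  enc <- .encoderInit(V, n, config$dropout)
  lim <- sqrt(3 / n)
  params <- list(
    W1 = enc$W1, b1 = enc$b1, g1 = enc$bn1$g, beta1 = enc$bn1$beta,
    W2 = enc$W2, b2 = enc$b2, g2 = enc$bn2$g, beta2 = enc$bn2$beta)
  if (method == "gozero") {
    params$C <- matrix(stats::runif(K * n, -lim, lim), K, n,
                       dimnames = list(allClasses, NULL))
    params$rho <- stats::setNames(rep(softplusInv(0.1), K), allClasses)
    params$Rel <- matrix(stats::runif(length(rels) * n, -lim, lim),
                         length(rels), n, dimnames = list(rels, NULL))
    params$gc <- rep(1, n); params$betac <- rep(0, n)
  } else {
    Kt <- length(targetClasses)
    limc <- sqrt(6 / (n + Kt))
    params$Wc <- matrix(stats::runif(Kt * n, -limc, limc), Kt, n,
                        dimnames = list(targetClasses, NULL))
    params$bc <- stats::setNames(rep(0, Kt), targetClasses)
  }
  bn1 <- enc$bn1; bn2 <- enc$bn2; bnc <- .bnInit(n)
  adam <- .adamInit(params)

  Ytr <- .labelMatrix(annotations, trainIds, targetClasses)
  Yva <- .labelMatrix(annotations, validIds, targetClasses)
  Xtr <- features[trainIds, , drop = FALSE]
  Xva <- features[validIds, , drop = FALSE]
  tIdx <- match(targetClasses, allClasses)
  mom <- config$bnMomentum

  mkEncoder <- function(p) list(
    W1 = p$W1, b1 = p$b1,
    bn1 = list(g = p$g1, beta = p$beta1, mean = bn1$mean, var = bn1$var),
    W2 = p$W2, b2 = p$b2,
    bn2 = list(g = p$g2, beta = p$beta2, mean = bn2$mean, var = bn2$var),
    dropout = config$dropout)

  evalCenters <- function(p) {
    if (method != "gozero") return(NULL)
    istd <- 1 / sqrt(bnc$var + .BN_EPS)
    xhat <- (p$C - rep(bnc$mean, each = K)) * rep(istd, each = K)
    Cb <- xhat * rep(p$gc, each = K) + rep(p$betac, each = K)
    rownames(Cb) <- allClasses
    Cb
  }

  mkModel <- function(p, history) {
    encP <- mkEncoder(p)
    if (method == "gozero") {
      space <- embeddingSpace(evalCenters(p), softplus(p$rho), p$Rel,
                              gamma = config$gamma)
    } else {
      encP$Wc <- p$Wc; encP$bc <- p$bc
      space <- embeddingSpace(
        matrix(0, 1, n, dimnames = list(".none", NULL)),
        c(.none = 0), gamma = config$gamma)
    }
    cfg <- unclass(config)
    cfg$freshClasses <- fresh
    new("GOZeroModel", method = method, encoder = encP, space = space,
        classBN = list(g = p$gc, beta = p$betac,
                       mean = bnc$mean, var = bnc$var),
        targetClasses = targetClasses, config = cfg, history = history)
  }

  validScore <- function(p) {
    mod <- mkModel(p, data.frame())
    S <- predictFunctions(mod, Xva, targetClasses)
    if (config$checkpoint == "fmax") {
      computeFmax(S, Yva)$fmax
    } else {
      eps <- 1e-12
      -(-mean(Yva * log(pmin(pmax(S, eps), 1 - eps)) +
                (1 - Yva) * log(1 - pmin(pmax(S, eps), 1 - eps))))
    }
  }

  nTr <- length(trainIds)
  history <- data.frame()
  best <- list(score = -Inf, params = params, bn1 = bn1, bn2 = bn2, bnc = bnc)
  wait <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nTr)
    starts <- seq(1, nTr, by = config$batch)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch - 1, nTr)]
      B <- length(idx)
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- Ytr[idx, , drop = FALSE]

      encP <- list(W1 = params$W1, b1 = params$b1,
                   bn1 = list(g = params$g1, beta = params$beta1,
                              mean = bn1$mean, var = bn1$var),
                   W2 = params$W2, b2 = params$b2,
                   bn2 = list(g = params$g2, beta = params$beta2,
                              mean = bn2$mean, var = bn2$var),
                   dropout = config$dropout)
      fc <- .encoderForward(encP, Xb, training = TRUE)
      E <- fc$e
      bn1 <- .bnUpdate(bn1, fc$c1, mom)
      bn2 <- .bnUpdate(bn2, fc$c2, mom)

      grads <- list()
      if (method == "gozero") {
        bnC <- list(g = params$gc, beta = params$betac,
                    mean = bnc$mean, var = bnc$var)
        cc <- .bnForward(bnC, params$C, training = TRUE)
        Cb <- cc$out; rownames(Cb) <- allClasses
        bnc <- .bnUpdate(bnc, cc, mom)
        r <- softplus(params$rho)
        hF <- params$Rel["hasFunction", ]

        M <- Cb[tIdx, , drop = FALSE]
        logits <- E %*% t(M) + drop(E %*% hF) + rep(r[tIdx], each = B)
        pHat <- sigmoid(logits)
        dlogits <- (pHat - Yb) / length(logits)

        de <- dlogits %*% M + outer(rowSums(dlogits), hF)
        dCb <- matrix(0, K, n, dimnames = list(allClasses, NULL))
        dCb[tIdx, ] <- crossprod(dlogits, E)
        dr <- stats::setNames(numeric(K), allClasses)
        dr[tIdx] <- colSums(dlogits)
        dRel <- params$Rel * 0
        dRel["hasFunction", ] <- drop(crossprod(E, rowSums(dlogits)))

        nfb <- config$nfBatch
        k1 <- .nf1Kernel(Cb, r, .sampleNF(nf@nf1, nfb), config$gamma, TRUE)
        k2 <- .nf2Kernel(Cb, r, .sampleNF(nf@nf2, nfb), config$gamma, TRUE)
        k3 <- .nf34Kernel(Cb, r, params$Rel, .sampleNF(nf@nf3, nfb),
                          config$gamma, -1, TRUE)
        k4 <- .nf34Kernel(Cb, r, params$Rel, .sampleNF(nf@nf4, nfb),
                          config$gamma, +1, TRUE)
        for (k in list(k1, k2, k3, k4)) {
          dCb <- dCb + k$dC
          dr <- dr + k$dR
          if (!is.null(k$dRel)) dRel <- dRel + k$dRel
        }
        bbC <- .bnBackward(bnC, cc, dCb)
        grads$C <- bbC$dz
        grads$gc <- bbC$dg
        grads$betac <- bbC$dbeta
        grads$rho <- dr * sigmoid(params$rho)
        grads$Rel <- dRel
      } else {
        logits <- E %*% t(params$Wc) + rep(params$bc, each = B)
        pHat <- sigmoid(logits)
        dlogits <- (pHat - Yb) / length(logits)
        de <- dlogits %*% params$Wc
        grads$Wc <- crossprod(dlogits, E)
        grads$bc <- colSums(dlogits)
      }
      gEnc <- .encoderBackward(encP, fc, de)
      grads <- c(grads, gEnc)
      upd <- .adamStep(params, grads, adam, config$lr)
      params <- upd$params; adam <- upd$state
    }

    # full-set loss breakdown in evaluation mode
    mod <- mkModel(params, history)
    lb <- jointLoss(mod, Xtr, Ytr, nf)
    vs <- validScore(params)
    history <- rbind(history, data.frame(
      epoch = epoch, bce = lb$bce, nf1 = lb$nf1, nf2 = lb$nf2,
      nf3 = lb$nf3, nf4 = lb$nf4, total = lb$total, valid = vs))
    if (verbose)
      message(sprintf("epoch %3d  total %.4f  bce %.4f  valid %.4f",
                      epoch, lb$total, lb$bce, vs))
    if (vs > best$score + 1e-9) {
      best <- list(score = vs, params = params, bn1 = bn1, bn2 = bn2,
                   bnc = bnc)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  params <- best$params; bn1 <- best$bn1; bn2 <- best$bn2; bnc <- best$bnc
  mkModel(params, history)
}

#' Predict class scores for proteins
#'
#' Scores every requested class for every protein with the geometric
#' membership score (method `"gozero"`; classes only need to be embedded,
#' not trained -- scoring an untrained class is the zero-shot path) or the
#' sigmoid classification layer (method `"mlp"`; restricted to trained
#' classes).  Optionally applies hierarchical max-propagation so that every
#' ancestor scores at least as high as any of its descendants.
#'
#' @param model a [GOZeroModel-class]
#' @param features binary feature matrix (proteins x V)
#' @param classIds classes to score (default: the model's target classes)
#' @param propagate logical; apply hierarchical max-propagation
#' @param closure ancestor map from [subclassClosure()] (required when
#'   `propagate = TRUE`)
#' @return Score matrix in `[0, 1]` (proteins x classes).
#' @export
predictFunctions <- function(model, features, classIds = NULL,
                             propagate = FALSE, closure = NULL) {
  if (is.null(classIds)) classIds <- model@targetClasses
  fresh <- model@config$freshClasses
  if (length(fresh) && any(classIds %in% fresh))
    stop("fresh normalization classes are not prediction targets")
  E <- encodeProtein(model, features)
  if (model@method == "gozero") {
    space <- model@space
    .checkEmbedded(space@centers, classIds)
    S <- .scoreKernel(E, space@centers[classIds, , drop = FALSE],
                      classRadii(space)[classIds],
                      space@relations["hasFunction", ])
  } else {
    idx <- match(classIds, model@targetClasses)
    if (anyNA(idx))
      stop("MLP baseline cannot score untrained classes: ",
           paste(classIds[is.na(idx)], collapse = ", "))
    S <- sigmoid(E %*% t(model@encoder$Wc[idx, , drop = FALSE]) +
                   rep(model@encoder$bc[idx], each = nrow(E)))
  }
  dimnames(S) <- list(rownames(features), classIds)
  if (propagate) {
    if (is.null(closure)) stop("propagate = TRUE requires a closure map")
    S <- propagateScores(S, closure)
  }
  S
}

#' Hierarchical max-propagation of a score matrix
#'
#' Raises each ancestor's score to the maximum of its descendants' scores,
#' so that predicted sets thresholded at any t are closed under ancestors.
#'
#' @param scores proteins x classes score matrix with class-id colnames
#' @param closure ancestor map from [subclassClosure()]
#' @return Score matrix of the same shape.
#' @export
propagateScores <- function(scores, closure) {
  cls <- colnames(scores)
  out <- scores
  for (cl in cls) {
    anc <- intersect(setdiff(closure[[cl]], cl), cls)
    for (a in anc) out[, a] <- pmax(out[, a], scores[, cl])
  }
  out
}

#' Zero-shot evaluation protocol
#'
#' Removes the annotations of the held-out classes from the *direct*
#' (unpropagated) annotation set, propagates, retrains the geometric model
#' without those classes in the supervised loss, and scores the held-out
#' classes through their axiom-constrained embeddings alone.  Class-centric
#' AUC is reported on the test split (protein and class both unseen) and on
#' all proteins (class unseen, proteins seen during training).  When
#' `trained = TRUE` a paired run trains with the classes included and
#' reports the supervised test AUC for comparison.
#'
#' @param features binary feature matrix (all proteins)
#' @param annotations direct, unpropagated annotation set
#' @param nf a [NormalizedAxioms-class]
#' @param closure ancestor map from [subclassClosure()]
#' @param holdout class ids to hold out
#' @param trainIds,validIds,testIds split of the protein ids
#' @param config a [trainConfig()]
#' @param trained also run the paired supervised model
#' @return data.frame with columns class, positives, aucTest, aucAll and
#'   (when `trained`) aucTrained.
#' @export
zeroShotProtocol <- function(features, annotations, nf, closure, holdout,
                             trainIds, validIds, testIds,
                             config = trainConfig(), trained = TRUE) {
  defined <- nf@nf2$e          # classes with a definition rewrite
  noDef <- setdiff(holdout, defined)
  if (length(noDef))
    warning("held-out class(es) without definition axioms (predictions ",
            "rely on the hierarchy only): ", paste(noDef, collapse = ", "))

  full <- propagateAnnotations(annotations, closure)
  stripped <- annotationSet(lapply(annotations, setdiff, y = holdout),
                            propagated = FALSE)
  strippedProp <- propagateAnnotations(stripped, closure)

  zs <- trainModel(features, strippedProp, nf, trainIds, validIds,
                   config = config, method = "gozero")
  Yall <- .labelMatrix(full, rownames(features), holdout)
  Sall <- predictFunctions(zs, features, holdout)
  Stest <- Sall[testIds, , drop = FALSE]
  Ytest <- Yall[testIds, , drop = FALSE]

  res <- data.frame(class = holdout,
                    positives = colSums(Yall[, holdout, drop = FALSE]),
                    aucTest = vapply(holdout, function(cl)
                      rocAUC(Stest[, cl], Ytest[, cl]), 0),
                    aucAll = vapply(holdout, function(cl)
                      rocAUC(Sall[, cl], Yall[, cl]), 0),
                    row.names = NULL)
  if (trained) {
    sup <- trainModel(features, full, nf, trainIds, validIds,
                      config = config, method = "gozero")
    Ssup <- predictFunctions(sup, features[testIds, , drop = FALSE], holdout)
    res$aucTrained <- vapply(holdout, function(cl)
      rocAUC(Ssup[, cl], Ytest[, cl]), 0)
  }
  res
}
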