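# Independent brute-force oracles.  These deliberately share no code with
# the package implementations they check: closures by exhaustive path
# enumeration, metrics by explicit loops over thresholds and pairs, grouping
# by union-find.

# all ancestors of `id` by exhaustive DFS over every path
oracleAncestors <- function(edges, id) {
  out <- id
  stack <- list(id)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (p in edges$d[edges$c == cur]) {
      out <- c(out, p)
      stack[[length(stack) + 1L]] <- p
    }
  }
  sort(unique(out))
}

oracleFmax <- function(pred, labels, thresholds) {
  best <- 0
  for (t in thresholds) {
    precs <- c(); recs <- c()
    for (i in seq_len(nrow(pred))) {
      P <- which(pred[i, ] >= t)
      T <- which(labels[i, ] > 0)
      if (length(P)) precs <- c(precs, length(intersect(P, T)) / length(P))
      if (length(T)) recs <- c(recs, length(intersect(P, T)) / length(T))
    }
    if (!length(recs)) stop("no annotated protein")
    p <- if (length(precs)) mean(precs) else NA
    r <- mean(recs)
    f <- if (!is.na(p) && p + r > 0) 2 * p * r / (p + r) else 0
    if (f > best) best <- f
  }
  best
}

oracleSmin <- function(pred, labels, ic, thresholds) {
  best <- Inf
  for (t in thresholds) {
    rus <- c(); mis <- c()
    for (i in seq_len(nrow(pred))) {
      P <- colnames(pred)[pred[i, ] >= t]
      T <- colnames(labels)[labels[i, ] > 0]
      rus <- c(rus, sum(ic[setdiff(T, P)]))
      mis <- c(mis, sum(ic[setdiff(P, T)]))
    }
    s <- sqrt(mean(rus)^2 + mean(mis)^2)
    if (s < best) best <- s
  }
  best
}

oracleAUPR <- function(pred, labels) {
  s <- as.vector(pred); y <- as.vector(labels) > 0
  ths <- sort(unique(s), decreasing = TRUE)
  npos <- sum(y)
  prevR <- 0; area <- 0
  for (t in ths) {
    sel <- s >= t
    tp <- sum(sel & y)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + (rec - prevR) * prec
    prevR <- rec
  }
  area
}

# ROC AUC by O(n^2) pair counting with half-credit ties
oracleAUC <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# connected components by union-find
oracleComponents <- function(proteins, edges) {
  parent <- stats::setNames(seq_along(proteins), proteins)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges$qseqid[k]); b <- find(edges$sseqid[k])
    if (a != b) parent[a] <- b
  }
  vapply(proteins, function(p) find(p), 0L, USE.NAMES = TRUE)
}

# --- finite-interpretation checker for the equivalence rewrite -----------
# An interpretation over a domain of size m assigns each class a subset of
# 1..m and each relation a subset of (1..m)^2.  existsR(R, E) is the set
# {x : exists y, (x,y) in R and y in E}.

randomInterp <- function(m, pSet = 0.5, pRel = 0.3) {
  list(
    set = function() which(stats::runif(m) < pSet),
    rel = function() {
      M <- matrix(stats::runif(m * m) < pRel, m, m)
      which(M, arr.ind = TRUE)
    })
}

existsR <- function(R, E) {
  if (!nrow(R) || !length(E)) return(integer())
  sort(unique(R[R[, 2] %in% E, 1]))
}

subsetOf <- function(a, b) all(a %in% b)

# does the interpretation satisfy C = D and (R some E)?
satEquivalence <- function(C, D, R, E)
  setequal(C, intersect(D, existsR(R, E)))

# generic satisfaction of a single normalized axiom row under an
# interpretation (cls: named list id -> subset; rel: named list id -> pairs)
satNormalRow <- function(form, row, cls, rel) {
  switch(form,
    nf1 = subsetOf(cls[[row$c]], cls[[row$d]]),
    nf2 = subsetOf(intersect(cls[[row$c]], cls[[row$d]]), cls[[row$e]]),
    nf3 = subsetOf(cls[[row$c]], existsR(rel[[row$r]], cls[[row$d]])),
    nf4 = subsetOf(existsR(rel[[row$r]], cls[[row$c]]), cls[[row$d]]),
    stop("unknown form ", form))
}

# extract, from a NormalizedAxioms object, the rewrite rows belonging to one
# equivalence C = D and (R some E): the rows mentioning C or its fresh class
rewriteRowsFor <- function(nf, eq) {
  xs <- nf@nf2$d[nf@nf2$e == eq$c]   # fresh class of this equivalence
  rows <- list()
  add <- function(form, df, keep)
    for (i in which(keep)) rows[[length(rows) + 1L]] <<-
      list(form = form, row = df[i, , drop = FALSE])
  add("nf1", nf@nf1, nf@nf1$c == eq$c & nf@nf1$d == eq$d)
  add("nf2", nf@nf2, nf@nf2$e == eq$c)
  add("nf3", nf@nf3, nf@nf3$c == eq$c)
  add("nf4", nf@nf4, nf@nf4$d %in% xs)
  list(rows = rows, fresh = xs)
}

satAllRows <- function(rw, cls, rel)
  all(vapply(rw$rows, function(x) satNormalRow(x$form, x$row, cls, rel), TRUE))

# search for an entailment disagreement between one equivalence and the
# package's normalized rewrite of it, over random finite interpretations
# with domain size <= maxDomain; stops at the first counterexample
checkRewriteSoundness <- function(nf, eq, nSamples = 100, maxDomain = 6) {
  rw <- rewriteRowsFor(nf, eq)
  stopifnot(length(rw$rows) == 4, length(rw$fresh) == 1)
  examined <- 0L
  for (i in seq_len(nSamples)) {
    m <- sample(2:maxDomain, 1)
    gen <- randomInterp(m)
    rel <- stats::setNames(list(gen$rel()), eq$r)
    D <- gen$set(); E <- gen$set()
    pre <- existsR(rel[[eq$r]], E)

    # direction eq -> rewrite: canonical model of the equivalence must
    # satisfy every rewrite row (fresh class = the existential preimage)
    cls <- stats::setNames(list(intersect(D, pre), D, E, pre),
                           c(eq$c, eq$d, eq$e, rw$fresh))
    stopifnot(satEquivalence(cls[[eq$c]], D, rel[[eq$r]], E))
    if (!satAllRows(rw, cls, rel))
      stop("rewrite violated by a model of the equivalence")
    examined <- examined + 1L

    # direction rewrite -> eq: interpretations satisfying every rewrite row
    # must satisfy the equivalence; sample both unbiased and biased toward
    # the premise
    for (v in list(list(X = gen$set(), C = gen$set()),
                   list(X = sort(unique(c(pre, gen$set()))),
                        C = intersect(intersect(D, pre), gen$set())))) {
      cls2 <- stats::setNames(list(v$C, D, E, v$X),
                              c(eq$c, eq$d, eq$e, rw$fresh))
      if (satAllRows(rw, cls2, rel)) {
        examined <- examined + 1L
        if (!satEquivalence(v$C, D, rel[[eq$r]], E))
          stop("equivalence violated by a model of the rewrite")
      }
    }
  }
  examined
}
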