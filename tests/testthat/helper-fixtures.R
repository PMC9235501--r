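# Shared fixtures.  Expensive training runs are memoized so that module
# tests and the acceptance suite reuse the same models.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

cachedSupervisedRun <- function(seed, method = "gozero", ...) {
  cached(paste0("sup-", method, "-", seed),
         supervisedFixtureRun(seed = seed, method = method, ...))
}

cachedNullRun <- function(seed) {
  cached(paste0("null-", seed),
         supervisedFixtureRun(
           seed = seed,
           spec = syntheticSpec(seed = seed, inclusionProb = 0.05)))
}

cachedZeroShotRun <- function(seed) {
  cached(paste0("zs-", seed), zeroShotFixtureRun(seed = seed))
}

# small model shared by several model-module tests (setup must come from
# tinyTrainSetup(seed = 1) so the cache key is stable)
cachedTinyModel <- function(s) {
  cached("tiny-model",
         trainModel(s$data$features, s$data$annotations, s$nf,
                    s$train, s$valid,
                    config = fixtureTrainConfig(1, n = 16L, epochs = 8L,
                                                patience = 8L)))
}

# a small hand-built ontology: chain + branch + one equivalence
#   A5 <- A4 <- A3 <- A2 <- A1(root);  B <- A2;  Z = A2 and (R1 some A4)
tinyOntology <- function() {
  Ontology(
    classes = data.frame(
      id = c("A1", "A2", "A3", "A4", "A5", "B", "Z"),
      name = paste("class", 1:7), namespace = "synthetic",
      obsolete = FALSE),
    relations = data.frame(id = "R1", name = "regulates"),
    axioms = data.frame(
      form = c(rep("subclass", 5), "intersection_equivalence"),
      c = c("A2", "A3", "A4", "A5", "B", "Z"),
      d = c("A1", "A2", "A3", "A4", "A2", "A2"),
      r = c(rep(NA, 5), "R1"),
      e = c(rep(NA, 5), "A4")))
}

# random small score/label instance for metric oracle comparisons; tied
# scores are introduced deliberately
randomMetricInstance <- function(nProt, nCls) {
  S <- matrix(round(stats::runif(nProt * nCls), 2), nProt, nCls,
              dimnames = list(paste0("p", seq_len(nProt)),
                              paste0("c", seq_len(nCls))))
  Y <- matrix(stats::rbinom(nProt * nCls, 1, 0.35), nProt, nCls,
              dimnames = dimnames(S))
  if (all(rowSums(Y) == 0)) Y[1, 1] <- 1
  list(S = S, Y = Y)
}

expect_setequal_df <- function(a, b) {
  keyA <- do.call(paste, c(a, sep = "\r"))
  keyB <- do.call(paste, c(b, sep = "\r"))
  expect_setequal(keyA, keyB)
}
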