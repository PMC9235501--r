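# End-to-end experiments on the synthetic fixture.  These are the package's
# reference workflows: generate data, split by similarity groups, train,
# predict, evaluate -- used by the vignette, the test suite and
# scripts/acceptance.R.

#' Desk-scale training configuration for the synthetic fixture
#'
#' The fixture (60 classes, 300 proteins, vocabulary 200) is far below the
#' scale the full model is sized for, so the embedding dimension, batch size
#' and dropout are reduced accordingly; see the methods vignette for the
#' rationale behind each value.
#'
#' @param seed integer seed
#' @param ... overrides passed to [trainConfig()]
#' @return A [trainConfig()].
#' @export
fixtureTrainConfig <- function(seed = 1L, ...) {
  args <- list(n = 64L, batch = 32L, epochs = 80L, patience = 15L,
               dropout = 0.1, lr = 3e-3, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(trainConfig, args)
}

#' Supervised benchmark run on the synthetic fixture
#'
#' Generates a fixture, splits proteins into similarity groups, trains the
#' requested model and evaluates on the held-out test proteins: per-class
#' test AUC, macro AUC over well-supported classes, and the full
#' protein-centric report.
#'
#' @param seed integer seed (drives the generator, the split and training)
#' @param spec a [syntheticSpec()]; defaults to the study conditions with
#'   this seed
#' @param config a [trainConfig()]
#' @param method `"gozero"` or `"mlp"`
#' @param minPositives support threshold for the `macroAUCHighSupport`
#'   summary (training positives)
#' @return List: model, split, per-class `auc` (test set),
#'   `trainPositives`, `macroAUCHighSupport`, `evaluation`
#'   (an `EvaluationResult`), plus the generated data.
#' @export
supervisedFixtureRun <- function(seed = 1L,
                                 spec = syntheticSpec(seed = seed),
                                 config = fixtureTrainConfig(seed),
                                 method = c("gozero", "mlp"),
                                 minPositives = 20L) {
  method <- match.arg(method)
  ont <- generateOntology(spec)
  data <- generateProteins(spec, ont)
  nf <- normalizeAxioms(ont)
  closure <- subclassClosure(nf, classes = classIds(ont))

  sp <- similaritySplit(rownames(data$features), data$hits, seed = seed)
  ids <- split(names(sp$split), sp$split)

  model <- trainModel(data$features, data$annotations, nf,
                      ids$train, ids$valid, config = config, method = method)
  target <- targetClasses(model)
  Stest <- predictFunctions(model, data$features[ids$test, , drop = FALSE])
  Ytest <- labelMatrix(data$annotations, ids$test, target)
  auc <- vapply(target, function(cl) rocAUC(Stest[, cl], Ytest[, cl]), 0)
  trainPositives <- colSums(labelMatrix(data$annotations, ids$train, target))
  high <- names(trainPositives)[trainPositives >= minPositives]
  high <- high[!is.na(auc[high])]

  ic <- informationContent(data$annotations, nf)
  root <- "SYN:0000001"
  evaluation <- evaluatePredictions(Stest, Ytest, ic = ic, roots = root)

  list(model = model, split = sp, ids = ids, auc = auc,
       trainPositives = trainPositives,
       macroAUCHighSupport = if (length(high)) mean(auc[high]) else NA_real_,
       evaluation = evaluation, data = data, ontology = ont, nf = nf,
       closure = closure)
}

#' Zero-shot benchmark run on the synthetic fixture
#'
#' Selects one planted defined class (the best-supported one) and one
#' undefined comparison class (a leaf with similar support), removes them
#' from the direct annotations before propagation, retrains, and reports the
#' zero-shot class-centric AUC on the test split and on all proteins,
#' alongside the paired supervised AUC.
#'
#' @inheritParams supervisedFixtureRun
#' @param trained also run the paired supervised model
#' @return The [zeroShotProtocol()] data.frame with an added `defined`
#'   column.
#' @export
zeroShotFixtureRun <- function(seed = 1L,
                               spec = syntheticSpec(seed = seed),
                               config = fixtureTrainConfig(seed),
                               trained = TRUE) {
  ont <- generateOntology(spec)
  data <- generateProteins(spec, ont)
  nf <- normalizeAxioms(ont)
  closure <- subclassClosure(nf, classes = classIds(ont))
  sp <- similaritySplit(rownames(data$features), data$hits, seed = seed)
  ids <- split(names(sp$split), sp$split)

  counts <- table(unlist(data$annotations, use.names = FALSE))
  defs <- .syntheticDefinitions(ont)$c
  defs <- defs[defs %in% names(counts)]
  defHold <- defs[which.max(counts[defs])]
  nPos <- counts[[defHold]]
  leaves <- .syntheticLeaves(ont)
  leaves <- leaves[leaves %in% names(counts)]
  undefHold <- leaves[which.min(abs(counts[leaves] - nPos))]

  res <- suppressWarnings(
    zeroShotProtocol(data$features, data$direct, nf, closure,
                     holdout = c(defHold, undefHold),
                     trainIds = ids$train, validIds = ids$valid,
                     testIds = ids$test, config = config, trained = trained))
  res$defined <- res$class %in% defs
  res
}
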