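# Pipeline wiring: simulate -> normalize -> split -> train -> predict ->
# diamond -> combine -> evaluate (-> zeroshot), with a run manifest that
# captures enough to reproduce any run.  inst/scripts/zerogo is a thin
# command-line wrapper over these functions.

#' Write / read a prediction TSV
#'
#' Three tab-separated columns: protein_id, go_id, score.
#' @param scores score matrix (proteins x classes)
#' @param path TSV path
#' @return `path` (write) or the score matrix (read).
#' @export
writePredictions <- function(scores, path) {
  idx <- which(scores >= 0, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(scores)[idx[, 1]],
                   go_id = colnames(scores)[idx[, 2]],
                   score = scores[idx])
  df <- df[order(df$protein_id, df$go_id, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("protein_id", "go_id", "score"))
  prot <- sort(unique(df$protein_id), method = "radix")
  cls <- sort(unique(df$go_id), method = "radix")
  S <- matrix(0, length(prot), length(cls), dimnames = list(prot, cls))
  S[cbind(match(df$protein_id, prot), match(df$go_id, cls))] <- df$score
  S
}

#' Default pipeline configuration
#'
#' @param seed master seed
#' @param spec synthetic-spec overrides (list), used by the simulate stage
#' @param train [trainConfig()] overrides (list)
#' @param identityThreshold split identity threshold (percent)
#' @param fractions split fractions over groups
#' @param alpha combination weight, or `NULL` to tune on validation Fmax
#' @param zeroshot logical; also run the zero-shot benchmark
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, spec = list(), train = list(),
                           identityThreshold = 50,
                           fractions = c(train = 0.81, valid = 0.09,
                                         test = 0.10),
                           alpha = NULL, zeroshot = FALSE) {
  list(seed = as.integer(seed), spec = spec, train = train,
       identityThreshold = identityThreshold, fractions = fractions,
       alpha = alpha, zeroshot = zeroshot)
}

#' Run the full fixture pipeline
#'
#' Simulates a dataset, normalizes the ontology, splits the proteins by
#' similarity groups, trains the geometric model, predicts on the test set,
#' computes DiamondScore, combines the two, evaluates, and (optionally) runs
#' the zero-shot benchmark.  All outputs plus a run manifest (config
#' snapshot, input digests, seed, package version, stage timings) land in
#' `outdir`.  Re-running with the same config and seed reproduces the
#' outputs byte for byte.
#'
#' @param config from [pipelineConfig()] or a YAML file path of the same
#'   structure
#' @param outdir output directory
#' @return The evaluation result list, invisibly; side effect: files in
#'   `outdir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipelineConfig()
  base[names(config)] <- config
  config <- base
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); tic <- function() Sys.time()
  took <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  spec <- do.call(syntheticSpec, c(config$spec,
                                   list(seed = config$seed)[!("seed" %in% names(config$spec))]))
  files <- simulateDataset(spec, file.path(outdir, "data"))
  timings$simulate <- took(t0)

  t0 <- tic()
  ont <- files$ontology
  data <- files$data
  nf <- normalizeAxioms(ont)
  writeNormalizedAxioms(nf, file.path(outdir, "normalized_axioms.tsv"))
  closure <- subclassClosure(nf, classes = classIds(ont))
  timings$normalize <- took(t0)

  t0 <- tic()
  sp <- similaritySplit(rownames(data$features), data$hits,
                        identityThreshold = config$identityThreshold,
                        fractions = config$fractions, seed = config$seed)
  ids <- split(names(sp$split), sp$split)
  utils::write.table(
    data.frame(protein_id = names(sp$split), split = sp$split,
               group = sp$group[names(sp$split)]),
    file.path(outdir, "split.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  timings$split <- took(t0)

  t0 <- tic()
  tcfg <- do.call(fixtureTrainConfig,
                  c(list(seed = config$seed), config$train))
  model <- trainModel(data$features, data$annotations, nf,
                      ids$train, ids$valid, config = tcfg)
  timings$train <- took(t0)

  t0 <- tic()
  target <- targetClasses(model)
  Stest <- predictFunctions(model, data$features[ids$test, , drop = FALSE])
  writePredictions(Stest, file.path(outdir, "predictions.tsv"))
  Svalid <- predictFunctions(model, data$features[ids$valid, , drop = FALSE])
  timings$predict <- took(t0)

  t0 <- tic()
  trainAnn <- data$annotations[ids$train]
  attr(trainAnn, "propagated") <- TRUE
  Dtest <- diamondScoreMatrix(ids$test, data$hits, trainAnn, target)
  Dvalid <- diamondScoreMatrix(ids$valid, data$hits, trainAnn, target)
  writePredictions(Dtest, file.path(outdir, "diamond.tsv"))
  timings$diamond <- took(t0)

  t0 <- tic()
  Yvalid <- labelMatrix(data$annotations, ids$valid, target)
  Scomb <- combineScores(Stest, Dtest, alpha = config$alpha,
                         valid = list(model = Svalid, diamond = Dvalid,
                                      labels = Yvalid))
  writePredictions(Scomb, file.path(outdir, "combined.tsv"))
  timings$combine <- took(t0)

  t0 <- tic()
  Ytest <- labelMatrix(data$annotations, ids$test, target)
  ic <- informationContent(data$annotations, nf)
  evalModel <- evaluatePredictions(Stest, Ytest, ic = ic,
                                   roots = "SYN:0000001")
  evalComb <- evaluatePredictions(Scomb, Ytest, ic = ic,
                                  roots = "SYN:0000001")
  writeEvaluation(evalModel, file.path(outdir, "evaluation_model.json"),
                  file.path(outdir, "evaluation_model.tsv"))
  writeEvaluation(evalComb, file.path(outdir, "evaluation_combined.json"),
                  file.path(outdir, "evaluation_combined.tsv"))
  timings$evaluate <- took(t0)

  zs <- NULL
  if (isTRUE(config$zeroshot)) {
    t0 <- tic()
    zs <- zeroShotFixtureRun(seed = config$seed, spec = spec, config = tcfg)
    utils::write.table(zs, file.path(outdir, "zeroshot.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    timings$zeroshot <- took(t0)
  }

  digests <- tryCatch(
    as.list(tools::md5sum(unlist(files[c("obo", "annotations", "features",
                                         "hits")]))),
    error = function(e) list())
  manifest <- list(
    command = "runPipeline",
    version = as.character(utils::packageVersion("zeroGO")),
    seed = config$seed,
    config = config,
    inputDigests = digests,
    timings = timings,
    alpha = attr(Scomb, "alpha"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(model = evalModel, combined = evalComb, zeroshot = zs,
                 manifest = manifest))
}
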