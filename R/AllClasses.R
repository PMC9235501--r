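#' @import methods
NULL

#' Ontology container
#'
#' Holds the classes, relations and raw EL axioms of an ontology, typically
#' read from an OBO file with [readOBO()] or generated with
#' [generateOntology()].  Three raw axiom shapes are supported: plain
#' subclass axioms (C SubClassOf D), existential subclass axioms
#' (C SubClassOf R some D) and intersection equivalences
#' (C EquivalentTo D and R some E) -- the shapes in which Gene Ontology
#' definition axioms are expressed.
#'
#' @slot classes data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete`; one row per ontology class.
#' @slot relations data.frame with columns `id`, `name`.  The reserved
#'   relation `"hasFunction"` linking proteins to classes is always present.
#' @slot axioms data.frame with columns `form`, `c`, `d`, `r`, `e`.
#'   `form` is one of `"subclass"` (uses c, d), `"existential_subclass"`
#'   (c, r, d) and `"intersection_equivalence"` (c, d, r, e, read as
#'   C EquivalentTo D and R some E); unused operands are `NA`.
#' @export
setClass("Ontology", representation(
  classes   = "data.frame",
  relations = "data.frame",
  axioms    = "data.frame"
))

.AXIOM_FORMS <- c("subclass", "existential_subclass", "intersection_equivalence")

.emptyAxioms <- function() {
  data.frame(c = character(), d = character(), r = character(),
             e = character(), form = character(),
             stringsAsFactors = FALSE)[, c("form", "c", "d", "r", "e")]
}

setValidity("Ontology", function(object) {
  cls <- object@classes
  msgs <- character()
  need <- c("id", "name", "namespace", "obsolete")
  if (!all(need %in% names(cls)))
    return(paste("classes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(cls$id))
    msgs <- c(msgs, paste("duplicated class ids:",
                          paste(unique(cls$id[duplicated(cls$id)]), collapse = ", ")))
  if (!all(c("id", "name") %in% names(object@relations)))
    return("relations must have columns id, name")
  if (anyDuplicated(object@relations$id))
    msgs <- c(msgs, "duplicated relation ids")
  if (!"hasFunction" %in% object@relations$id)
    msgs <- c(msgs, "reserved relation 'hasFunction' missing")
  ax <- object@axioms
  if (nrow(ax)) {
    if (!all(ax$form %in% .AXIOM_FORMS))
      msgs <- c(msgs, "unknown axiom form")
    ids <- c(ax$c, ax$d, ax$e)
    bad <- setdiff(ids[!is.na(ids)], cls$id)
    if (length(bad))
      msgs <- c(msgs, paste("unresolved class ids in axioms:",
                            paste(unique(bad), collapse = ", ")))
    badr <- setdiff(ax$r[!is.na(ax$r)], object@relations$id)
    if (length(badr))
      msgs <- c(msgs, paste("unresolved relation ids in axioms:",
                            paste(unique(badr), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an Ontology
#'
#' @param classes data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete` (the latter two are filled with `"synthetic"` / `FALSE`
#'   when absent).
#' @param relations data.frame with columns `id`, `name`; the reserved
#'   `hasFunction` relation is added when missing.
#' @param axioms data.frame of raw axioms (see [Ontology-class]).
#' @return An [Ontology-class] object.
#' @export
Ontology <- function(classes, relations = NULL, axioms = NULL) {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  if (is.null(classes$name)) classes$name <- classes$id
  if (is.null(classes$namespace)) classes$namespace <- "synthetic"
  if (is.null(classes$obsolete)) classes$obsolete <- FALSE
  classes <- classes[, c("id", "name", "namespace", "obsolete")]
  if (is.null(relations))
    relations <- data.frame(id = character(), name = character(),
                            stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (is.null(relations$name)) relations$name <- relations$id
  if (!"hasFunction" %in% relations$id)
    relations <- rbind(relations,
                       data.frame(id = "hasFunction", name = "has function"))
  if (is.null(axioms)) axioms <- .emptyAxioms()
  axioms <- as.data.frame(axioms, stringsAsFactors = FALSE)
  for (col in c("form", "c", "d", "r", "e"))
    if (is.null(axioms[[col]])) axioms[[col]] <- rep(NA_character_, nrow(axioms))
  new("Ontology", classes = classes, relations = relations,
      axioms = axioms[, c("form", "c", "d", "r", "e")])
}

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", nrow(object@classes), "classes (",
      sum(object@classes$obsolete), "obsolete ),",
      nrow(object@relations), "relations,",
      nrow(object@axioms), "raw axioms\n")
  tab <- table(object@axioms$form)
  if (length(tab))
    cat("  axiom forms:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @describeIn Ontology-class class id vector (non-obsolete first-class ids)
#' @param object,x an `Ontology`
#' @export
classIds <- function(object, obsolete = FALSE) {
  cls <- object@classes
  if (!obsolete) cls <- cls[!cls$obsolete, , drop = FALSE]
  cls$id
}

#' @describeIn Ontology-class relation id vector
#' @export
relationIds <- function(object) object@relations$id

#' @describeIn Ontology-class raw axiom table
#' @export
rawAxioms <- function(object) object@axioms

#' Normalized EL axiom set
#'
#' The result of rewriting raw EL axioms into the four normal forms used by
#' the geometric losses: NF1 `C SubClassOf D`, NF2 `C and D SubClassOf E`,
#' NF3 `C SubClassOf R some D`, NF4 `R some C SubClassOf D`.  Equivalence
#' axioms introduce one fresh class each; fresh classes take part in the
#' geometric losses but are never prediction targets.
#'
#' @slot nf1 data.frame(c, d)
#' @slot nf2 data.frame(c, d, e)
#' @slot nf3 data.frame(c, r, d)
#' @slot nf4 data.frame(r, c, d)
#' @slot freshClasses character vector of generated class ids
#' @export
setClass("NormalizedAxioms", representation(
  nf1 = "data.frame", nf2 = "data.frame",
  nf3 = "data.frame", nf4 = "data.frame",
  freshClasses = "character"
))

setValidity("NormalizedAxioms", function(object) {
  msgs <- character()
  chk <- function(df, cols, what) {
    if (!identical(names(df), cols))
      return(paste(what, "must have columns", paste(cols, collapse = ",")))
    if (nrow(df) && anyDuplicated(df))
      return(paste("duplicate entries in", what))
    NULL
  }
  msgs <- c(msgs,
            chk(object@nf1, c("c", "d"), "nf1"),
            chk(object@nf2, c("c", "d", "e"), "nf2"),
            chk(object@nf3, c("c", "r", "d"), "nf3"),
            chk(object@nf4, c("r", "c", "d"), "nf4"))
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs)) paste(unlist(msgs), collapse = "; ") else TRUE
})

setMethod("show", "NormalizedAxioms", function(object) {
  cat("NormalizedAxioms:",
      "nf1 =", nrow(object@nf1), "| nf2 =", nrow(object@nf2),
      "| nf3 =", nrow(object@nf3), "| nf4 =", nrow(object@nf4),
      "| fresh classes =", length(object@freshClasses), "\n")
})

#' @describeIn NormalizedAxioms-class one of the four normal-form tables
#' @param object a `NormalizedAxioms`
#' @param form `"nf1"`, `"nf2"`, `"nf3"` or `"nf4"`
#' @export
normalForm <- function(object, form = c("nf1", "nf2", "nf3", "nf4")) {
  form <- match.arg(form)
  slot(object, form)
}

#' @describeIn NormalizedAxioms-class ids of normalization-generated classes
#' @export
freshClasses <- function(object) object@freshClasses

#' @describeIn NormalizedAxioms-class all class ids mentioned in any normal form
#' @export
normalizedClassIds <- function(object) {
  unique(c(object@nf1$c, object@nf1$d,
           object@nf2$c, object@nf2$d, object@nf2$e,
           object@nf3$c, object@nf3$d,
           object@nf4$c, object@nf4$d,
           object@freshClasses))
}

#' EL n-ball embedding space
#'
#' Classes are n-balls (a center vector plus a non-negative radius),
#' relations are translation vectors.  Radii are stored unconstrained and
#' mapped through softplus by [classRadii()], which keeps them positive
#' without gradient clipping.  The reserved `hasFunction` relation vector
#' links protein embeddings to class balls in the prediction score.
#'
#' @slot dim embedding dimension n
#' @slot centers numeric matrix, one row per class (rownames are class ids)
#' @slot radiiRaw named numeric vector of unconstrained radii
#' @slot relations numeric matrix, one row per relation (incl. hasFunction)
#' @slot gamma margin parameter of the hinge losses
#' @export
setClass("EmbeddingSpace", representation(
  dim = "integer", centers = "matrix", radiiRaw = "numeric",
  relations = "matrix", gamma = "numeric"
))

setValidity("EmbeddingSpace", function(object) {
  msgs <- character()
  if (ncol(object@centers) != object@dim)
    msgs <- c(msgs, "centers must have `dim` columns")
  if (ncol(object@relations) != object@dim)
    msgs <- c(msgs, "relation vectors must have `dim` columns")
  if (is.null(rownames(object@centers)))
    msgs <- c(msgs, "centers must have class-id rownames")
  if (!identical(sort(names(object@radiiRaw)), sort(rownames(object@centers))))
    msgs <- c(msgs, "radiiRaw names must match center rownames")
  if (!"hasFunction" %in% rownames(object@relations))
    msgs <- c(msgs, "relation vector 'hasFunction' missing")
  if (length(object@gamma) != 1 || is.na(object@gamma))
    msgs <- c(msgs, "gamma must be a scalar")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "EmbeddingSpace", function(object) {
  cat("EmbeddingSpace: n =", object@dim, "|", nrow(object@centers),
      "classes |", nrow(object@relations), "relations | gamma =",
      object@gamma, "\n")
})

#' @describeIn EmbeddingSpace-class embedding dimension n
#' @param object an `EmbeddingSpace`
#' @export
embeddingDim <- function(object) object@dim

#' @describeIn EmbeddingSpace-class class center matrix
#' @export
classCenters <- function(object) object@centers

#' @describeIn EmbeddingSpace-class non-negative class radii (softplus of the
#'   stored unconstrained values)
#' @export
classRadii <- function(object) {
  r <- softplus(object@radiiRaw)
  names(r) <- names(object@radiiRaw)
  r
}

#' @describeIn EmbeddingSpace-class relation vector matrix
#' @export
relationVectors <- function(object) object@relations

#' @describeIn EmbeddingSpace-class hinge margin gamma
#' @export
margin <- function(object) object@gamma

#' Numerically stable softplus
#'
#' `log(1 + exp(x))`, the non-negativity map used for class radii.
#' @param x numeric
#' @export
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Trained function-prediction model
#'
#' Bundles the protein encoder (two residual MLP blocks), the class
#' embedding space, the class-center normalization statistics, the target
#' class list used for the supervised loss, the training configuration and
#' the per-epoch loss history.
#'
#' @slot method `"gozero"` (geometric score head constrained by normal-form
#'   losses) or `"mlp"` (plain sigmoid classification layer baseline)
#' @slot encoder list of encoder parameters and batch-norm running statistics
#' @slot space the [EmbeddingSpace-class] (empty for the MLP baseline)
#' @slot classBN list of normalization parameters/statistics for class centers
#' @slot targetClasses classes with supervised labels during training
#' @slot config training configuration (see [trainConfig()])
#' @slot history data.frame of per-epoch loss components and validation metric
#' @export
setClass("GOZeroModel", representation(
  method = "character", encoder = "list", space = "EmbeddingSpace",
  classBN = "list", targetClasses = "character",
  config = "list", history = "data.frame"
))

setMethod("show", "GOZeroModel", function(object) {
  cat("GOZeroModel (", object@method, "): V =",
      ncol(object@encoder$W1), "-> n =", nrow(object@encoder$W1),
      "|", length(object@targetClasses), "target classes |",
      nrow(object@history), "epochs trained\n")
})

#' @describeIn GOZeroModel-class the class embedding space
#' @param object a `GOZeroModel`
#' @export
modelSpace <- function(object) object@space

#' @describeIn GOZeroModel-class classes used in the supervised loss
#' @export
targetClasses <- function(object) object@targetClasses

#' @describeIn GOZeroModel-class per-epoch training history
#' @export
trainingHistory <- function(object) object@history
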