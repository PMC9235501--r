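# OBO ingestion, EL normalization, subclass closure, true-path-rule
# propagation and information content.

#' Read an ontology from an OBO file
#'
#' Parses `[Term]` and `[Typedef]` stanzas (tags: id, name, namespace, is_a,
#' relationship, intersection_of, is_obsolete).  `is_a` lines become plain
#' subclass axioms, `relationship` lines become existential subclass axioms,
#' and a pair of `intersection_of` lines (one bare class, the genus, plus one
#' relation-qualified class, the existential filler) becomes an intersection
#' equivalence `C EquivalentTo D and R some E` -- the shape of Gene Ontology
#' definition axioms.  Obsolete terms are kept in the class table but
#' excluded from axioms; cross-namespace `is_a` edges are dropped with a
#' warning (the GO sub-ontologies are not related by is_a).  Unknown tags are
#' ignored and counted in a message.
#'
#' @param path path to an OBO 1.2/1.4 file
#' @return An [Ontology-class].
#' @export
readOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)         # strip trailing comments
  lines <- sub("\\s+$", "", lines)

  terms <- list(); typedefs <- list()
  cur <- NULL; curKind <- NULL; unknown <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (curKind == "Term") terms[[length(terms) + 1L]] <<- cur
    else if (curKind == "Typedef") typedefs[[length(typedefs) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      kind <- sub("^\\[(.*)\\]$", "\\1", ln)
      curKind <- kind
      cur <- if (kind %in% c("Term", "Typedef"))
        list(line = i, is_a = character(), relationship = character(),
             intersection_of = character())
      else NULL
      if (!kind %in% c("Term", "Typedef")) curKind <- "other"
      next
    }
    if (is.null(cur)) next
    if (!grepl("^[A-Za-z_]+:", ln))
      stop("malformed stanza line ", i, " in ", path, ": '", ln, "'")
    tag <- sub(":.*$", "", ln)
    val <- sub("^[A-Za-z_]+:\\s*", "", ln)
    if (tag %in% c("is_a", "relationship", "intersection_of"))
      cur[[tag]] <- c(cur[[tag]], val)
    else if (tag %in% c("id", "name", "namespace", "is_obsolete"))
      cur[[tag]] <- val
    else unknown <- unknown + 1L
  }
  flush()
  if (unknown > 0)
    message("readOBO: ignored ", unknown, " line(s) with unhandled tags")

  if (!length(terms))
    return(Ontology(classes = data.frame(id = character(), name = character(),
                                         namespace = character(),
                                         obsolete = logical())))

  getf <- function(x, f, default) if (is.null(x[[f]])) default else x[[f]]
  classes <- data.frame(
    id = vapply(terms, function(t) getf(t, "id", NA_character_), ""),
    name = vapply(terms, function(t) getf(t, "name", ""), ""),
    namespace = vapply(terms, function(t) getf(t, "namespace", "synthetic"), ""),
    obsolete = vapply(terms, function(t)
      identical(tolower(getf(t, "is_obsolete", "false")), "true"), TRUE),
    stringsAsFactors = FALSE)
  if (anyNA(classes$id)) {
    bad <- terms[[which(is.na(classes$id))[1]]]
    stop("malformed [Term] stanza starting at line ", bad$line, ": missing id")
  }
  relations <- data.frame(
    id = vapply(typedefs, function(t) getf(t, "id", NA_character_), ""),
    name = vapply(typedefs, function(t) getf(t, "name", ""), ""),
    stringsAsFactors = FALSE)

  ns <- stats::setNames(classes$namespace, classes$id)
  ax <- list(); crossNs <- 0L
  for (t in terms) {
    if (identical(tolower(getf(t, "is_obsolete", "false")), "true")) next
    cid <- t$id
    for (p in t$is_a) {
      if (!is.na(ns[p]) && !is.na(ns[cid]) && ns[p] != ns[cid]) {
        crossNs <- crossNs + 1L; next
      }
      ax[[length(ax) + 1L]] <- data.frame(form = "subclass", c = cid, d = p,
                                          r = NA_character_, e = NA_character_)
    }
    for (rl in t$relationship) {
      parts <- strsplit(trimws(rl), "\\s+")[[1]]
      if (length(parts) != 2)
        stop("malformed relationship line in term ", cid, ": '", rl, "'")
      ax[[length(ax) + 1L]] <- data.frame(form = "existential_subclass",
                                          c = cid, d = parts[2], r = parts[1],
                                          e = NA_character_)
    }
    if (length(t$intersection_of)) {
      parts <- lapply(t$intersection_of, function(x) strsplit(trimws(x), "\\s+")[[1]])
      lens <- vapply(parts, length, 1L)
      if (!(length(parts) == 2 && sort(lens)[1] == 1 && sort(lens)[2] == 2))
        stop("unsupported intersection_of structure in term ", cid,
             " (expected one genus class and one relation-qualified filler)")
      genus <- parts[[which(lens == 1)]][1]
      rel <- parts[[which(lens == 2)]]
      ax[[length(ax) + 1L]] <- data.frame(form = "intersection_equivalence",
                                          c = cid, d = genus, r = rel[1],
                                          e = rel[2])
    }
  }
  if (crossNs > 0)
    warning("readOBO: dropped ", crossNs, " cross-namespace is_a edge(s)")
  axioms <- if (length(ax)) do.call(rbind, ax) else .emptyAxioms()

  refs <- unique(c(axioms$d, axioms$e))
  refs <- refs[!is.na(refs)]
  dangling <- setdiff(refs, classes$id)
  if (length(dangling))
    stop("unresolved class ids referenced in ", path, ": ",
         paste(dangling, collapse = ", "))
  usedRels <- unique(axioms$r[!is.na(axioms$r)])
  missingRels <- setdiff(usedRels, relations$id)
  if (length(missingRels))           # OBO files often omit [Typedef] stanzas
    relations <- rbind(relations,
                       data.frame(id = missingRels, name = missingRels))
  Ontology(classes = classes, relations = relations, axioms = axioms)
}

#' Write an ontology to an OBO file
#'
#' Inverse of [readOBO()]: emits `[Term]` stanzas with id, name, namespace,
#' is_a, relationship and intersection_of lines and `[Typedef]` stanzas for
#' relations other than the reserved `hasFunction`.
#'
#' @param ontology an [Ontology-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeOBO <- function(ontology, path) {
  cls <- ontology@classes
  ax <- ontology@axioms
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(cls))) {
    id <- cls$id[i]
    block <- c("[Term]", paste0("id: ", id), paste0("name: ", cls$name[i]),
               paste0("namespace: ", cls$namespace[i]))
    if (cls$obsolete[i]) block <- c(block, "is_obsolete: true")
    sub <- ax[!is.na(ax$c) & ax$c == id, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      row <- sub[j, ]
      block <- c(block, switch(row$form,
        subclass = paste0("is_a: ", row$d),
        existential_subclass = paste0("relationship: ", row$r, " ", row$d),
        intersection_equivalence = c(paste0("intersection_of: ", row$d),
                                     paste0("intersection_of: ", row$r, " ", row$e))))
    }
    out <- c(out, block, "")
  }
  rels <- ontology@relations
  rels <- rels[rels$id != "hasFunction", , drop = FALSE]
  for (i in seq_len(nrow(rels)))
    out <- c(out, "[Typedef]", paste0("id: ", rels$id[i]),
             paste0("name: ", rels$name[i]), "")
  writeLines(out, path)
  invisible(path)
}

#' Normalize raw EL axioms into the four normal forms
#'
#' Plain subclass axioms map to NF1 and existential subclass axioms to NF3.
#' An intersection equivalence `C EquivalentTo D and R some E` is rewritten
#' into four axioms via one fresh class X: `C SubClassOf D` (NF1),
#' `C SubClassOf R some E` (NF3), `R some E SubClassOf X` (NF4) and
#' `D and X SubClassOf C` (NF2).  The rewrite entails the original
#' equivalence in both directions for any interpretation of X.  Fresh class
#' ids are `NFX:<counter>`, assigned over a canonical ordering of the input
#' equivalences so normalization is reproducible.
#'
#' @param x an [Ontology-class] or a raw axiom data.frame
#'   (columns form, c, d, r, e)
#' @return A [NormalizedAxioms-class].
#' @export
normalizeAxioms <- function(x) {
  ax <- if (is(x, "Ontology")) x@axioms else as.data.frame(x)
  if (is(x, "Ontology")) {
    known <- c(x@classes$id, x@relations$id)
    ops <- unique(c(ax$c, ax$d, ax$e, ax$r))
    bad <- setdiff(ops[!is.na(ops)], known)
    if (length(bad))
      stop("unresolved operands in axioms: ", paste(bad, collapse = ", "))
    obs <- x@classes$id[x@classes$obsolete]
    if (length(obs) && nrow(ax)) {
      drop <- ax$c %in% obs | ax$d %in% obs |
        (!is.na(ax$e) & ax$e %in% obs)
      ax <- ax[!drop, , drop = FALSE]
    }
  }
  nf1 <- data.frame(c = character(), d = character())
  nf2 <- data.frame(c = character(), d = character(), e = character())
  nf3 <- data.frame(c = character(), r = character(), d = character())
  nf4 <- data.frame(r = character(), c = character(), d = character())
  fresh <- character()
  if (nrow(ax)) {
    bad <- setdiff(ax$form, .AXIOM_FORMS)
    if (length(bad)) stop("unknown raw axiom form(s): ", paste(bad, collapse = ", "))
    sub <- ax[ax$form == "subclass", , drop = FALSE]
    if (nrow(sub)) nf1 <- data.frame(c = sub$c, d = sub$d)
    ex <- ax[ax$form == "existential_subclass", , drop = FALSE]
    if (nrow(ex)) nf3 <- data.frame(c = ex$c, r = ex$r, d = ex$d)
    eq <- ax[ax$form == "intersection_equivalence", , drop = FALSE]
    if (nrow(eq)) {
      eq <- eq[order(eq$c, eq$d, eq$r, eq$e, method = "radix"), ,
               drop = FALSE]
      fresh <- sprintf("NFX:%06d", seq_len(nrow(eq)))
      nf1 <- rbind(nf1, data.frame(c = eq$c, d = eq$d))
      nf3 <- rbind(nf3, data.frame(c = eq$c, r = eq$r, d = eq$e))
      nf4 <- rbind(nf4, data.frame(r = eq$r, c = eq$e, d = fresh))
      nf2 <- rbind(nf2, data.frame(c = eq$d, d = fresh, e = eq$c))
    }
  }
  new("NormalizedAxioms",
      nf1 = unique(nf1), nf2 = unique(nf2), nf3 = unique(nf3),
      nf4 = unique(nf4), freshClasses = fresh)
}

#' Reflexive-transitive subclass closure
#'
#' Computes, for every class appearing in the NF1 subclass edges, the set of
#' its ancestors (including itself).  Fresh normalization classes are
#' excluded from the ancestor sets reported for real classes.  NF1 edges
#' among real classes must form a DAG; a cycle is reported with one witness.
#'
#' @param nf a [NormalizedAxioms-class]
#' @param classes optional character vector of additional class ids to give
#'   (reflexive-only) entries
#' @return Named list: class id -> character vector of ancestor ids.
#' @export
subclassClosure <- function(nf, classes = NULL) {
  edges <- nf@nf1
  fresh <- nf@freshClasses
  real <- !(edges$c %in% fresh | edges$d %in% fresh)
  edges <- edges[real, , drop = FALSE]
  ids <- unique(c(edges$c, edges$d, classes))
  ids <- setdiff(ids, fresh)
  parents <- split(edges$d, factor(edges$c, levels = ids))

  anc <- vector("list", length(ids)); names(anc) <- ids
  state <- integer(length(ids)); names(state) <- ids  # 0 new, 1 active, 2 done
  stackTrace <- character()
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) {
      cyc <- c(stackTrace[which(stackTrace == id)[1]:length(stackTrace)], id)
      stop("cycle among subclass axioms: ", paste(cyc, collapse = " -> "))
    }
    state[[id]] <<- 1L
    stackTrace <<- c(stackTrace, id)
    acc <- id
    for (p in parents[[id]]) acc <- c(acc, visit(p))
    acc <- unique(acc)
    stackTrace <<- stackTrace[-length(stackTrace)]
    state[[id]] <<- 2L
    anc[[id]] <<- acc
    acc
  }
  for (id in ids) visit(id)
  anc
}

#' Construct an annotation set
#'
#' An annotation set is a named list mapping protein ids to character
#' vectors of class ids, with a logical `propagated` attribute recording
#' whether it is closed under subclass ancestors.
#'
#' @param x named list of character vectors
#' @param propagated logical
#' @return The annotation set.
#' @export
annotationSet <- function(x, propagated = FALSE) {
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(v) unique(as.character(v)))
  attr(x, "propagated") <- propagated
  x
}

#' @rdname annotationSet
#' @export
isPropagated <- function(x) isTRUE(attr(x, "propagated"))

#' Read a protein annotation table
#'
#' Reads a TSV with columns `protein_id`, `go_id`, `evidence_code` (no
#' header) and keeps rows whose evidence code is in the whitelist.  The
#' default whitelist is the experimental-evidence set commonly used to build
#' function-prediction corpora: EXP IDA IPI IMP IGI IEP TAS IC HTP HDA HMP
#' HGI HEP.
#'
#' @param path TSV path
#' @param evidence character whitelist of evidence codes, or `NULL` to keep
#'   everything
#' @return An unpropagated annotation set.
#' @export
readAnnotations <- function(path,
                            evidence = c("EXP", "IDA", "IPI", "IMP", "IGI",
                                         "IEP", "TAS", "IC", "HTP", "HDA",
                                         "HMP", "HGI", "HEP")) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("protein_id", "go_id", "evidence_code"),
                          colClasses = "character")
  if (!is.null(evidence)) df <- df[df$evidence_code %in% evidence, , drop = FALSE]
  annotationSet(split(df$go_id, df$protein_id), propagated = FALSE)
}

#' Write a protein annotation table
#'
#' @param annotations an annotation set
#' @param path output TSV path
#' @param evidence evidence code written on every row (default "IEA"
#'   for derived, "EXP" is typical for fixtures)
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path, evidence = "EXP") {
  df <- data.frame(
    protein_id = rep(names(annotations), lengths(annotations)),
    go_id = unlist(annotations, use.names = FALSE),
    evidence_code = evidence)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Propagate annotations by the true-path rule
#'
#' Every annotation to a class implies annotation to all of its subclass
#' ancestors; each protein's class set is replaced by the union of the
#' ancestor sets of its classes.  Idempotent and monotone.
#'
#' @param annotations an annotation set
#' @param closure ancestor map from [subclassClosure()]
#' @return A propagated annotation set.
#' @export
propagateAnnotations <- function(annotations, closure) {
  out <- lapply(names(annotations), function(p) {
    cls <- annotations[[p]]
    missing <- setdiff(cls, names(closure))
    if (length(missing))
      stop("protein ", p, ": unknown class id(s) ",
           paste(missing, collapse = ", "))
    unique(unlist(closure[cls], use.names = FALSE))
  })
  names(out) <- names(annotations)
  annotationSet(out, propagated = TRUE)
}

#' Information content of ontology classes
#'
#' Computes per-class information content from a propagated annotation
#' corpus.  The default is the conditional form used by the CAFA Smin
#' metric: `IC(c) = -log P(c | parents(c))`, where the probability is the
#' fraction of proteins annotated with all direct parents of `c` that are
#' also annotated with `c` (and its parents).  `method = "marginal"` gives
#' plain `-log P(c)` over the corpus, the form used when reporting the
#' average information content of predictions.  Classes with no annotated
#' protein fall back to an additive pseudocount.
#'
#' @param annotations a propagated annotation set
#' @param nf a [NormalizedAxioms-class] supplying the direct-parent edges
#' @param method `"conditional"` or `"marginal"`
#' @param unit `"bits"` (log base 2) or `"nats"`
#' @param pseudocount additive count used for never-annotated classes
#' @param classes optional class ids to report (default: all classes in the
#'   subclass closure)
#' @return Named numeric vector of IC values (>= 0).
#' @export
informationContent <- function(annotations, nf,
                               method = c("conditional", "marginal"),
                               unit = c("bits", "nats"),
                               pseudocount = 1, classes = NULL) {
  method <- match.arg(method); unit <- match.arg(unit)
  if (!length(annotations)) stop("empty annotation corpus")
  if (!isPropagated(annotations))
    stop("annotations must be propagated before computing information content")
  logf <- if (unit == "bits") function(x) log2(x) else function(x) log(x)

  fresh <- nf@freshClasses
  edges <- nf@nf1
  edges <- edges[!(edges$c %in% fresh | edges$d %in% fresh), , drop = FALSE]
  if (is.null(classes))
    classes <- unique(c(edges$c, edges$d,
                        unlist(annotations, use.names = FALSE)))
  parents <- split(edges$d, factor(edges$c, levels = classes))

  nProt <- length(annotations)
  counts <- table(factor(unlist(annotations, use.names = FALSE),
                         levels = classes))
  ic <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    nc <- counts[[cl]]
    if (method == "marginal") {
      p <- if (nc > 0) nc / nProt else pseudocount / (nProt + pseudocount)
    } else {
      par <- parents[[cl]]
      npar <- if (length(par) == 0) nProt
      else sum(vapply(annotations, function(s) all(par %in% s), TRUE))
      # under propagation count(c & parents(c)) == count(c)
      p <- if (nc > 0) nc / npar
      else if (npar > 0) pseudocount / (npar + pseudocount)
      else 1
    }
    ic[[cl]] <- max(0, -logf(p))
  }
  ic
}

#' Export / import normalized axioms as TSV
#'
#' Columns: form (nf1-nf4), c, d, e, r; unused operands are empty.
#' @param nf a [NormalizedAxioms-class]
#' @param path TSV path
#' @return `path` (write) or a [NormalizedAxioms-class] (read).
#' @export
writeNormalizedAxioms <- function(nf, path) {
  blank <- function(n) rep("", n)
  rows <- rbind(
    if (nrow(nf@nf1)) data.frame(form = "nf1", c = nf@nf1$c, d = nf@nf1$d,
                                 e = blank(nrow(nf@nf1)), r = blank(nrow(nf@nf1))),
    if (nrow(nf@nf2)) data.frame(form = "nf2", c = nf@nf2$c, d = nf@nf2$d,
                                 e = nf@nf2$e, r = blank(nrow(nf@nf2))),
    if (nrow(nf@nf3)) data.frame(form = "nf3", c = nf@nf3$c, d = nf@nf3$d,
                                 e = blank(nrow(nf@nf3)), r = nf@nf3$r),
    if (nrow(nf@nf4)) data.frame(form = "nf4", c = nf@nf4$c, d = nf@nf4$d,
                                 e = blank(nrow(nf@nf4)), r = nf@nf4$r))
  if (is.null(rows)) rows <- data.frame(form = character(), c = character(),
                                        d = character(), e = character(),
                                        r = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalizedAxioms
#' @export
readNormalizedAxioms <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  pick <- function(f, cols) {
    sub <- df[df$form == f, cols, drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  fresh <- unique(c(df$d[df$form == "nf4"]))
  fresh <- fresh[grepl("^NFX:", fresh)]
  new("NormalizedAxioms",
      nf1 = pick("nf1", c("c", "d")),
      nf2 = pick("nf2", c("c", "d", "e")),
      nf3 = pick("nf3", c("c", "r", "d")),
      nf4 = pick("nf4", c("r", "c", "d")),
      freshClasses = fresh)
}
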