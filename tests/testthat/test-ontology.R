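# OBO parsing, EL normalization, subclass closure, true-path-rule
# propagation and information content.

oboText <- function(...) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("readOBO maps stanza lines onto the three raw axiom shapes", {
  path <- oboText(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0003674", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0005488", "name: binding",
    "namespace: molecular_function", "is_a: GO:0003674 ! molecular_function",
    "xref: ignored:1", "",
    "[Term]", "id: GO:0065007", "name: biological regulation",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0051098", "name: regulation of binding",
    "namespace: molecular_function",
    "intersection_of: GO:0065007",
    "intersection_of: RO:0002211 GO:0005488", "",
    "[Term]", "id: GO:0000001", "name: gone",
    "namespace: molecular_function", "is_obsolete: true", "",
    "[Typedef]", "id: RO:0002211", "name: regulates")
  suppressMessages(ont <- readOBO(path))
  expect_s4_class(ont, "Ontology")
  expect_equal(nrow(ont@classes), 5)
  expect_true("RO:0002211" %in% relationIds(ont))
  ax <- rawAxioms(ont)
  expect_equal(ax[ax$form == "subclass", c("c", "d")],
               data.frame(c = "GO:0005488", d = "GO:0003674"),
               ignore_attr = TRUE)
  eq <- ax[ax$form == "intersection_equivalence", ]
  expect_equal(unname(unlist(eq[, c("c", "d", "r", "e")])),
               c("GO:0051098", "GO:0065007", "RO:0002211", "GO:0005488"))
  # obsolete terms contribute no axioms and are flagged
  expect_true(ont@classes$obsolete[ont@classes$id == "GO:0000001"])
  expect_false("GO:0000001" %in% ax$c)
})

test_that("readOBO handles empty files and rejects malformed input", {
  expect_equal(nrow(readOBO(oboText(""))@classes), 0)
  expect_error(readOBO(oboText("[Term]", "id: X:1", "no tag here")),
               "malformed")
  expect_error(readOBO(oboText("[Term]", "id: X:1", "name: x",
                               "is_a: X:9999")),
               "unresolved.*X:9999")
  expect_error(readOBO(file.path(tempdir(), "does-not-exist.obo")),
               "not found")
})

test_that("cross-namespace is_a edges are dropped with a warning", {
  path <- oboText(
    "[Term]", "id: X:1", "name: a", "namespace: molecular_function", "",
    "[Term]", "id: X:2", "name: b", "namespace: biological_process",
    "is_a: X:1")
  expect_warning(ont <- readOBO(path), "cross-namespace")
  expect_equal(nrow(rawAxioms(ont)), 0)
})

test_that("normalization rewrites each raw shape into the right lists", {
  # plain subclass -> NF1 only
  nf <- normalizeAxioms(data.frame(
    form = "subclass", c = "GO:0043167", d = "GO:0005488",
    r = NA_character_, e = NA_character_))
  expect_equal(normalForm(nf, "nf1"),
               data.frame(c = "GO:0043167", d = "GO:0005488"))
  expect_equal(nrow(normalForm(nf, "nf2")), 0)
  expect_equal(nrow(normalForm(nf, "nf3")), 0)
  expect_equal(nrow(normalForm(nf, "nf4")), 0)

  # one equivalence -> one entry in each list plus one fresh class
  nf <- normalizeAxioms(data.frame(
    form = "intersection_equivalence", c = "Z", d = "D", r = "R", e = "E"))
  expect_equal(vapply(c("nf1", "nf2", "nf3", "nf4"),
                      function(f) nrow(normalForm(nf, f)), 0L),
               c(nf1 = 1L, nf2 = 1L, nf3 = 1L, nf4 = 1L))
  expect_length(freshClasses(nf), 1)
  x <- freshClasses(nf)
  expect_equal(normalForm(nf, "nf1"), data.frame(c = "Z", d = "D"))
  expect_equal(normalForm(nf, "nf3"), data.frame(c = "Z", r = "R", d = "E"))
  expect_equal(normalForm(nf, "nf4"), data.frame(r = "R", c = "E", d = x))
  expect_equal(normalForm(nf, "nf2"), data.frame(c = "D", d = x, e = "Z"))

  # empty input, determinism, linear output size
  empty <- normalizeAxioms(zeroGO:::.emptyAxioms())
  expect_equal(nrow(normalForm(empty, "nf1")), 0)
  ax <- rawAxioms(tinyOntology())
  expect_identical(normalizeAxioms(ax), normalizeAxioms(ax))
  nAll <- sum(vapply(c("nf1", "nf2", "nf3", "nf4"), function(f)
    nrow(normalForm(normalizeAxioms(ax), f)), 0L))
  expect_lte(nAll, 4 * nrow(ax))
})

test_that("normalized rewrites agree with the equivalence on finite models", {
  set.seed(7)
  nf <- normalizeAxioms(tinyOntology())
  eq <- rawAxioms(tinyOntology())
  eq <- eq[eq$form == "intersection_equivalence", ]
  examined <- checkRewriteSoundness(nf, as.list(eq), nSamples = 60)
  expect_gt(examined, 60)
})

test_that("subclass closure equals exhaustive path enumeration", {
  nf <- normalizeAxioms(data.frame(
    form = "subclass", c = c("A", "B"), d = c("B", "C"),
    r = NA_character_, e = NA_character_))
  cl <- subclassClosure(nf)
  expect_setequal(cl$A, c("A", "B", "C"))
  expect_setequal(subclassClosure(nf, classes = "solo")$solo, "solo")

  set.seed(11)
  for (rep in 1:5) {
    ids <- paste0("N", 1:10)
    edges <- do.call(rbind, lapply(2:10, function(i) {
      ps <- sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))
      data.frame(c = ids[i], d = ids[ps])
    }))
    nfR <- normalizeAxioms(data.frame(form = "subclass", c = edges$c,
                                      d = edges$d, r = NA_character_,
                                      e = NA_character_))
    cl <- subclassClosure(nfR)
    for (id in ids)
      expect_setequal(cl[[id]], oracleAncestors(unique(edges), id))
  }
})

test_that("subclass cycles are rejected with a witness", {
  nf <- normalizeAxioms(data.frame(
    form = "subclass", c = c("A", "B", "C"), d = c("B", "C", "A"),
    r = NA_character_, e = NA_character_))
  expect_error(subclassClosure(nf), "cycle.*->")
})

test_that("fresh classes are excluded from real-class ancestor sets", {
  nf <- normalizeAxioms(rawAxioms(tinyOntology()))
  cl <- subclassClosure(nf)
  expect_false(any(grepl("^NFX:", unlist(cl))))
  expect_setequal(cl$Z, c("Z", "A2", "A1"))
})

test_that("true-path propagation is correct, idempotent and monotone", {
  nf <- normalizeAxioms(tinyOntology())
  cl <- subclassClosure(nf, classes = classIds(tinyOntology()))
  ann <- annotationSet(list(p1 = "A5", p2 = c("B", "A3")))
  prop <- propagateAnnotations(ann, cl)
  expect_true(isPropagated(prop))
  expect_setequal(prop$p1, c("A5", "A4", "A3", "A2", "A1"))
  expect_setequal(prop$p2, c("B", "A3", "A2", "A1"))
  # idempotence
  expect_equal(propagateAnnotations(prop, cl)[], prop[])
  # monotonicity on random cases
  set.seed(3)
  for (i in 1:10) {
    a <- sample(names(cl), 2)
    small <- propagateAnnotations(annotationSet(list(p = a[1])), cl)
    big <- propagateAnnotations(annotationSet(list(p = a)), cl)
    expect_true(all(small$p %in% big$p))
  }
  expect_error(
    propagateAnnotations(annotationSet(list(p = "NOPE")), cl),
    "unknown class")
})

test_that("annotation IO round-trips and filters by evidence code", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tA1\tEXP", "p1\tA2\tIEA", "p2\tB\tIDA"), path)
  ann <- readAnnotations(path)
  expect_equal(ann$p1, "A1")   # IEA filtered by the experimental whitelist
  expect_equal(ann$p2, "B")
  all <- readAnnotations(path, evidence = NULL)
  expect_setequal(all$p1, c("A1", "A2"))

  out <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(ann, out)
  expect_equal(readAnnotations(out)[], ann[])
})

test_that("conditional information content matches hand-enumerated counts", {
  # chain C4 <- C3 <- C2 <- C1; 8 proteins, annotation counts 8/4/2/1
  ax <- data.frame(form = "subclass", c = c("C2", "C3", "C4"),
                   d = c("C1", "C2", "C3"), r = NA_character_,
                   e = NA_character_)
  nf <- normalizeAxioms(ax)
  cl <- subclassClosure(nf)
  direct <- c(rep("C1", 4), rep("C2", 2), "C3", "C4")
  ann <- propagateAnnotations(
    annotationSet(as.list(stats::setNames(direct, paste0("p", 1:8)))), cl)
  ic <- informationContent(ann, nf)
  # root covers all proteins -> 0 bits; each level halves -> 1 bit each
  expect_equal(unname(ic[c("C1", "C2", "C3", "C4")]), c(0, 1, 1, 1))
  # marginal form: -log2(count / n)
  icm <- informationContent(ann, nf, method = "marginal")
  expect_equal(unname(icm[c("C1", "C2", "C3", "C4")]), c(0, 1, 2, 3))
  # nats switch
  icn <- informationContent(ann, nf, unit = "nats")
  expect_equal(unname(icn["C2"]), log(2))
  expect_error(informationContent(
    annotationSet(stats::setNames(list(), character()), propagated = TRUE),
    nf), "empty")
  expect_error(informationContent(annotationSet(list(p = "C1")), nf),
               "propagated")
})

test_that("marginal IC is non-increasing from child to parent", {
  # under true-path propagation a parent is at least as frequent as any
  # child, so -log P(c) cannot decrease toward the leaves; the conditional
  # form has no such guarantee (a child perfectly determined by its parent
  # has conditional IC 0 regardless of the parent's own IC)
  for (seed in 1:3) {
    spec <- syntheticSpec(seed = seed, nProteins = 80L)
    ont <- generateOntology(spec)
    data <- generateProteins(spec, ont)
    nf <- normalizeAxioms(ont)
    ic <- informationContent(data$annotations, nf, method = "marginal")
    edges <- normalForm(nf, "nf1")
    edges <- edges[!edges$c %in% freshClasses(nf) &
                     !edges$d %in% freshClasses(nf), ]
    counts <- table(unlist(data$annotations))
    seen <- edges$c %in% names(counts) & edges$d %in% names(counts)
    expect_true(all(ic[edges$d[seen]] <= ic[edges$c[seen]] + 1e-9))
  }
})

test_that("normalized axiom TSV round-trips", {
  nf <- normalizeAxioms(tinyOntology())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeNormalizedAxioms(nf, path)
  back <- readNormalizedAxioms(path)
  for (f in c("nf1", "nf2", "nf3", "nf4"))
    expect_setequal_df(normalForm(back, f), normalForm(nf, f))
  expect_setequal(freshClasses(back), freshClasses(nf))
})
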