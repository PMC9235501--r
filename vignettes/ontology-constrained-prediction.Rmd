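---
title: "Ontology-constrained function prediction with EL n-ball embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-constrained function prediction with EL n-ball embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeroGO)
```

## The model

zeroGO treats protein function prediction as axiom inference in a geometric
model of the Gene Ontology. Every ontology class `c` is an *n-ball*: a
center `f(c)` in n-dimensional space plus a non-negative radius `r(c)`.
Every relation `R` is a translation vector. Under this geometry, EL axioms
become ball-containment constraints, and each of the four EL normal forms
contributes a hinge loss with margin `gamma`:

| form | axiom | loss goes to zero when |
|------|-------|------------------------|
| NF1 | `C ⊑ D` | ball c inside ball d |
| NF2 | `C ⊓ D ⊑ E` | the c∩d intersection region inside ball e |
| NF3 | `C ⊑ ∃R.D` | ball c near the R-translate of ball d |
| NF4 | `∃R.C ⊑ D` | the R-translated ball c inside ball d |

Raw axioms are ingested in three shapes (plain subclass, existential
subclass, and intersection equivalences `C ≡ D ⊓ ∃R.E`, the shape of GO
definition axioms). An equivalence is rewritten with one fresh class `X`
into `C ⊑ D` (NF1), `C ⊑ ∃R.E` (NF3), `∃R.E ⊑ X` (NF4) and `D ⊓ X ⊑ C`
(NF2). This rewrite entails the original equivalence in both directions for
*any* interpretation of `X`; the test suite confirms it with a brute-force
finite-interpretation search over domains of up to six elements. Fresh
classes participate in the losses but are never prediction targets.

Proteins enter the same space through two residual MLP blocks over their
binary domain-annotation vector `x`:

```
MLPBlock(x) = DropOut(BatchNorm(ReLU(W x + b)))
h = MLPBlock1(x);   f(p) = h + MLPBlock2(h)
```

and the prediction score for class `c` is the membership of `f(p)` in the
hasFunction-translated ball, `sigmoid(f(p)·(f(hF) + f(c)) + r(c))`. We read
the transpose in that expression as an inner product between the protein
embedding and the translated center; no bias beyond `r(c)` is added. The
joint objective is mean binary cross-entropy over the supervised targets
plus the four normal-form losses, minimized with Adam. Classes without a
single training annotation are excluded from the cross-entropy but kept in
the normal-form losses — their balls are placed by the axioms alone, which
is what makes zero-shot scoring of those classes possible.

### Assumptions

* Annotations obey the true-path rule; labels are propagated to all
  subclass ancestors before training and evaluation.
* The subclass graph restricted to real (non-fresh) classes is a DAG;
  cycles are rejected with a witness.
* Features are binary presence/absence indicators; no feature weighting is
  attempted.

## Tunable parameters

All training knobs live in `trainConfig()`:

| parameter | default | notes |
|-----------|---------|-------|
| `n` | 1024 | embedding dimension of protein and class vectors |
| `gamma` | 0.1 | hinge margin; 0 forces exact containment, larger values leave slack |
| `lr` | 1e-3 | Adam step size |
| `batch` | 64 | proteins per step |
| `epochs` / `patience` | 100 / 10 | early stopping on the validation metric |
| `dropout` | 0.5 | in both MLP blocks, training mode only |
| `checkpoint` | `"fmax"` | keep the epoch with best validation Fmax; `"loss"` selects by validation cross-entropy instead (the better criterion is an open choice; Fmax matches how the model is ultimately judged) |
| `minAnnotated` | 1 | training annotations required for a class to enter the supervised loss |
| `nfBatch` | 256 | axioms sampled per normal form per step; reported loss breakdowns always use the full lists |
| `seed` | 1 | fixes every stochastic component; identical runs are bit-identical on one machine |

`fixtureTrainConfig()` is the desk-scale profile used throughout the
vignette, tests and acceptance script: `n = 64`, `batch = 32`,
`epochs = 80`, `patience = 15`, `dropout = 0.1`, `lr = 3e-3`. The synthetic
corpus (300 proteins, vocabulary 200) is two to three orders of magnitude
smaller than a real UniProtKB corpus, so a 1024-dimensional embedding and
heavy dropout would be badly over-parameterized for it; these reduced
values are the package's choice of a sensible problem size for a complete
train–evaluate cycle in seconds on one CPU.

## Numerical choices

* **Radii.** Stored unconstrained and mapped through softplus, keeping
  `r(c) > 0` with smooth gradients instead of clipping.
* **Batch normalization of class centers.** The model normalizes class
  center vectors (one layer with learnable scale and shift, statistics over
  the class set) whenever centers are consumed by the losses or the score;
  prediction uses frozen running statistics. The exact placement of this
  normalization is an open design point; a single documented layer keeps it
  auditable.
* **Loss warm-up.** In the first few epochs the normal-form losses *rise*
  while the normalization statistics and radii settle, then fall steadily;
  validation Fmax rises monotonically. Per-epoch monotone decrease of the
  total loss is therefore not a property of this architecture and is not
  asserted anywhere — improvement over the run is.
* **Backpropagation.** All gradients (including the batch-norm backward
  pass and the hinge-loss geometry) are hand-derived matrix code, verified
  against central finite differences in the test suite (relative error
  below 1e-4 on every parameter).
* **NF2 third term.** The published form of the intersection loss uses the
  radius of `c` in its third hinge term; we implement it exactly as
  printed.
* **Ties and degenerate inputs.** ROC AUC uses average ranks (half credit
  for ties); classes with no positive or no negative protein are excluded
  from class-centric AUC with a logged count; hinge gradients at
  coincident centers use a guarded norm (`max(‖·‖, 1e-12)`); `min(r(c),
  r(d))` differentiates through `r(c)` on ties.
* **Threshold grids.** Fmax/Smin default to 0.01 steps on `[0, 1]`, the
  CAFA convention; precision at a threshold is averaged over proteins with
  at least one prediction.
* **Information content.** The Smin default is the conditional CAFA form
  `-log P(c | parents(c))` (bits by default, nats optional); a `marginal`
  switch gives `-log P(c)` for average-IC reporting. Note that conditional
  IC is *not* monotone along subclass edges — a child fully determined by
  its parent has conditional IC near 0 regardless of the parent's own IC —
  so only the marginal form is asserted monotone in the tests.
* **Determinism.** All character orderings that feed parameter layouts or
  output files use locale-independent radix sorting, so runs reproduce
  across locales as well as across sessions.
* **Score propagation.** Hierarchical max-propagation (every ancestor
  scores at least its best descendant) is available at prediction time but
  off by default; whether the published pipeline propagates scores before
  evaluation is unstated, and evaluation already propagates labels.

## The synthetic generator

`syntheticSpec()` defines the study conditions the package is exercised
under: 60 classes (52 in a rooted random subclass DAG of depth ≤ 4 plus 8
defined compound classes), 2 relations, 6 plain existential axioms, 300
proteins, a feature vocabulary of 200, and a planted signal in which each
leaf class owns 4 characteristic features emitted at rate 0.9 against a
background rate of 0.05. Each protein draws 1–3 leaves; a protein carrying
the filler leaf of a definition also draws a leaf under its genus with
probability 0.7, mimicking how compound regulator-style classes co-occur
with their genus in real corpora and giving defined classes realistic
support (15–25 positives). Setting `inclusionProb = backgroundRate`
removes the signal entirely and is the null condition used in the tests.

The planted definitions are **honest**: a protein is annotated with a
defined class exactly when it carries both the genus and the filler, so
zero-shot recovery of a held-out defined class is information-theoretically
possible — and observed (class-centric AUC ≈ 0.95 across seeds), while
held-out classes *without* a definition axiom stay near chance under the
same protocol. On this fixture the defined classes are deterministic
functions of two trained classes, so zero-shot sits near the AUC ceiling
and the paired supervised model improves on it mainly through the
undefined classes; on real corpora, where definitions are noisier,
the supervised margin is larger.

The similarity table gives ortholog-style structure: only proteins with
*identical* leaf profiles exceed the 50% identity used for grouping, while
partially overlapping proteins get informative bitscores below the
grouping threshold. What the generator does **not** emulate: realistic GO
topology statistics (tens of thousands of classes, deep multi-parent
tangles), annotation incompleteness (the open-world nature of real GO
corpora), feature noise structured by domain architecture, or real
sequence similarity distributions. Passing the test suite therefore shows
the machinery is correct and the zero-shot mechanism works as designed; it
does not certify performance numbers on real corpora.

## Evaluation suite

Protein-centric Fmax (CAFA definition), Smin
(`min_t sqrt(ru(t)^2 + mi(t)^2)` over remaining uncertainty and
misinformation weighted by IC), pooled AUPR with step-wise integration,
class-centric macro AUC, AUC binned by annotation count, and the mean IC of
predictions at the Fmax threshold. Every metric is checked against an
independent brute-force oracle (exhaustive threshold enumeration, O(n²)
pair counting) on small instances. Sub-ontology roots are excluded from
evaluation targets, as propagation predicts them trivially.

The similarity-group splitter assigns split fractions (81/9/10 by default)
over *groups*, not proteins, so protein-level fractions may deviate
slightly; no test protein shares a group — hence exceeds the identity
threshold — with any training protein.

## Known limitations

* Only the three OBO-expressible axiom shapes are ingested; nested class
  expressions, unions, disjointness and role chains are rejected with a
  clear message. Whether axioms beyond these shapes would further improve
  the embedding is untested here.
* The MLP baseline shares the encoder implementation with the geometric
  model by construction; it cannot score classes outside its training
  targets.
* The convex model+similarity combination rule (`alpha` tuned on
  validation Fmax over a 0.01 grid) is a reasonable default; the published
  combination rule for such score fusions is not printed and may differ.
* Training is plain R matrix code sized for desk-scale corpora; a
  GPU-scale reimplementation would be needed for full UniProtKB training.
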