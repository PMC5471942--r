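---
title: "Tiered learning for ATC code prediction: models, measures and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered learning for ATC code prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tieredatc)
```

## The problem and the model

The WHO Anatomical Therapeutic Chemical (ATC) system assigns drugs
five-level codes: an anatomical main-group letter (14 groups), a two-digit
therapeutic group, two one-letter subgroups, and a two-digit substance
identifier. A compound may hold several codes — aspirin is both `B01AC06`
and `N02BA01` — and this package follows the convention of treating every
(compound, code) pair as a separate labelled instance for training and
scoring. Prediction stops at level 4: the fifth level identifies a
substance rather than a therapeutic class.

A single flat multiclass classifier per level ignores a strong empirical
regularity: the child-code distribution under any ATC prefix is highly
*characteristic* — most anatomical groups concentrate their mass on a few
therapeutic groups, and ever more so deeper in the tree. Tiered learning
(TL) exploits this by training **one classifier instance per prefix**.
Level 1 comes from an *initializer*; the instance addressed by the
realized prefix then predicts the next-level component, using only
training compounds under that prefix. Each prediction is therefore a
root-to-leaf walk, and the predicted prefix at level $k$ extends the one
at level $k-1$ by construction.

Three accuracy measures describe a run, all on the percent scale over
evaluated instances:

* $A(k)$ — share whose predicted level-$k$ *component* equals the true
  one, computed independently of the other levels (so a run may be right
  at level 2 yet wrong at level 1);
* $CA(k) = \frac{1}{k}\sum_{j \le k} A(j)$ — cumulative accuracy;
* $N(k)$ — share (and count) whose predicted components are correct at
  *every* level $1..k$.

Instances whose true code is shallower than $k$ are excluded from the
$A(k)$ and $N(k)$ denominators (denominators are reported); abstentions
score as wrong. These definitions imply $N(1) = A(1) = CA(1)$,
$\min_{j\le k} A(j) \le CA(k) \le \max_{j\le k} A(j)$, and a
non-increasing path-correct count — identities the test suite asserts on
every computed report. Note that computing $A(k)$ on the cascade's
level-$k$ component even when upstream levels were wrong is the only
reading under which $CA(k)$ is exactly the arithmetic mean of the printed
per-level accuracies, which the package's acceptance checks reproduce.

## Initialization

Two seeding strategies are provided. `init = "supervised"` trains one
classifier on the whole training set to predict the level-1 letter — this
is identical, by construction, to the flat baseline's level-1 model.
`init_external()` wraps a compound-to-letter map from outside knowledge
(another predictor's output, curated repository annotations); a complete
correct map corresponds to "perfect first-level" seeding and pins
$A(1) = N(1) = 100\%$. Compounds missing from the map either abstain
(default; scored wrong) or receive the map's majority letter.

## Base learners and numerical choices

`base_learner()` describes the classifier family used at every node:
naive Bayes, MLP (`nnet`), SVM (`e1071`), random forest
(`randomForest`), plus two cheap backends, a majority-class learner and a
k-nearest-neighbour learner, used as baselines and as an exactly
checkable oracle. Defaults (radial SVM with cost 1; 8 hidden units,
decay 0.01, 150 iterations for the MLP; 200 trees; $k=1$) are ordinary
mid-range settings, recorded in every model object and provenance record;
no claim is made that they are optimal for any particular dataset.

Numerical conventions, chosen once and applied everywhere:

* **Ties** (majority counts, equal distances, equal classifier scores)
  break to the lexicographically smallest code component, so results are
  reproducible and independent of row order wherever possible. Stochastic
  learners draw from the seed recorded in the specification.
* **Degenerate nodes**: a node with a single observed child, or fewer
  than `min_node_size` (default 2) instances, gets a constant
  majority-child model — a discriminative fit on one instance or one
  class is meaningless. Failed underlying fits fall back the same way.
* **Unseen test prefixes** (possible only with external seeding, when a
  seed letter never occurs in training) resolve by `fallback`:
  `"parent-majority"` walks to the nearest observed ancestor and emits
  its majority next component; `"abstain"` stops the path.
* **Naive Bayes variance floor**: within-class standard deviations of
  zero (common on synthetic or binary features) would give degenerate
  Gaussian densities, so fitted sds are floored at $10^{-3}$.
* **Rounding**: percentages are kept in full precision and rounded
  half-up to two decimals only at presentation (`round_half_up()`, with a
  $10^{-9}$ epsilon so decimal boundary cases such as 69.085 round the
  way the printed tables do).

A design point worth stating: node models are trained **eagerly on true
training prefixes** — every prefix observed in training gets its
classifier, fitted on the instances truly under it. Predicted prefixes
matter only at prediction time, when they select among these instances.
Training "on the predicted prefix" instead would couple node training to
a particular test run without changing which data each node can see; the
eager form is equivalent and far more testable (node purity is assertable
from the stored node metadata). The optional chemical-similarity
pre-tessellation of compound space is exposed only as a preprocessing
idea, not a tested path.

## Descriptors

Three descriptor families are built behind one matrix interface:

* **CFP** — chemical fingerprints from SMILES. The linear fingerprint
  hashes every simple path of at most 7 bonds (element symbols and bond
  orders, direction-canonicalized) onto a 2048-bit vector; the Morgan
  fingerprint iteratively re-hashes per-atom invariants (element, degree,
  bond-order sum) with sorted neighbour invariants to radius 4 and folds
  all shells to 2048 bits. The Morgan folded length is a package default
  chosen to match the linear fingerprint length; radius and linear
  parameters follow the values this method was studied with. SMILES
  interpretation is delegated to Open Babel (ChemmineOB); the hashing and
  enumeration are this package's own, deterministic, and invariant to the
  input atom ordering of the same kekulized structure.
* **CIP** — the chemical interaction profile: a vector of combined
  chemical–chemical association scores (integers 0–1000) against an
  ordered reference compound list, looked up symmetrically, zero where no
  record exists. When a query is itself a reference its cell is set to
  1000 (perfect self-association; configurable to 0). The reference list
  is frozen at training time and reused verbatim for test compounds —
  the only choice that keeps train and test descriptors in one feature
  space without leaking test information.
* **CTP** — the chemical–target profile: shared-target counts against the
  reference list, keeping only records with combined score ≥ 700
  (inclusive) and proteins of one organism (human, `9606.`-prefixed, by
  default; the prefix before the first dot is matched).

Unknown query ids simply yield zero rows — a compound absent from an
association dump carries no interaction evidence, which is informative in
itself and should not be fatal.

## The synthetic benchmark

`generate_hierarchy()` draws a valid ATC-grammar tree (default: all 14
letters, two children per node at depths 2–4, hence 112 leaves) whose
per-parent child distributions are Dirichlet with concentration 0.5 —
peaked, as the characteristic-distribution premise demands; the
concentration parameter lets tests take the limit (one dominant child) or
flatten it. `generate_dataset()` attaches compounds (default 20 per leaf,
balanced, so top groups are equiprobable) and features:

* `leaf_gaussian`: each node adds an isotropic Gaussian offset to its
  subtree centroid with sds 6/3/1.8/1.2 at depths 1–4, against
  within-leaf noise of sd 0.25. Offsets comfortably exceed the noise at
  every depth, so all four levels are recoverable and, at zero noise, a
  nearest-neighbour cascade is exact. These are the package's canonical
  study conditions for recovery tests (2240 compounds, a quarter held
  out).
* `context_dependent`: depth-2 codes whose level-2 class is encoded by a
  context block *reused across anatomical groups under different
  mappings* (cyclic shifts), with no feature carrying the group letter.
  With two balanced groups the shifts cancel marginally: a flat level-2
  classifier faces a Bayes ceiling of 50% while a group-conditioned one
  can reach 100%. The level-1 letter must then come from external
  seeding — deliberately so, since the construction isolates the value of
  conditioning itself, mirroring perfect-first-level initialization.

Association tables score same-group pairs around 800 and others around
200 (sd 100, truncated to [0, 1000]); target tables give each group a
disjoint pool of 30 synthetic proteins with per-compound draws of 8 and
scores uniform on [500, 1000], so about half the records survive the
700 filter and cross-group shared-target counts are exactly zero. Setting
the two association means equal removes the CIP signal entirely — the
null case tests that the cascade then falls to chance.

What the generator does *not* emulate: real chemical structure (SMILES
paths are tested on a small bundled list of real molecules instead),
unbalanced and sparse real-world code distributions, correlated
descriptor noise, and compounds carrying multiple codes. Passing the
recovery and separation suites therefore demonstrates the correctness of
the machinery under controlled structure, not expected accuracy on
ChEMBL/STITCH-scale data; the external interfaces accept such data, but
no download is required or attempted.

All generator randomness flows from the mandatory seed through a local
RNG (the caller's `.Random.seed` is untouched), with fixed small offsets
separating the tree, dataset, association and target draws.

## Evaluation protocol choices

Cross-validation assigns instances to folds stratified by level-1 letter
(seeded; `folds = n` degenerates to leave-one-out). The train/test
splitter apportions per-stratum test counts by largest remainder, so the
global fraction is exact — 2232 instances at the default 75/25 give
1674/558. The random-label control permutes whole training codes (keeping
every label a valid code) before training and scores held-out data; on
the balanced 14-group benchmark, level-1 accuracy then sits at the
analytic chance level of 1/14 ≈ 7.1%.

Multi-code compounds are evaluated as expanded (compound, code)
instances by default. How a single predicted path *should* be scored
against several true codes is genuinely underdetermined; the expansion
convention is symmetric with training and keeps the three measures'
identities exact. An "any code correct" per-compound mode is provided
(`evaluate_against_table(..., mode = "any")`) but off by default.

## Problem sizes

The bundled suites run on deliberately compact instances of the study
conditions: metric oracles on 200 random sets of ≤ 20 instances; the
consistency property over three synthetic runs totalling more than
10,000 cascade predictions; nearest-neighbour oracle equivalence on 48
training instances; SVM recovery on the canonical 2240-compound
benchmark; and the context-dependent comparison on 400 compounds. These
sizes were chosen as the smallest at which each property is
statistically unambiguous.

## Known limitations

* The cascade emits exactly one path per compound; there is no
  probability-calibrated multi-path (beam) prediction.
* Fifth-level codes are parsed but never predicted.
* Fingerprints operate on the kekulized molecular graph; tautomers or
  alternative kekulizations of the same aromatic system may fingerprint
  differently, as they would under any bond-order-sensitive scheme.
* No ROC/AUC machinery or significance testing is included; the three
  measures above are the package's scope.
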