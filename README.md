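# tieredatc

Hierarchical prediction of WHO **Anatomical Therapeutic Chemical (ATC)
codes** for small-molecule compounds by *tiered learning*: a top-down
cascade in which a dedicated classifier instance is trained for every ATC
prefix, so that the code predicted at each level selects the classifier
that refines the next one.

ATC codes place a drug in a five-level tree — an anatomical main-group
letter (one of 14: A, B, C, D, G, H, J, L, M, N, P, R, S, V), a two-digit
therapeutic group, two subgroup letters, and a two-digit substance
identifier. Aspirin, for instance, carries both `B01AC06` (antithrombotic)
and `N02BA01` (analgesic). Predicting these codes *in silico* supports
screening-library construction and drug repositioning. The package targets
the first four levels; the fifth merely enumerates substances.

The premise is empirical: each branch of the ATC tree has a
*characteristic* child distribution — activity of one anatomical type
largely precludes others — so conditioning on the higher-level code
shrinks and homogenises the learning problem at the next level. The
package is aimed at cheminformatics researchers who want to train, apply
and rigorously evaluate such cascades, compare them against flat
baselines, and benchmark descriptor choices without first assembling a
large annotated dataset.

## What is implemented

* **Cascade and baseline** — `tiered_train()` fits the per-prefix cascade
  (a classed model with `predict`, `print` and `summary` methods);
  `stp_train()` fits the flat per-level baseline (STP, "standard training
  and prediction"). Level-1 seeding is either a supervised classifier
  (`init = "supervised"`) or an external compound-to-letter map
  (`init_external()`). Pluggable learner families via `base_learner()`:
  naive Bayes, MLP, SVM, random forest, plus majority and k-NN baselines.
* **Descriptors** — chemical fingerprints from SMILES (hashed linear paths,
  default length 2048 / path size 7 bonds; Morgan neighbourhoods, default
  radius 4 folded to 2048 bits); chemical interaction profiles (CIP:
  combined association scores 0–1000 against a frozen reference compound
  list, zero where unknown); chemical–target profiles (CTP: shared-target
  counts restricted to combined scores ≥ 700 and one organism, human by
  default). STITCH-dialect TSV readers/writers, gzip-transparent.
* **Evaluation** — per-level accuracy A(k), cumulative accuracy
  CA(k) = (1/k)·Σ<sub>j≤k</sub> A(j), and the path-correct measure N(k),
  with stratified k-fold cross-validation (`cross_validate()`) and a
  random-label control (`random_label_control()`).
* **Synthetic benchmark** — `generate_hierarchy()` / `generate_dataset()`
  build valid ATC-grammar code trees with characteristic (Dirichlet) child
  distributions, Gaussian or context-dependent feature models, and
  matching association/target tables, so every pipeline stage is testable
  offline.
* **Command line** — `cli_main()` (and the installed
  `inst/cli/tieredatc.R` script) exposes `simulate`, `build-descriptors`,
  `train`, `predict`, `evaluate`, `crossval` and `control` subcommands
  with YAML/JSON configs and provenance records.

## Worked example

```r
library(tieredatc)

sc   <- synthetic_config(n_top = 6, n_per_leaf = 12, noise_sd = 3, seed = 42)
tree <- generate_hierarchy(sc)
sim  <- generate_dataset(tree, sc)
sp   <- split_dataset(sim$codes, seed = 42)          # stratified 75/25

fit  <- tiered_train(sim$x[sp$train, ], sim$codes[sp$train],
                     learner = base_learner("svm"))
fit
#> Tiered ATC classifier
#>   learner: svm; initializer: supervised; max level: 4
#>   432 instances, 16 features, 42 prefix nodes (0 constant)

pred <- predict(fit, sim$x[sp$test, ])
head(pred[, c("id", "path")], 3)
#>          id  path
#> 1 SYNC00003 A01AA
#> 2 SYNC00005 A01AA
#> 3 SYNC00018 A01AB

evaluate_predictions(pred, sim$codes[sp$test])
#> ATC prediction evaluation (TL), 144 instance(s)
#>  level   n    A(k)   CA(k)          N(k)
#>      1 144 100.00% 100.00% 100.00% (144)
#>      2 144  99.31%  99.65%  99.31% (143)
#>      3 144  93.06%  97.45%  92.36% (133)
#>      4 144  68.75%  90.28%   64.58% (93)
```

Reading the report: A(k) is the share of (compound, code) instances whose
predicted level-k *component* is correct regardless of the other levels;
CA(k) averages A(1)..A(k); N(k) counts instances whose whole prefix
through level k is right — here 93 of the 144 held-out instances carry a
fully correct four-level code, and accuracy decays with depth as the
classes multiply.

On real data, build descriptors from your own tables instead of the
simulator: `build_cfp()` on SMILES, or `build_cip()` / `build_ctp()` on
STITCH-style dumps read with `read_stitch_associations()` /
`read_stitch_targets()`.

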