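test_that("the code tree has the configured shape and valid codes", {
  sc <- synthetic_config(seed = 1)
  tree <- generate_hierarchy(sc)
  expect_length(tree$leaves, 14 * 2 * 2 * 2)  # 112 leaves
  expect_equal(parse_atc(tree$leaves)$raw, tree$leaves)
  expect_equal(sum(tree$leaf_prob), 1, tolerance = 1e-9)

  tree2 <- generate_hierarchy(sc)
  expect_identical(tree, tree2)  # same seed, same tree

  sc3 <- synthetic_config(n_top = 3, children = c(4L, 2L, 3L), seed = 2)
  expect_length(generate_hierarchy(sc3)$leaves, 3 * 4 * 2 * 3)
})

test_that("small concentrations give each parent one dominant child", {
  sc <- synthetic_config(n_top = 6, concentration = 1e-4, seed = 5)
  tree <- generate_hierarchy(sc)
  for (letter in tree$letters) {
    p <- tree$leaf_prob[startsWith(names(tree$leaf_prob), letter)]
    byl2 <- tapply(p, substr(names(p), 1, 3), sum) / sum(p)
    expect_gte(max(byl2), 0.99)
  }
  # a moderate concentration is still clearly peaked on average
  scm <- synthetic_config(n_top = 14, concentration = 0.5, seed = 6)
  trm <- generate_hierarchy(scm)
  dom <- vapply(trm$letters, function(letter) {
    p <- trm$leaf_prob[startsWith(names(trm$leaf_prob), letter)]
    max(tapply(p, substr(names(p), 1, 3), sum) / sum(p))
  }, 0)
  expect_gt(mean(dom), 0.6)
})

test_that("datasets are seed-reproducible with balanced groups", {
  sc <- synthetic_config(n_top = 5, n_per_leaf = 3, seed = 11)
  tree <- generate_hierarchy(sc)
  s1 <- generate_dataset(tree, sc)
  s2 <- generate_dataset(tree, sc)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$codes, s2$codes)
  expect_equal(nrow(s1$x), 3 * length(tree$leaves))
  # balanced assignment: equiprobable top groups
  expect_true(all(table(substr(s1$codes, 1, 1)) == 3 * 8))
})

test_that("characteristic assignment follows the tree's distributions", {
  sc <- synthetic_config(n_top = 3, n_per_leaf = 400, feature_dim = 2,
                         assignment = "characteristic", seed = 31)
  tree <- generate_hierarchy(sc)
  sim <- generate_dataset(tree, sc)  # ~9600 compounds
  counts <- table(factor(sim$codes, levels = tree$leaves))
  gof <- suppressWarnings(
    chisq.test(as.vector(counts), p = tree$leaf_prob / sum(tree$leaf_prob)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("zero-noise gaussian leaves are exactly recoverable", {
  sc <- synthetic_config(n_top = 3, n_per_leaf = 2, noise_sd = 0, seed = 13)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  fit <- tiered_train(sim$x, sim$codes, base_learner("knn"))
  expect_equal(predict(fit, sim$x)$path, substr(sim$codes, 1, 5))
})

test_that("association scores track branch membership and stay in range", {
  sc <- synthetic_config(n_top = 3, n_per_leaf = 2, seed = 17)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  assoc <- generate_association_table(sim)
  expect_true(all(assoc$combined_score >= 0 & assoc$combined_score <= 1000))
  letter <- setNames(substr(sim$codes, 1, 1), sim$compounds$id)
  same <- letter[assoc$chemical_a] == letter[assoc$chemical_b]
  expect_gt(mean(assoc$combined_score[same]),
            mean(assoc$combined_score[!same]) + 300)

  a2 <- generate_association_table(sim)
  expect_identical(assoc, a2)
})

test_that("a signal-free association table drops tiered accuracy to chance", {
  sc <- synthetic_config(n_top = 4, n_per_leaf = 4,
                         within_branch_score = 500, cross_branch_score = 500,
                         seed = 41)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  assoc <- generate_association_table(sim)
  sp <- split_dataset(sim$codes, train_fraction = 0.5, seed = 41)
  ids <- sim$compounds$id
  refs <- ids[sp$train]
  cfg <- descriptor_config("cip", cip_self_score = 0)
  xtr <- unclass(build_cip(ids[sp$train], assoc, refs, cfg))
  xts <- unclass(build_cip(ids[sp$test], assoc, refs, cfg))
  fit <- tiered_train(xtr, sim$codes[sp$train], base_learner("knn"))
  a1 <- accuracy_at_level(predict(fit, xts), sim$codes[sp$test], 1)
  expect_lt(a1, 100 / 4 + 25)  # chance is 25% over 4 balanced groups
})

test_that("disjoint branch protein pools leave cross-branch CTP cells at zero", {
  sc <- synthetic_config(n_top = 3, n_per_leaf = 2, seed = 19)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  tg <- generate_target_table(sim)
  expect_true(all(tg$combined_score >= 0 & tg$combined_score <= 1000))
  ids <- sim$compounds$id
  ctp <- build_ctp(ids, tg, ids)
  letter <- substr(sim$codes, 1, 1)
  cross <- outer(letter, letter, "!=")
  expect_true(all(unclass(ctp)[cross] == 0L))
  # within-branch sharing exists
  expect_gt(sum(unclass(ctp)[!cross & upper.tri(cross)]), 0)
})

test_that("generated tables round-trip through the writers and readers", {
  sc <- synthetic_config(n_top = 2, n_per_leaf = 2, seed = 3)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  assoc <- generate_association_table(sim)
  tg <- generate_target_table(sim)

  ap <- tempfile(fileext = ".tsv")
  write_stitch_associations(assoc, ap)
  expect_equal(as.data.frame(read_stitch_associations(ap)),
               as.data.frame(assoc))

  tp <- tempfile(fileext = ".tsv.gz")
  write_stitch_targets(tg, tp)
  back <- as.data.frame(read_stitch_targets(tp))
  rownames(back) <- NULL; tg2 <- as.data.frame(tg); rownames(tg2) <- NULL
  expect_equal(back, tg2)

  cp <- tempfile(fileext = ".tsv")
  write_compound_table(sim$compounds, cp)
  expect_equal(read_compound_table(cp)$atc_codes, sim$compounds$atc_codes)
})

test_that("the configuration is validated", {
  expect_error(synthetic_config(), "mandatory")
  expect_error(synthetic_config(n_top = 0, seed = 1))
  expect_error(synthetic_config(within_branch_score = 2000, seed = 1))
})
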