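# Small separable benchmark shared by several blocks.
sep_sim <- function(seed = 21, n_top = 4, n_per_leaf = 6, noise_sd = 0.25) {
  sc <- synthetic_config(n_top = n_top, n_per_leaf = n_per_leaf,
                         noise_sd = noise_sd, seed = seed)
  generate_dataset(generate_hierarchy(sc), sc)
}

test_that("the supervised initializer learns separable level-1 classes", {
  sim <- sep_sim()
  sp <- split_dataset(sim$codes, seed = 1)
  init <- init_supervised(sim$x[sp$train, ], sim$codes[sp$train],
                          base_learner("svm"))
  pred <- tieredatc:::predict_initializer(init, sim$x[sp$test, ],
                                          rownames(sim$x)[sp$test])
  truth <- substr(sim$codes[sp$test], 1, 1)
  expect_gte(100 * mean(pred == truth), 95)

  # single-class training degenerates to a constant predictor
  expect_warning(
    cinit <- init_supervised(matrix(rnorm(10), 5), rep("A01", 5),
                             base_learner("svm")),
    "single level-1 class")
  expect_equal(unique(tieredatc:::predict_initializer(
    cinit, matrix(0, 2, 2), c("a", "b"))), "A")
})

test_that("external seeding looks ids up and applies the missing policy", {
  sim <- sep_sim(seed = 4, n_top = 3, n_per_leaf = 3)
  map <- setNames(substr(sim$codes, 1, 1), sim$compounds$id)
  init <- init_external(map)
  got <- tieredatc:::predict_initializer(init, sim$x, sim$compounds$id)
  expect_equal(got, unname(map))

  # perfect seeding gives A(1) = 100%
  fit <- tiered_train(sim$x, sim$codes, base_learner("majority"), init = init)
  pred <- predict(fit, sim$x)
  expect_equal(accuracy_at_level(pred, sim$codes, 1), 100)

  # empty map with the abstain policy predicts nothing
  none <- init_external(setNames(character(0), character(0)))
  expect_true(all(is.na(tieredatc:::predict_initializer(
    none, sim$x[1:3, ], c("u1", "u2", "u3")))))

  expect_error(init_external(c(c1 = "Z")), "anatomical group letter")
})

test_that("an external seed from a level-1 flat run equals supervised init", {
  sim <- sep_sim(seed = 31, n_top = 3, n_per_leaf = 4)
  sp <- split_dataset(sim$codes, seed = 2)
  xtr <- sim$x[sp$train, ]; xts <- sim$x[sp$test, ]
  stp <- stp_train(xtr, sim$codes[sp$train], base_learner("knn"), levels = 1)
  l1 <- predict(stp, xts)$L1
  init <- init_supervised(xtr, sim$codes[sp$train], base_learner("knn"))
  expect_equal(tieredatc:::predict_initializer(init, xts, rownames(xts)), l1)
})

test_that("node models exist exactly for observed parents and stay pure", {
  x <- matrix(rnorm(12), 6, 2)
  codes <- c("A01", "A01", "A02", "A02", "B01", "B01")
  fit <- tiered_train(x, codes, base_learner("majority"), max_level = 2)
  expect_setequal(names(fit$nodes), c("A", "B"))
  expect_setequal(fit$node_meta[["A"]]$classes, c("01", "02"))
  # node B sees a single child: trivial constant model
  expect_true(fit$node_meta[["B"]]$constant)
  # node purity: every instance used at a node has that true prefix
  for (p in names(fit$node_meta)) {
    rows <- fit$node_meta[[p]]$rows
    expect_true(all(startsWith(codes[rows], p)))
  }
  expect_error(tiered_train(x[0, , drop = FALSE], character(0)),
               "empty training set")
})

test_that("undersized nodes fall back to constant majority-child models", {
  x <- matrix(seq_len(10), ncol = 1)
  codes <- c("A01", "A02", "A02", "B01", "B02", "B01", "B02", "B01",
             "B01", "B01")
  fit <- tiered_train(x, codes, base_learner("svm"), max_level = 2,
                      min_node_size = 5)
  expect_true(fit$node_meta[["A"]]$constant)    # 3 < 5 instances
  expect_false(fit$node_meta[["B"]]$constant)   # 7 instances, 2 classes
  p <- predict(fit, matrix(c(1, 2), ncol = 1))
  expect_equal(p$L2[p$L1 == "A"], rep("02", sum(p$L1 == "A")))
})

test_that("the cascade selects the node addressed by the realized prefix", {
  # predicted "A" then "02" must route level 3 through the A02 node
  sim <- sep_sim(seed = 9, n_top = 2, n_per_leaf = 5, noise_sd = 0)
  fit <- tiered_train(sim$x, sim$codes, base_learner("knn"))
  expect_true(all(c("A", "B") %in%
                    names(Filter(function(m) m$depth == 1, fit$node_meta))))
  d2 <- names(Filter(function(m) m$depth == 2, fit$node_meta))
  expect_true(all(nchar(d2) == 3))
  pred <- predict(fit, sim$x)
  # zero noise: every path is recovered exactly
  expect_equal(pred$path, substr(sim$codes, 1, 5))
  # and predicted prefixes extend level by level
  expect_equal(substr(pred$path, 1, 1), pred$L1)
  expect_equal(substr(pred$path, 2, 3), pred$L2)
})

test_that("predictions are hierarchy-consistent; the flat baseline need not be", {
  sim <- sep_sim(seed = 13, n_top = 4, n_per_leaf = 5, noise_sd = 3)
  sp <- split_dataset(sim$codes, seed = 13)
  tl <- tiered_train(sim$x[sp$train, ], sim$codes[sp$train],
                     base_learner("naive_bayes"))
  ptl <- predict(tl, sim$x[sp$test, ])
  expect_true(all(hierarchy_consistent(ptl, sim$codes[sp$train])))

  # deterministic flat violation: the level-2 model only ever saw "01"
  # under B, yet level 1 routes the test point to A
  x <- matrix(c(0, 1), ncol = 1)
  stp <- stp_train(x, c("A", "B01"), base_learner("knn"), levels = 2)
  p <- predict(stp, matrix(0, ncol = 1))
  expect_equal(p$path, "A01")
  expect_false(hierarchy_consistent(p, c("A", "B01")))
})

test_that("unseen prefixes resolve by fallback policy", {
  x <- matrix(c(1, 1.1, 5, 5.1), ncol = 1)
  codes <- c("A01AA", "A01AB", "A02BA", "A02BB")
  # external seed letter N never occurs in training: no node exists
  fit <- tiered_train(x, codes, base_learner("knn"),
                      init = init_external(c(t1 = "N")))
  p <- predict(fit, matrix(1, 1, 1, dimnames = list("t1", NULL)))
  # parent-majority walks to the root: majority level-2 under "" is 01/02
  # tie -> "01", then majority under descent
  expect_equal(p$L1, "N")
  expect_equal(p$L2, "01")
  expect_false(is.na(p$L4))

  fita <- tiered_train(x, codes, base_learner("knn"),
                       init = init_external(c(t1 = "N")),
                       fallback = "abstain")
  pa <- predict(fita, matrix(1, 1, 1, dimnames = list("t1", NULL)))
  expect_equal(pa$L1, "N")
  expect_true(all(is.na(c(pa$L2, pa$L3, pa$L4))))
  expect_equal(pa$path, "N")
})

test_that("a majority cascade reproduces the chain of conditional modes", {
  codes <- c("A01AA", "A01AA", "A01AB", "A02BA",
             "B01AA", "B01AA", "B01AA", "A01AA")
  x <- matrix(0, length(codes), 2)
  fit <- tiered_train(x, codes, base_learner("majority"))
  p <- predict(fit, matrix(0, 1, 2))
  # exhaustive enumeration of conditional modes: A (5>3), then 01 (4>1),
  # then A (4), then A (3>1)
  parsed <- parse_atc(codes)
  path <- ""
  for (k in 1:4) {
    nd <- class_distribution(codes, path)
    ch <- nd$children
    path <- paste0(path, names(ch)[order(-ch, names(ch))][1])
  }
  expect_equal(p$path, path)
  expect_equal(p$path, "A01AA")
})

test_that("identical inputs and seeds give identical models and predictions", {
  sim <- sep_sim(seed = 17, n_top = 3, n_per_leaf = 4)
  for (fam in c("random_forest", "mlp", "svm")) {
    f1 <- tiered_train(sim$x, sim$codes, base_learner(fam, seed = 5))
    f2 <- tiered_train(sim$x, sim$codes, base_learner(fam, seed = 5))
    expect_identical(predict(f1, sim$x), predict(f2, sim$x))
  }
})

test_that("feature-dimension mismatches are refused", {
  sim <- sep_sim(seed = 2, n_top = 2, n_per_leaf = 3)
  fit <- tiered_train(sim$x, sim$codes, base_learner("majority"))
  expect_error(predict(fit, sim$x[, 1:3]), "dimension mismatch")
  stp <- stp_train(sim$x, sim$codes, base_learner("majority"))
  expect_error(predict(stp, sim$x[, 1:3]), "dimension mismatch")
})

test_that("model bundles round-trip and reject foreign versions", {
  sim <- sep_sim(seed = 3, n_top = 2, n_per_leaf = 3)
  fit <- tiered_train(sim$x, sim$codes, base_learner("knn"))
  dir <- file.path(tempdir(), "bundle-test")
  save_model(fit, dir)
  back <- load_model(dir)
  expect_identical(predict(back, sim$x), predict(fit, sim$x))

  meta <- jsonlite::read_json(file.path(dir, "bundle.json"))
  meta$version <- 99L
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "version")
  expect_error(load_model(tempdir()), "not a model bundle")
})
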