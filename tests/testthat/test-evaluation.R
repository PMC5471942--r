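test_that("A(k) matches the level component regardless of other levels", {
  truth <- c("A01", "A02", "B01")
  pred <- make_prediction(1:3, L1 = c("A", "A", "A"),
                          L2 = c("01", "01", "01"))
  # level-2 match is on the component: A01 and B01 both match "01"
  expect_equal(accuracy_at_level(pred, truth, 2), 100 * 2 / 3)
  # B01's level-1 letter is wrong
  expect_equal(accuracy_at_level(pred, truth, 1), 100 * 2 / 3)
  expect_error(accuracy_at_level(pred, truth, 5), "between 1 and 4")
  expect_error(accuracy_at_level(pred, truth, 0), "between 1 and 4")

  # abstentions count as wrong
  pna <- make_prediction(1:3, L1 = c("A", NA, "B"), L2 = c("01", NA, "01"))
  expect_equal(accuracy_at_level(pna, truth, 1), 100 * 2 / 3)
})

test_that("cumulative accuracy is the running mean of per-level accuracies", {
  expect_equal(cumulative_accuracy(c(100, 79.03)), 89.52)
  expect_equal(cumulative_accuracy(c(77.95, 60.22)), 69.09)
  expect_equal(cumulative_accuracy(60.22), 60.22)
  expect_equal(cumulative_accuracy(c(100, 79.03), digits = NULL),
               mean(c(100, 79.03)))
  expect_error(cumulative_accuracy(numeric(0)), "non-empty")
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(89.515), 89.52)
  expect_equal(round_half_up(69.085), 69.09)
  expect_equal(round_half_up(70.295), 70.30)
  expect_equal(round_half_up(-1.005), -1.01)
  expect_equal(round_half_up(2.344), 2.34)
})

test_that("N(k) requires every level through k to be correct", {
  truth <- c("A01", "A02")
  pred <- make_prediction(1:2, L1 = c("A", "B"), L2 = c("01", "02"))
  n1 <- correct_to_level(pred, truth, 1)
  n2 <- correct_to_level(pred, truth, 2)
  expect_equal(n1$percent, 50)
  expect_equal(n2$percent, 50)
  expect_equal(n2$count, 1L)
  expect_equal(n2$n, 2L)
})

test_that("full reports satisfy the measure identities", {
  set.seed(8)
  for (rep in 1:5) {
    truth <- vapply(1:30, function(i) rand_code(sample(2:5, 1)), "")
    tp <- parse_atc(truth)
    comp <- tp$components
    flip <- matrix(runif(length(comp)) < 0.4, nrow(comp))
    comp[flip] <- "ZZ"
    pred <- make_prediction(1:30, comp[, 1], comp[, 2], comp[, 3], comp[, 4])
    ev <- evaluate_predictions(pred, truth)
    lv <- ev$levels
    for (k in which(!is.nan(lv$A))) {
      expect_equal(lv$CA[k], mean(lv$A[1:k]))
      expect_lte(lv$CA[k], max(lv$A[1:k]) + 1e-12)
      expect_gte(lv$CA[k], min(lv$A[1:k]) - 1e-12)
    }
    expect_equal(lv$A[1], lv$CA[1])
    expect_equal(lv$A[1], lv$N[1])
    expect_true(all(diff(lv$N_count) <= 0))
    expect_true(all(lv$N_count <= lv$A_count))
  }
})

test_that("reports serialize to JSON and TSV", {
  truth <- c("A01AA01", "B01AC06")
  pred <- make_prediction(1:2, c("A", "B"), c("01", "01"), c("A", "A"),
                          c("A", "C"))
  ev <- evaluate_predictions(pred, truth)
  jp <- tempfile(fileext = ".json")
  write_eval_json(ev, jp, config = list(seed = 1))
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$levels$A, ev$levels$A)
  expect_equal(back$config$seed, 1)

  tp <- tempfile(fileext = ".tsv")
  write_eval_tsv(ev, tp)
  long <- read.delim(tp)
  expect_equal(nrow(long), 12L)  # 4 levels x 3 metrics
  expect_setequal(unique(long$metric), c("A", "CA", "N"))
})

test_that("multi-code compounds score per instance, or once under any-code", {
  compounds <- data.frame(id = c("asp", "eth"),
                          atc_codes = c("B01AC06;N02BA01", "V03AB16"))
  pred <- make_prediction(c("asp", "eth"),
                          L1 = c("B", "V"), L2 = c("01", "03"),
                          L3 = c("A", "A"), L4 = c("C", "B"))
  inst <- evaluate_against_table(pred, compounds)
  # 3 instances; the N02BA01 instance is wrong at every level
  expect_equal(inst$levels$n[1], 3)
  expect_equal(inst$levels$A[1], 100 * 2 / 3)
  anyc <- evaluate_against_table(pred, compounds, mode = "any")
  # 2 compounds; aspirin matches one of its codes fully
  expect_equal(anyc$levels$n[1], 2)
  expect_equal(anyc$levels$A[1], 100)
  expect_equal(anyc$levels$N[4], 100)
})

test_that("cross-validation is stratified, seeded, and learns separable data", {
  sc <- synthetic_config(n_top = 4, n_per_leaf = 6, seed = 19)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  cv1 <- cross_validate(sim$x, sim$codes, base_learner("knn"), folds = 3,
                        seed = 77)
  cv2 <- cross_validate(sim$x, sim$codes, base_learner("knn"), folds = 3,
                        seed = 77)
  expect_identical(cv1$mean$levels, cv2$mean$levels)
  expect_gte(cv1$mean$levels$A[1], 95)
  expect_equal(length(cv1$fold_reports), 3L)
  # every instance is scored exactly once across folds
  expect_equal(cv1$mean$n_instances, nrow(sim$x))

  # leave-one-out degenerate case runs
  tiny <- sim$x[1:8, ]; tcodes <- sim$codes[1:8]
  # (a single level-1 class in these folds rightly warns of a constant
  # initializer)
  loo <- suppressWarnings(
    cross_validate(tiny, tcodes, base_learner("majority"), folds = 8,
                   seed = 1))
  expect_equal(loo$mean$n_instances, 8L)
})

test_that("permuting training labels collapses accuracy on separable data", {
  sc <- synthetic_config(n_top = 6, n_per_leaf = 8, seed = 23)
  sim <- generate_dataset(generate_hierarchy(sc), sc)
  sp <- split_dataset(sim$codes, seed = 23)
  fit <- tiered_train(sim$x[sp$train, ], sim$codes[sp$train],
                      base_learner("knn"))
  honest <- evaluate_predictions(predict(fit, sim$x[sp$test, ]),
                                 sim$codes[sp$test])
  null <- random_label_control(sim$x, sim$codes, base_learner("knn"),
                               seed = 23)
  expect_lt(null$levels$A[1], honest$levels$A[1])
  expect_gte(honest$levels$A[1], 95)
})
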