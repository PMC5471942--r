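# Shared fixtures and independent oracles used across the suite.

# Construct an atc_prediction object directly from per-level components
# (the contract of the prediction container), for metric tests that do not
# need a fitted model.
make_prediction <- function(ids, L1 = NA, L2 = NA, L3 = NA, L4 = NA,
                            mode = "test") {
  n <- length(ids)
  comp <- cbind(L1 = rep_len(as.character(L1), n),
                L2 = rep_len(as.character(L2), n),
                L3 = rep_len(as.character(L3), n),
                L4 = rep_len(as.character(L4), n))
  path <- vapply(seq_len(n), function(i) {
    r <- comp[i, ]
    stop_at <- which(is.na(r))
    if (length(stop_at)) r <- r[seq_len(stop_at[1] - 1)]
    paste(r, collapse = "")
  }, "")
  structure(data.frame(id = as.character(ids), comp, path = path,
                       stringsAsFactors = FALSE),
            mode = mode, max_level = 4L,
            class = c("atc_prediction", "data.frame"))
}

# Exhaustive per-instance recount of A(k), CA(k), N(k): a from-first-
# principles oracle, written as plain loops so it shares nothing with the
# package implementation.
recount_metrics <- function(pred, truth_codes) {
  comp_true <- lapply(truth_codes, function(code) atc_levels(parse_atc(code)))
  out <- list()
  for (k in 1:4) {
    hits <- 0L; path_hits <- 0L; n <- 0L
    for (i in seq_along(truth_codes)) {
      tr <- comp_true[[i]]
      if (length(tr) < k) next
      n <- n + 1L
      pk <- pred[[paste0("L", k)]][i]
      if (!is.na(pk) && pk == tr[k]) hits <- hits + 1L
      all_ok <- TRUE
      for (j in 1:k) {
        pj <- pred[[paste0("L", j)]][i]
        if (is.na(pj) || pj != tr[j]) { all_ok <- FALSE; break }
      }
      if (all_ok) path_hits <- path_hits + 1L
    }
    out[[k]] <- list(A = 100 * hits / n, N = 100 * path_hits / n,
                     N_count = path_hits, n = n)
  }
  for (k in 1:4) {
    out[[k]]$CA <- mean(vapply(1:k, function(j) out[[j]]$A, 0))
  }
  out
}

# Brute-force tiered 1-NN path oracle: level 1 is the label of the nearest
# training instance overall; each later level is the next component of the
# nearest training instance among those whose true code extends the path
# realized so far. Ties break to the lexicographically smallest label.
oracle_nn_path <- function(train_x, train_codes, test_x, max_level = 4) {
  parsed <- parse_atc(train_codes)
  widths <- c(1, 3, 4, 5)
  t(apply(test_x, 1, function(row) {
    d <- sqrt(rowSums((train_x - matrix(row, nrow(train_x), ncol(train_x),
                                        byrow = TRUE))^2))
    path <- character(0)
    for (k in 1:max_level) {
      if (k == 1) {
        cand <- seq_along(train_codes)
      } else {
        pfx <- paste(path, collapse = "")
        cand <- which(parsed$depth >= k &
                        substr(parsed$raw, 1, nchar(pfx)) == pfx)
      }
      labs <- parsed$components[cand, k]
      best <- cand[order(d[cand], labs)][1]
      path <- c(path, parsed$components[best, k])
    }
    path
  }))
}

# A random valid ATC code of the given depth.
rand_code <- function(depth) {
  parts <- c(sample(c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                      "P", "R", "S", "V"), 1),
             sprintf("%02d", sample(99, 1)),
             sample(LETTERS, 1), sample(LETTERS, 1),
             sprintf("%02d", sample(99, 1)))
  paste(parts[seq_len(depth)], collapse = "")
}

example_smiles <- function() {
  read_smiles_file(system.file("extdata", "example_compounds.smi",
                               package = "tieredatc"))
}

toy_targets <- function() {
  data.frame(
    chemical = c("c1", "c1", "c2", "c2", "c3", "c1"),
    protein = c("9606.p1", "9606.p2", "9606.p1", "9606.p2", "9606.p1",
                "10090.p3"),
    combined_score = c(700L, 900L, 699L, 800L, 750L, 990L),
    stringsAsFactors = FALSE)
}
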