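# Synthetic ATC-like benchmarks.
#
# The generator emulates the statistical structure that motivates
# prefix-conditioned prediction: every branch of the hierarchy has a
# characteristic (peaked) child distribution, and compound features carry
# branch information at every level. It produces valid ATC-grammar code
# trees, labelled compounds with feature vectors, and STITCH-dialect
# association / target tables, so the full pipeline is exercisable with no
# external data.

#' Synthetic benchmark configuration
#'
#' @param n_top number of level-1 anatomical groups (default 14, the full
#'   WHO set).
#' @param children integer vector of children per node at depths 2..4
#'   (default `c(2, 2, 2)`).
#' @param concentration Dirichlet concentration of each parent's child
#'   distribution (default 0.5; smaller is more peaked / "characteristic",
#'   large is near-uniform). Only used with `assignment = "characteristic"`.
#' @param n_per_leaf compounds per leaf (default 20).
#' @param assignment `"balanced"` (exactly `n_per_leaf` per leaf, so top
#'   groups are equiprobable) or `"characteristic"` (leaves drawn from the
#'   tree's child distributions).
#' @param feature_model `"leaf_gaussian"` (each hierarchy node adds a
#'   Gaussian offset to its subtree's feature centroid, so every level is
#'   linearly recoverable) or `"context_dependent"` (depth-2 codes whose
#'   level-2 class is encoded by a feature block *reused across anatomical
#'   groups with different meanings*; see [generate_dataset()]).
#' @param feature_dim feature dimensionality (default 16).
#' @param noise_sd within-leaf feature noise (default 0.25).
#' @param level_scales sd of the per-node centroid offsets at depths 1..4
#'   (default `c(6, 3, 1.8, 1.2)`, comfortably above `noise_sd` at every
#'   depth).
#' @param within_branch_score mean association score for same-group pairs
#'   (default 800).
#' @param cross_branch_score mean association score for other pairs
#'   (default 200).
#' @param score_sd association score spread (default 100).
#' @param target_pool_size proteins in each group's target pool (default 30).
#' @param targets_per_compound protein interactions drawn per compound
#'   (default 8).
#' @param distinct_children give sibling sets different component labels
#'   across parents (default `FALSE`: every parent reuses the same labels,
#'   e.g. level-2 groups `01`/`02` under every letter). With distinct
#'   labels a flat per-level classifier can combine a letter with a
#'   component never observed under it, which the tiered cascade cannot.
#' @param organism organism prefix for generated protein ids (default
#'   `"9606"`).
#' @param seed integer seed (mandatory; all generator randomness flows from
#'   it, with no global RNG state left behind).
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_top = 14L, children = c(2L, 2L, 2L),
                             concentration = 0.5, n_per_leaf = 20L,
                             assignment = c("balanced", "characteristic"),
                             feature_model = c("leaf_gaussian",
                                               "context_dependent"),
                             feature_dim = 16L, noise_sd = 0.25,
                             level_scales = c(6, 3, 1.8, 1.2),
                             within_branch_score = 800,
                             cross_branch_score = 200, score_sd = 100,
                             target_pool_size = 30L,
                             targets_per_compound = 8L,
                             distinct_children = FALSE,
                             organism = "9606", seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  assignment <- match.arg(assignment)
  feature_model <- match.arg(feature_model)
  stopifnot(n_top >= 1L, n_top <= 14L, length(children) == 3L,
            all(children >= 1L), n_per_leaf >= 1L, feature_dim >= 1L,
            noise_sd >= 0, concentration > 0,
            within_branch_score >= 0, within_branch_score <= 1000,
            cross_branch_score >= 0, cross_branch_score <= 1000)
  structure(list(n_top = as.integer(n_top), children = as.integer(children),
                 concentration = concentration,
                 n_per_leaf = as.integer(n_per_leaf),
                 assignment = assignment, feature_model = feature_model,
                 feature_dim = as.integer(feature_dim), noise_sd = noise_sd,
                 level_scales = level_scales,
                 within_branch_score = within_branch_score,
                 cross_branch_score = cross_branch_score,
                 score_sd = score_sd,
                 target_pool_size = as.integer(target_pool_size),
                 targets_per_compound = as.integer(targets_per_compound),
                 distinct_children = isTRUE(distinct_children),
                 organism = organism, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic ATC-grammar code tree
#'
#' Builds a four-level hierarchy of valid ATC-grammar codes: `n_top`
#' anatomical letters, each with `children[1]` two-digit therapeutic
#' groups, `children[2]` subgroup letters and `children[3]`
#' chemical-subgroup letters. Each parent's child distribution is drawn
#' from a Dirichlet with the configured concentration, so small
#' concentrations give each parent one dominant child -- the characteristic
#' distributions that make prefix conditioning informative.
#'
#' @param config a [synthetic_config()].
#' @return object of class `"atc_tree"`: list with `leaves` (depth-4
#'   codes), `leaf_prob` (per-leaf probability under the characteristic
#'   distributions) and `letters`.
#' @export
generate_hierarchy <- function(config) {
  letters14 <- ATC_LETTERS[seq_len(config$n_top)]
  m <- config$children
  if (config$distinct_children) {
    # offset each parent's label set so siblings of different parents get
    # different component labels (two-digit labels wrap at 99, letters at Z)
    leaves <- character(0)
    for (i in seq_along(letters14)) {
      l2 <- sprintf("%02d", (((i - 1L) * m[1L] + seq_len(m[1L]) - 1L) %% 99L) + 1L)
      for (j in seq_along(l2)) {
        l3 <- LETTERS[(((i * 7L + j) + seq_len(m[2L]) - 2L) %% 26L) + 1L]
        for (k in seq_along(l3)) {
          l4 <- LETTERS[(((i * 3L + j * 5L + k) + seq_len(m[3L]) - 2L) %% 26L) + 1L]
          leaves <- c(leaves, paste0(letters14[i], l2[j], l3[k], l4))
        }
      }
    }
  } else {
    l2 <- sprintf("%02d", seq_len(m[1L]))
    l3 <- LETTERS[seq_len(m[2L])]
    l4 <- LETTERS[seq_len(m[3L])]
    leaves <- as.vector(outer(outer(outer(letters14, l2, paste0),
                                    l3, paste0), l4, paste0))
  }
  leaves <- sort(leaves)
  rdirichlet1 <- function(k) {
    g <- rgamma(k, shape = config$concentration)
    if (!all(is.finite(g)) || sum(g) <= 0) {
      # gamma draws underflow at very small concentrations: the limit is a
      # single dominant child, so emit a one-hot distribution
      g <- as.numeric(seq_len(k) == sample.int(k, 1L))
    }
    g / sum(g)
  }
  # per-parent Dirichlet child distributions, multiplied down the paths;
  # top-level groups are equiprobable
  leaf_prob <- with_local_seed(config$seed, {
    pr <- setNames(rep(1 / config$n_top, length(leaves)), leaves)
    for (d in 1:3) {
      pref <- substr(leaves, 1L, ATC_WIDTHS[d])
      child <- substr(leaves, ATC_WIDTHS[d] + 1L, ATC_WIDTHS[d + 1L])
      for (pp in sort(unique(pref))) {
        rows <- pref == pp
        kids <- sort(unique(child[rows]))
        p <- setNames(rdirichlet1(length(kids)), kids)
        pr[rows] <- pr[rows] * p[child[rows]]
      }
    }
    pr
  })
  parse_atc(leaves)  # every emitted code passes the grammar
  structure(list(leaves = leaves, leaf_prob = leaf_prob,
                 letters = letters14, config = config),
            class = "atc_tree")
}

#' @export
print.atc_tree <- function(x, ...) {
  cat(sprintf("<atc_tree> %d top group(s), %d leaves to depth 4\n",
              length(x$letters), length(x$leaves)))
  invisible(x)
}

#' Generate a labelled synthetic compound set with features
#'
#' Under `feature_model = "leaf_gaussian"`, every hierarchy node adds an
#' isotropic Gaussian offset (sd `level_scales[depth]`) to its subtree's
#' centroid and compounds scatter around their leaf centroid with sd
#' `noise_sd`; all four levels are then recoverable from the features, and
#' at `noise_sd = 0` a nearest-neighbour cascade recovers every path
#' exactly.
#'
#' Under `feature_model = "context_dependent"`, compounds carry depth-2
#' codes and the features encode only a within-group context block: context
#' code c maps to the level-2 class by a cyclic shift that differs per
#' anatomical group, and no feature carries the group letter itself. With
#' two groups the two shifts cancel marginally, so a flat level-2
#' classifier faces a Bayes accuracy of at most 50% while a
#' group-conditioned classifier can reach 100%. This isolates, by
#' construction, the benefit of conditioning each prediction on the level
#' above (the level-1 letter must come from external seeding, mirroring
#' perfect first-level initialization).
#'
#' @param tree an [generate_hierarchy()] tree.
#' @param config the same [synthetic_config()].
#' @return object of class `"atc_sim"`: list with feature matrix `x` (rows
#'   named by synthetic compound ids), `codes` (one code per compound),
#'   `compounds` (a compound table), `tree` and `config`.
#' @export
generate_dataset <- function(tree, config = tree$config) {
  leaves <- if (config$feature_model == "context_dependent") {
    sort(unique(substr(tree$leaves, 1L, 3L)))
  } else {
    tree$leaves
  }
  with_local_seed(config$seed + 1L, {
    n <- config$n_per_leaf * length(leaves)
    codes <- if (config$assignment == "balanced") {
      rep(leaves, each = config$n_per_leaf)
    } else {
      prob <- if (config$feature_model == "context_dependent") {
        tapply(tree$leaf_prob, substr(names(tree$leaf_prob), 1L, 3L), sum)[leaves]
      } else {
        tree$leaf_prob[leaves]
      }
      sample(leaves, n, replace = TRUE, prob = prob)
    }
    ids <- sprintf("SYNC%05d", seq_len(n))
    x <- if (config$feature_model == "leaf_gaussian") {
      leaf_gaussian_features(leaves, codes, config)
    } else {
      context_dependent_features(tree, codes, config)
    }
    rownames(x) <- ids
    compounds <- data.frame(id = ids, smiles = NA_character_,
                            atc_codes = codes, stringsAsFactors = FALSE)
    structure(list(x = x, codes = codes, compounds = compounds,
                   tree = tree, config = config),
              class = "atc_sim")
  })
}

leaf_gaussian_features <- function(leaves, codes, config) {
  p <- config$feature_dim
  # one offset per distinct prefix at each depth; leaf centroid = sum along
  # its path
  centroids <- matrix(0, length(leaves), p,
                      dimnames = list(leaves, NULL))
  parsed <- parse_atc(leaves)
  for (d in 1:4) {
    pref <- substr(parsed$raw, 1L, ATC_WIDTHS[d])
    for (pp in unique(pref)) {
      off <- rnorm(p, sd = config$level_scales[d])
      rows <- pref == pp
      centroids[rows, ] <- centroids[rows, , drop = FALSE] +
        matrix(off, sum(rows), p, byrow = TRUE)
    }
  }
  centroids[codes, , drop = FALSE] +
    matrix(rnorm(length(codes) * p, sd = config$noise_sd),
           length(codes), p)
}

context_dependent_features <- function(tree, codes, config) {
  m2 <- config$children[1L]
  p <- max(config$feature_dim, m2)
  letter <- substr(codes, 1L, 1L)
  child <- match(substr(codes, 2L, 3L), sprintf("%02d", seq_len(m2)))
  shift <- match(letter, tree$letters) - 1L
  context <- ((child - 1L + shift) %% m2) + 1L
  x <- matrix(rnorm(length(codes) * p, sd = config$noise_sd),
              length(codes), p)
  x[cbind(seq_along(codes), context)] <-
    x[cbind(seq_along(codes), context)] + 3
  x
}

#' @export
print.atc_sim <- function(x, ...) {
  cat(sprintf("<atc_sim> %d compound(s), %d feature(s), model '%s'\n",
              nrow(x$x), ncol(x$x), x$config$feature_model))
  invisible(x)
}

#' Generate a STITCH-dialect chemical-chemical association table
#'
#' Pairs of compounds in the same anatomical group receive combined scores
#' centred on `within_branch_score`, other pairs on `cross_branch_score`
#' (sd `score_sd`, truncated to \[0, 1000\] and rounded), so interaction
#' profiles correlate with code proximity. Setting the two means equal
#' removes the signal entirely. All compound pairs are emitted up to
#' `max_pairs`, beyond which a random subset is drawn.
#'
#' @param sim an [generate_dataset()] result.
#' @param config the same [synthetic_config()].
#' @param max_pairs cap on emitted pairs (default 200000).
#' @return data.frame of class `"stitch_assoc"` with columns `chemical_a`,
#'   `chemical_b`, `combined_score`.
#' @export
generate_association_table <- function(sim, config = sim$config,
                                       max_pairs = 2e5) {
  ids <- sim$compounds$id
  letter <- substr(sim$codes, 1L, 1L)
  with_local_seed(config$seed + 2L, {
    n <- length(ids)
    pairs <- utils::combn(n, 2L)
    if (ncol(pairs) > max_pairs) {
      pairs <- pairs[, sample(ncol(pairs), max_pairs), drop = FALSE]
    }
    same <- letter[pairs[1L, ]] == letter[pairs[2L, ]]
    mu <- ifelse(same, config$within_branch_score, config$cross_branch_score)
    score <- round(pmin(1000, pmax(0, rnorm(ncol(pairs), mu, config$score_sd))))
    out <- data.frame(chemical_a = ids[pairs[1L, ]],
                      chemical_b = ids[pairs[2L, ]],
                      combined_score = as.integer(score),
                      stringsAsFactors = FALSE)
    class(out) <- c("stitch_assoc", "data.frame")
    out
  })
}

#' Generate a STITCH-dialect chemical-protein target table
#'
#' Each anatomical group owns a disjoint pool of `target_pool_size`
#' synthetic proteins (ids prefixed with the configured organism); each
#' compound draws `targets_per_compound` interactions from its group's
#' pool with combined scores uniform on \[500, 1000\], so roughly half the
#' records survive the default confidence filter of 700 and shared-target
#' counts are high within groups and zero across them.
#'
#' @inheritParams generate_association_table
#' @return data.frame of class `"stitch_targets"` with columns `chemical`,
#'   `protein`, `combined_score`.
#' @export
generate_target_table <- function(sim, config = sim$config) {
  ids <- sim$compounds$id
  letter <- substr(sim$codes, 1L, 1L)
  with_local_seed(config$seed + 3L, {
    rows <- lapply(seq_along(ids), function(i) {
      pool <- sprintf("%s.SYNP_%s_%03d", config$organism, letter[i],
                      seq_len(config$target_pool_size))
      prot <- sample(pool, min(config$targets_per_compound, length(pool)))
      data.frame(chemical = ids[i], protein = prot,
                 combined_score = as.integer(round(runif(length(prot),
                                                         500, 1000))),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("stitch_targets", "data.frame")
    out
  })
}
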