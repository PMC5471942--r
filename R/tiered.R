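# Tiered learning: a top-down cascade of per-prefix classifier instances
# over the ATC hierarchy. The level-1 letter comes from an initializer
# (supervised level-1 classifier or external seed map); every observed
# prefix of depth 1..max_level-1 then owns a classifier trained only on
# instances under that prefix, predicting the next-level component. At test
# time the realized prefix path selects which classifier refines each level,
# so each prediction is a root-to-leaf walk and hierarchical consistency
# holds by construction.

#' Level-1 initializers for the tiered cascade
#'
#' `init_supervised()` trains a single classifier on the whole training set
#' to predict the first-level anatomical group letter. `init_external()`
#' wraps an externally supplied compound-to-letter map (another predictor's
#' output, curated repository annotations, ...); compounds absent from the
#' map are routed per `missing`: `"abstain"` (no prediction; scored as
#' wrong) or `"majority"` (the most frequent letter in the map).
#'
#' @param x numeric descriptor matrix (instances x features).
#' @param codes character vector of ATC codes, one per row of `x`.
#' @param learner a [base_learner()] specification.
#' @return object of class `"atc_initializer"`.
#' @export
init_supervised <- function(x, codes, learner = base_learner("svm")) {
  x <- as.matrix(x)
  parsed <- parse_atc(codes)
  y <- parsed$components[, 1L]
  if (length(unique(y)) == 1L) {
    warning("single level-1 class in training data; initializer is constant")
  }
  structure(list(type = "supervised",
                 fit = fit_node_learner(learner, x, y),
                 letters = sort(unique(y))),
            class = "atc_initializer")
}

#' @rdname init_supervised
#' @param seed_map named character vector mapping compound id to a level-1
#'   anatomical group letter.
#' @param missing policy for compounds absent from the map.
#' @export
init_external <- function(seed_map, missing = c("abstain", "majority")) {
  missing <- match.arg(missing)
  seed_map <- toupper(unlist(seed_map))
  bad <- !seed_map %in% ATC_LETTERS
  if (any(bad)) {
    stop(sprintf("seed map entry '%s' -> '%s' is not an anatomical group letter",
                 names(seed_map)[which(bad)[1L]], seed_map[which(bad)[1L]]))
  }
  structure(list(type = "external", map = seed_map, missing = missing,
                 letters = sort(unique(unname(seed_map)))),
            class = "atc_initializer")
}

predict_initializer <- function(init, x, ids) {
  if (init$type == "supervised") {
    return(predict_node(init$fit, x))
  }
  out <- unname(init$map[ids])
  if (anyNA(out) && init$missing == "majority") {
    if (length(init$map)) out[is.na(out)] <- majority_label(init$map)
  }
  out
}

#' Fit a tiered-learning cascade
#'
#' Trains one classifier instance per observed ATC prefix: the level-1
#' initializer, then for every prefix of depth 1..`max_level - 1` with
#' deeper training instances a classifier over those instances only,
#' predicting the next-level code component. Prefix nodes with fewer than
#' `min_node_size` instances or a single observed child get a constant
#' (majority-child) model. Nodes are trained on the *true* training
#' prefixes; predicted prefixes matter only at prediction time, where they
#' select which node refines each level.
#'
#' @param x numeric descriptor matrix, one row per (compound, code)
#'   instance; row names are compound ids (used by external initializers).
#' @param codes character vector of ATC codes, parallel to rows of `x`.
#'   Codes shorter than `max_level` simply terminate their training path
#'   early.
#' @param learner a [base_learner()] used at every prefix node.
#' @param init `"supervised"` (default; trains `init_learner` on all
#'   instances) or an `"atc_initializer"` from [init_external()].
#' @param init_learner learner for the supervised initializer (defaults to
#'   `learner`).
#' @param max_level deepest predicted level (default 4; level 5 identifies
#'   the chemical substance and is never predicted).
#' @param min_node_size minimum instances for a discriminative node fit
#'   (default 2; below it the node is a constant majority-child model).
#' @param fallback policy for test-time prefixes with no trained node:
#'   `"parent-majority"` (majority next component under the nearest
#'   observed ancestor) or `"abstain"` (no prediction from that level on;
#'   abstentions score as wrong).
#' @return object of class `"tiered_model"`.
#' @seealso [predict.tiered_model()], [stp_train()] for the flat baseline.
#' @export
tiered_train <- function(x, codes, learner = base_learner("svm"),
                         init = "supervised", init_learner = learner,
                         max_level = 4L, min_node_size = 2L,
                         fallback = c("parent-majority", "abstain")) {
  fallback <- match.arg(fallback)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  if (length(codes) != nrow(x)) {
    stop("`codes` must have one ATC code per row of `x`")
  }
  max_level <- as.integer(max_level)
  stopifnot(max_level >= 1L, max_level <= 4L)
  parsed <- parse_atc(codes)
  comp <- parsed$components
  depth <- parsed$depth

  initializer <- if (inherits(init, "atc_initializer")) {
    init
  } else if (identical(init, "supervised")) {
    init_supervised(x, codes, init_learner)
  } else {
    stop("`init` must be \"supervised\" or an atc_initializer")
  }

  nodes <- list()
  node_meta <- list()
  if (max_level >= 2L) {
    for (d in seq_len(max_level - 1L)) {
      deeper <- depth >= d + 1L
      if (!any(deeper)) next
      pref <- substr(parsed$raw[deeper], 1L, ATC_WIDTHS[d])
      for (p in sort(unique(pref))) {
        idx <- which(deeper)[pref == p]
        y <- comp[idx, d + 1L]
        fit <- fit_node_learner(learner, x[idx, , drop = FALSE], y,
                                min_n = min_node_size)
        nodes[[p]] <- fit
        node_meta[[p]] <- list(depth = d, n = length(idx), rows = idx,
                               classes = sort(unique(y)),
                               constant = fit$type == "constant")
      }
    }
  }

  structure(list(initializer = initializer, nodes = nodes,
                 node_meta = node_meta, learner = learner,
                 max_level = max_level, min_node_size = min_node_size,
                 fallback = fallback,
                 train_components = comp, train_depth = depth,
                 n_features = ncol(x), feature_names = colnames(x),
                 descriptor_kind = attr(x, "kind") %||% "unknown",
                 call = match.call()),
            class = "tiered_model")
}

# Majority next-level (level k) component among training instances under
# `prefix` (possibly ""), or NA if none reach level k.
parent_majority_component <- function(model, prefix, k) {
  comp <- model$train_components
  keep <- model$train_depth >= k
  if (nzchar(prefix)) {
    keep <- keep & !is.na(comp[, 1L]) &
      substr(apply_raw(model), 1L, nchar(prefix)) == prefix
  }
  if (!any(keep)) return(NA_character_)
  majority_label(comp[keep, k])
}

apply_raw <- function(model) {
  # reconstruct raw training codes from components (cached on first use)
  if (!is.null(model$.raw)) return(model$.raw)
  comp <- model$train_components
  raw <- apply(comp, 1L, function(r) paste(r[!is.na(r)], collapse = ""))
  raw
}

# Walk up the ancestors of `prefix` (prefix itself excluded) down to the
# root and return the first defined majority level-k component.
fallback_component <- function(model, prefix, k) {
  d <- prefix_depth(prefix)
  cand <- c(rev(vapply(seq_len(d), function(j) substr(prefix, 1L, ATC_WIDTHS[j]),
                       "")), "")
  for (a in cand) {
    m <- parent_majority_component(model, a, k)
    if (!is.na(m)) return(m)
  }
  NA_character_
}

#' Predict ATC code paths with a tiered model
#'
#' Level 1 comes from the initializer; each subsequent level from the node
#' model addressed by the prefix realized so far. Rows whose realized
#' prefix has no trained node are resolved by the model's fallback policy.
#' The result is one root-to-leaf path per row, so the predicted prefix at
#' level k always extends the predicted prefix at level k - 1.
#'
#' @param object a `"tiered_model"`.
#' @param newdata numeric matrix in the model's feature space.
#' @param ids compound ids (defaults to `rownames(newdata)`); required by
#'   external initializers.
#' @param ... unused.
#' @return An `"atc_prediction"` data.frame with columns `id`, `L1`..`L4`
#'   (predicted components, `NA` where abstained or beyond `max_level`) and
#'   `path` (concatenated prefix). Attribute `fallback` flags per-row,
#'   per-level fallback use.
#' @export
predict.tiered_model <- function(object, newdata, ids = rownames(newdata),
                                 ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature dimension mismatch: model has %d features, newdata %d",
                 object$n_features, ncol(newdata)))
  }
  n <- nrow(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- matrix(NA_character_, n, 4L, dimnames = list(NULL, paste0("L", 1:4)))
  fb <- matrix(FALSE, n, 4L)
  comp[, 1L] <- predict_initializer(object$initializer, newdata, ids)

  if (object$max_level >= 2L) {
    object$.raw <- apply_raw(object)
    for (k in 2:object$max_level) {
      prefix <- prediction_prefix(comp, k - 1L)
      live <- !is.na(prefix)
      if (!any(live)) break
      for (p in unique(prefix[live])) {
        rows <- which(live & prefix == p)
        node <- object$nodes[[p]]
        if (!is.null(node)) {
          comp[rows, k] <- predict_node(node, newdata[rows, , drop = FALSE])
        } else if (object$fallback == "parent-majority") {
          comp[rows, k] <- fallback_component(object, p, k)
          fb[rows, k] <- TRUE
        } else {
          fb[rows, k] <- TRUE  # abstain: leave NA
        }
      }
    }
  }
  new_atc_prediction(ids, comp, mode = "TL", max_level = object$max_level,
                     fallback = fb)
}

# Concatenate the first k predicted components; NA if any is missing.
prediction_prefix <- function(comp, k) {
  out <- comp[, 1L]
  if (k >= 2L) {
    for (j in 2:k) out <- ifelse(is.na(out) | is.na(comp[, j]), NA,
                                 paste0(out, comp[, j]))
  }
  out
}

new_atc_prediction <- function(ids, comp, mode, max_level, fallback = NULL) {
  # realized path: concatenation of the leading non-NA components
  path <- vapply(seq_along(ids), function(i) {
    r <- comp[i, seq_len(max_level)]
    stop_at <- which(is.na(r))
    if (length(stop_at)) r <- r[seq_len(stop_at[1L] - 1L)]
    paste(r, collapse = "")
  }, "")
  out <- data.frame(id = as.character(ids), comp, path = path,
                    stringsAsFactors = FALSE)
  structure(out, mode = mode, max_level = max_level, fallback = fallback,
            class = c("atc_prediction", "data.frame"))
}

#' @export
print.tiered_model <- function(x, ...) {
  cat("Tiered ATC classifier\n")
  cat(sprintf("  learner: %s; initializer: %s; max level: %d\n",
              x$learner$family, x$initializer$type, x$max_level))
  cat(sprintf("  %d instances, %d features, %d prefix nodes (%d constant)\n",
              nrow(x$train_components), x$n_features, length(x$nodes),
              sum(vapply(x$node_meta, `[[`, TRUE, "constant"))))
  invisible(x)
}

#' @export
summary.tiered_model <- function(object, ...) {
  meta <- object$node_meta
  df <- data.frame(
    prefix = names(meta),
    depth = vapply(meta, `[[`, 0L, "depth"),
    n = vapply(meta, `[[`, 0L, "n"),
    n_classes = vapply(meta, function(m) length(m$classes), 0L),
    constant = vapply(meta, `[[`, TRUE, "constant"),
    row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(df$prefix), ]
  structure(list(model = object, nodes = df), class = "summary.tiered_model")
}

#' @export
print.summary.tiered_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-prefix nodes:\n")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

# ---- flat baseline ----------------------------------------------------------

#' Flat per-level baseline (standard training and prediction, STP)
#'
#' Trains one independent classifier per ATC level k on all instances of
#' depth >= k. Unlike the tiered cascade, per-level predictions are
#' unconstrained: the baseline may emit a level-2 component never observed
#' under its own predicted level-1 letter.
#'
#' @inheritParams tiered_train
#' @param levels number of levels to model (default 4).
#' @return object of class `"stp_model"`.
#' @export
stp_train <- function(x, codes, learner = base_learner("svm"), levels = 4L) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  parsed <- parse_atc(codes)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L, levels <= 4L)
  fits <- vector("list", levels)
  for (k in seq_len(levels)) {
    idx <- which(parsed$depth >= k)
    if (!length(idx)) next
    fits[[k]] <- fit_node_learner(learner, x[idx, , drop = FALSE],
                                  parsed$components[idx, k])
  }
  structure(list(fits = fits, learner = learner, levels = levels,
                 n_features = ncol(x),
                 descriptor_kind = attr(x, "kind") %||% "unknown",
                 call = match.call()),
            class = "stp_model")
}

#' @rdname stp_train
#' @param object an `"stp_model"`.
#' @param newdata numeric matrix in the model's feature space.
#' @param ids compound ids (defaults to row names).
#' @param ... unused.
#' @export
predict.stp_model <- function(object, newdata, ids = rownames(newdata), ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature dimension mismatch: model has %d features, newdata %d",
                 object$n_features, ncol(newdata)))
  }
  n <- nrow(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- matrix(NA_character_, n, 4L, dimnames = list(NULL, paste0("L", 1:4)))
  for (k in seq_len(object$levels)) {
    if (!is.null(object$fits[[k]])) {
      comp[, k] <- predict_node(object$fits[[k]], newdata)
    }
  }
  new_atc_prediction(ids, comp, mode = "STP", max_level = object$levels)
}

#' @export
print.stp_model <- function(x, ...) {
  cat(sprintf("Flat per-level ATC classifier (STP): %s, %d level(s), %d features\n",
              x$learner$family, x$levels, x$n_features))
  invisible(x)
}

#' Check predictions against the training hierarchy
#'
#' A prediction is hierarchy-consistent with a training code set when every
#' predicted (parent prefix, child component) edge was observed in
#' training. Tiered predictions seeded by a supervised initializer satisfy
#' this by construction; the flat baseline need not.
#'
#' @param pred an `"atc_prediction"`.
#' @param train_codes character vector (or `"atc_code"`) of training codes.
#' @return logical vector, one entry per prediction row; `TRUE` when every
#'   non-`NA` predicted prefix occurred in the training codes.
#' @export
hierarchy_consistent <- function(pred, train_codes) {
  parsed <- as_atc(train_codes)
  observed <- unique(unlist(lapply(1:4, function(k) {
    keep <- parsed$depth >= k
    substr(parsed$raw[keep], 1L, ATC_WIDTHS[k])
  })))
  comp <- as.matrix(pred[paste0("L", 1:4)])
  ok <- rep(TRUE, nrow(comp))
  for (k in 1:4) {
    pfx <- prediction_prefix(comp, k)
    ok <- ok & (is.na(pfx) | pfx %in% observed)
  }
  ok
}

# ---- model persistence ------------------------------------------------------

BUNDLE_FORMAT <- "tieredatc/model-bundle"
BUNDLE_VERSION <- 1L

#' Save / load a model bundle
#'
#' A bundle is a directory holding `bundle.json` (format identifier,
#' version, descriptor kind, learner echo) and the serialized model.
#' Loading a bundle with a mismatched format or version fails loudly.
#'
#' @param model a `"tiered_model"` or `"stp_model"`.
#' @param dir bundle directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = BUNDLE_FORMAT, version = BUNDLE_VERSION,
               class = class(model)[1L],
               descriptor_kind = model$descriptor_kind,
               learner = model$learner$family,
               seed = model$learner$seed,
               package_version = as.character(utils::packageVersion("tieredatc")))
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "bundle.json")
  if (!file.exists(meta_path)) stop(sprintf("%s is not a model bundle", dir))
  meta <- jsonlite::read_json(meta_path)
  if (!identical(meta$format, BUNDLE_FORMAT)) {
    stop(sprintf("unrecognized bundle format '%s'", meta$format))
  }
  if (!identical(as.integer(meta$version), BUNDLE_VERSION)) {
    stop(sprintf("bundle version %s does not match supported version %d",
                 meta$version, BUNDLE_VERSION))
  }
  readRDS(file.path(dir, "model.rds"))
}
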