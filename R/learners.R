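#' Base-learner specification
#'
#' Describes the classifier family plugged into the tiered cascade (and the
#' flat baseline). The four families studied for this task are naive Bayes,
#' multilayer perceptron, support vector machine and random forest; a
#' majority-class learner and a k-nearest-neighbour learner are provided as
#' cheap baseline/oracle backends. The seed is recorded so stochastic
#' learners (MLP, random forest) are reproducible.
#'
#' Hyperparameters are passed through `...`:
#' * `svm`: `kernel` (default `"radial"`), `cost` (default 1);
#' * `mlp`: `size` (hidden units, default 8), `decay` (default 0.01),
#'   `maxit` (default 150);
#' * `random_forest`: `ntree` (default 200);
#' * `knn`: `k` (default 1).
#'
#' @param family one of `"naive_bayes"`, `"mlp"`, `"svm"`,
#'   `"random_forest"`, `"knn"`, `"majority"`.
#' @param ... named hyperparameters (see above).
#' @param seed integer seed used for any stochastic fit.
#' @return list of class `"base_learner"`.
#' @export
base_learner <- function(family = c("svm", "naive_bayes", "mlp",
                                    "random_forest", "knn", "majority"),
                         ..., seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, control = list(...),
                 seed = as.integer(seed)),
            class = "base_learner")
}

#' @export
print.base_learner <- function(x, ...) {
  ctl <- if (length(x$control)) {
    paste(names(x$control), unlist(x$control), sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("<base_learner> %s (%s), seed %d\n", x$family, ctl, x$seed))
  invisible(x)
}

# Majority label with lexicographic tie-break, so results do not depend on
# input order or RNG state.
majority_label <- function(y) {
  tab <- table(y)
  names(tab)[order(-as.integer(tab), names(tab))][1L]
}

constant_fit <- function(label, classes, n) {
  structure(list(type = "constant", label = label, classes = classes, n = n),
            class = "node_fit")
}

# Fit one classifier instance on a (sub)set of instances. Degenerate inputs
# (a single class, too few rows, or a failing underlying fit) fall back to a
# constant majority-label model.
fit_node_learner <- function(spec, x, y, min_n = 2L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) == 1L || length(y) < min_n) {
    return(constant_fit(majority_label(y), classes, length(y)))
  }
  fit <- tryCatch(
    fit_family(spec, x, y, classes),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(constant_fit(majority_label(y), classes, length(y)))
  }
  structure(list(type = "model", family = spec$family, fit = fit,
                 classes = classes, n = length(y)),
            class = "node_fit")
}

fit_family <- function(spec, x, y, classes) {
  ctl <- spec$control
  switch(spec$family,
    majority = list(label = majority_label(y)),
    knn = list(x = x, y = y, k = ctl$k %||% 1L),
    naive_bayes = {
      fit <- e1071::naiveBayes(as.data.frame(x), factor(y, levels = classes))
      # floor the per-class sds: zero within-class variance (common on
      # synthetic or binary features) would make the gaussian densities
      # degenerate at prediction time
      fit$tables <- lapply(fit$tables, function(tb) {
        if (is.matrix(tb) && ncol(tb) == 2L) tb[, 2L] <- pmax(tb[, 2L], 1e-3)
        tb
      })
      fit
    },
    svm = {
      sds <- apply(x, 2L, stats::sd)
      e1071::svm(x, factor(y, levels = classes),
                 kernel = ctl$kernel %||% "radial",
                 cost = ctl$cost %||% 1,
                 scale = sds > 0)
    },
    random_forest = {
      set.seed(spec$seed)
      randomForest::randomForest(x, factor(y, levels = classes),
                                 ntree = ctl$ntree %||% 200L)
    },
    mlp = {
      set.seed(spec$seed)
      ymat <- nnet::class.ind(factor(y, levels = classes))
      nnet::nnet(x, ymat, softmax = TRUE,
                 size = ctl$size %||% 8L,
                 decay = ctl$decay %||% 0.01,
                 maxit = ctl$maxit %||% 150L,
                 MaxNWts = 100000L, trace = FALSE)
    },
    stop(sprintf("unknown learner family '%s'", spec$family)))
}

# Predict labels for a fitted node. Always returns character.
predict_node <- function(fit, x) {
  if (fit$type == "constant") {
    return(rep(fit$label, nrow(x)))
  }
  cls <- fit$classes
  switch(fit$family,
    majority = rep(fit$fit$label, nrow(x)),
    knn = predict_knn(fit$fit, x),
    naive_bayes = as.character(predict(fit$fit, as.data.frame(x))),
    svm = as.character(predict(fit$fit, x)),
    random_forest = as.character(predict(fit$fit, x)),
    mlp = {
      p <- predict(fit$fit, x)
      # columns are in sorted class order; ties resolve to the smaller label
      cls[max.col(p, ties.method = "first")]
    },
    stop("unknown node fit"))
}

# k-nearest-neighbour prediction with fully deterministic tie handling:
# neighbours are ranked by (distance, label), and vote ties go to the
# lexicographically smallest label. With k = 1 this returns the label of
# the nearest training instance, ties broken towards the smaller label.
predict_knn <- function(fit, x) {
  trx <- fit$x
  k <- min(fit$k, nrow(trx))
  if (k == 1L) {
    # vectorised fast path: squared distances via the Gram expansion
    d2 <- outer(rowSums(x^2), rowSums(trx^2), "+") - 2 * tcrossprod(x, trx)
    d2 <- round(d2, 10)  # clip FP fuzz so exact ties stay ties
    return(vapply(seq_len(nrow(x)), function(i) {
      cand <- which(d2[i, ] == min(d2[i, ]))
      min(fit$y[cand])
    }, ""))
  }
  apply(x, 1L, function(row) {
    d <- sqrt(colSums((t(trx) - row)^2))
    ord <- order(d, fit$y)
    majority_label(fit$y[ord[seq_len(k)]])
  })
}
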