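# Evaluation measures for hierarchical ATC prediction.
#
# Three measures, all on the percent scale:
#   A(k)  -- accuracy at level k: share of evaluated instances whose
#            predicted level-k component equals the true one, computed
#            independently of the other levels;
#   CA(k) -- cumulative accuracy: arithmetic mean of A(1)..A(k);
#   N(k)  -- share (and count) of instances whose predicted components are
#            correct at every level 1..k.
# Instances whose true code is shallower than k are excluded from the
# A(k)/N(k) denominators; abstentions count as wrong.

eval_correct_matrix <- function(pred, truth) {
  truth <- as_atc(truth)
  comp <- as.matrix(pred[paste0("L", 1:4)])
  if (nrow(comp) != length(truth$raw)) {
    stop("predictions and truth must have the same number of instances")
  }
  correct <- matrix(FALSE, nrow(comp), 4L)
  for (k in 1:4) {
    correct[, k] <- !is.na(comp[, k]) & !is.na(truth$components[, k]) &
      comp[, k] == truth$components[, k]
  }
  list(correct = correct, depth = truth$depth)
}

#' Per-level prediction accuracy A(k)
#'
#' @param pred an `"atc_prediction"`.
#' @param truth true ATC codes (character or `"atc_code"`), one per
#'   prediction row.
#' @param k level, 1..4.
#' @return accuracy in percent over instances of depth >= k (`NaN` when no
#'   instance is that deep).
#' @export
accuracy_at_level <- function(pred, truth, k) {
  if (length(k) != 1L || is.na(k) || !k %in% 1:4) {
    stop("`k` must be a level index between 1 and 4")
  }
  cm <- eval_correct_matrix(pred, truth)
  elig <- cm$depth >= k
  100 * sum(cm$correct[elig, k]) / sum(elig)
}

#' Cumulative prediction accuracy CA(k)
#'
#' The arithmetic mean of the per-level accuracies A(1)..A(k), reported to
#' two decimals on the percent scale (half-up) by default.
#'
#' @param a_values numeric vector of per-level accuracies A(1)..A(k), in
#'   percent.
#' @param digits decimal places for presentation rounding (half-up);
#'   `NULL` returns full precision.
#' @return CA(k) in percent.
#' @examples
#' cumulative_accuracy(c(100, 79.03))  # 89.52
#' @export
cumulative_accuracy <- function(a_values, digits = 2) {
  if (length(a_values) == 0L) stop("`a_values` must be non-empty")
  ca <- mean(a_values)
  if (is.null(digits)) ca else round_half_up(ca, digits)
}

#' Path-correct measure N(k)
#'
#' Share and count of instances whose predicted components are correct at
#' every level 1..k.
#'
#' @inheritParams accuracy_at_level
#' @return list with `percent`, `count` and `n` (denominator).
#' @export
correct_to_level <- function(pred, truth, k) {
  if (length(k) != 1L || is.na(k) || !k %in% 1:4) {
    stop("`k` must be a level index between 1 and 4")
  }
  cm <- eval_correct_matrix(pred, truth)
  elig <- cm$depth >= k
  all_ok <- rowSums(cm$correct[, seq_len(k), drop = FALSE]) == k
  list(percent = 100 * sum(all_ok & elig) / sum(elig),
       count = sum(all_ok & elig), n = sum(elig))
}

#' Evaluate a prediction run
#'
#' Computes A(k), CA(k) and N(k) for k = 1..`max_level`, with the raw
#' counts behind each.
#'
#' @param pred an `"atc_prediction"`.
#' @param truth true ATC codes, one per prediction row (for multi-code
#'   compounds, expand to (compound, code) instances first; see
#'   [expand_instances()]).
#' @param max_level deepest level to report (default: the prediction's).
#' @return object of class `"atc_eval"`: list with a per-level data.frame
#'   `levels` (columns `level`, `n`, `A_count`, `A`, `CA`, `N_count`, `N`;
#'   percentages in full precision), `n_instances` and `mode`.
#' @export
evaluate_predictions <- function(pred, truth,
                                 max_level = attr(pred, "max_level") %||% 4L) {
  cm <- eval_correct_matrix(pred, truth)
  ks <- seq_len(max_level)
  A <- A_count <- N <- N_count <- n <- numeric(length(ks))
  for (k in ks) {
    elig <- cm$depth >= k
    n[k] <- sum(elig)
    A_count[k] <- sum(cm$correct[elig, k])
    A[k] <- 100 * A_count[k] / n[k]
    all_ok <- rowSums(cm$correct[, seq_len(k), drop = FALSE]) == k
    N_count[k] <- sum(all_ok & elig)
    N[k] <- 100 * N_count[k] / n[k]
  }
  CA <- vapply(ks, function(k) cumulative_accuracy(A[seq_len(k)], digits = NULL),
               numeric(1))
  report <- structure(
    list(levels = data.frame(level = ks, n = n, A_count = A_count, A = A,
                             CA = CA, N_count = N_count, N = N),
         n_instances = nrow(cm$correct),
         mode = attr(pred, "mode") %||% "unknown"),
    class = "atc_eval")
  validate_eval(report)
  report
}

# Internal sanity assertions on every computed report.
validate_eval <- function(report) {
  lv <- report$levels
  ok_range <- all(is.nan(lv$A) | (lv$A >= 0 & lv$A <= 100)) &&
    all(is.nan(lv$N) | (lv$N >= 0 & lv$N <= 100))
  stopifnot(ok_range)
  # the path-correct count can only shrink with depth (the percent form can
  # rise when shallow codes drop out of the denominator)
  stopifnot(all(diff(lv$N_count) <= 0))
  invisible(report)
}

#' @export
print.atc_eval <- function(x, ...) {
  cat(sprintf("ATC prediction evaluation (%s), %d instance(s)\n",
              x$mode, x$n_instances))
  lv <- x$levels
  out <- data.frame(level = lv$level, n = lv$n,
                    `A(k)` = sprintf("%.2f%%", round_half_up(lv$A, 2)),
                    `CA(k)` = sprintf("%.2f%%", round_half_up(lv$CA, 2)),
                    `N(k)` = sprintf("%.2f%% (%d)", round_half_up(lv$N, 2),
                                     lv$N_count),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Serialize evaluation reports
#'
#' `write_eval_json()` stores full precision plus provenance (`config`);
#' `write_eval_tsv()` writes one row per level and metric.
#'
#' @param report an `"atc_eval"`.
#' @param path output path.
#' @param config optional run configuration echoed into the JSON.
#' @export
write_eval_json <- function(report, path, config = NULL) {
  jsonlite::write_json(list(mode = report$mode,
                            n_instances = report$n_instances,
                            levels = report$levels,
                            config = config),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_json
#' @export
write_eval_tsv <- function(report, path) {
  lv <- report$levels
  long <- rbind(
    data.frame(level = lv$level, metric = "A", percent = lv$A,
               count = lv$A_count, n = lv$n),
    data.frame(level = lv$level, metric = "CA", percent = lv$CA,
               count = NA_integer_, n = lv$n),
    data.frame(level = lv$level, metric = "N", percent = lv$N,
               count = lv$N_count, n = lv$n))
  long <- long[order(long$level, long$metric), ]
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate predictions against a multi-code compound table
#'
#' Expands each compound's `';'`-delimited code list into (compound, code)
#' instances and scores the compound's single predicted path against each
#' instance (the default convention). `mode = "any"` instead scores each
#' compound once, counting a level correct if it matches any of the
#' compound's codes.
#'
#' @param pred an `"atc_prediction"` with one row per compound.
#' @param compounds data.frame with columns `id` and `atc_codes`.
#' @param mode `"instance"` (default) or `"any"`.
#' @inheritParams evaluate_predictions
#' @export
evaluate_against_table <- function(pred, compounds,
                                   mode = c("instance", "any"),
                                   max_level = attr(pred, "max_level") %||% 4L) {
  mode <- match.arg(mode)
  inst <- expand_instances(compounds$id, compounds$atc_codes)
  pidx <- match(inst$id, pred$id)
  if (anyNA(pidx)) {
    stop(sprintf("no prediction for compound '%s'", inst$id[is.na(pidx)][1L]))
  }
  pred_inst <- pred[pidx, , drop = FALSE]
  attributes(pred_inst)[c("mode", "max_level")] <-
    attributes(pred)[c("mode", "max_level")]
  class(pred_inst) <- class(pred)
  if (mode == "instance") {
    return(evaluate_predictions(pred_inst, inst$code, max_level = max_level))
  }
  # any-code-correct: keep, per compound and level, the best-matching code
  cm <- eval_correct_matrix(pred_inst, inst$code)
  by_comp <- split(seq_len(nrow(inst)), inst$id)
  ks <- seq_len(max_level)
  A <- A_count <- N <- N_count <- n <- numeric(length(ks))
  for (k in ks) {
    hit <- vapply(by_comp, function(rows) {
      elig <- cm$depth[rows] >= k
      if (!any(elig)) return(NA)
      any(cm$correct[rows[elig], k])
    }, NA)
    pathhit <- vapply(by_comp, function(rows) {
      elig <- cm$depth[rows] >= k
      if (!any(elig)) return(NA)
      any(rowSums(cm$correct[rows[elig], seq_len(k), drop = FALSE]) == k)
    }, NA)
    n[k] <- sum(!is.na(hit))
    A_count[k] <- sum(hit, na.rm = TRUE)
    A[k] <- 100 * A_count[k] / n[k]
    N_count[k] <- sum(pathhit, na.rm = TRUE)
    N[k] <- 100 * N_count[k] / n[k]
  }
  CA <- vapply(ks, function(k) mean(A[seq_len(k)]), numeric(1))
  structure(list(levels = data.frame(level = ks, n = n, A_count = A_count,
                                     A = A, CA = CA, N_count = N_count, N = N),
                 n_instances = length(by_comp), mode = "any-code"),
            class = "atc_eval")
}
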