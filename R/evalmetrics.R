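#' Plan repeated k-fold cross validation
#'
#' Within each repeat the indices `1..n` are shuffled and partitioned into
#' `k` folds whose sizes differ by at most 1. Defaults follow the published
#' evaluation protocol: k = 3 folds, 5 repeats.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (>= 2).
#' @param repeats number of reshuffled repeats.
#' @param seed RNG seed; the plan is deterministic given it.
#' @return A `fold_plan`: list with `assignments` (per repeat, a list of
#'   `k` disjoint index vectors covering `1..n`), `n`, `k`, `repeats`,
#'   `seed`.
#' @export
plan_repeated_kfold <- function(n, k = 3L, repeats = 5L, seed = 1L) {
  if (k < 2L) stop("plan_repeated_kfold: k must be >= 2")
  if (n < k) stop("plan_repeated_kfold: n (", n, ") must be >= k (", k, ")")
  stopifnot(repeats >= 1L)
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  assignments <- lapply(seq_len(repeats), function(r) {
    perm <- sample.int(n)
    split(perm, rep(seq_len(k), times = sizes))
  })
  structure(list(assignments = assignments, n = n, k = k,
                 repeats = repeats, seed = seed),
            class = "fold_plan")
}

#' Pooled and per-class confusion counts
#'
#' @param y_true,y_pred binary matrices of identical shape `(N, L)`.
#' @return A `confusion_counts`: list with `pooled` (named vector tp, fp,
#'   fn, tn summing to N*L) and `per_class` (L x 4 matrix).
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!identical(dim(y_true), dim(y_pred))) {
    stop("confusion_counts: shape mismatch (", paste(dim(y_true), collapse = "x"),
         " vs ", paste(dim(y_pred), collapse = "x"), ")")
  }
  check_binary(y_true, "y_true")
  check_binary(y_pred, "y_pred")
  tp <- colSums(y_true == 1 & y_pred == 1)
  fp <- colSums(y_true == 0 & y_pred == 1)
  fn <- colSums(y_true == 1 & y_pred == 0)
  tn <- colSums(y_true == 0 & y_pred == 0)
  per_class <- cbind(tp = tp, fp = fp, fn = fn, tn = tn)
  rownames(per_class) <- colnames(y_true)
  structure(list(pooled = c(tp = sum(tp), fp = sum(fp),
                            fn = sum(fn), tn = sum(tn)),
                 per_class = per_class),
            class = "confusion_counts")
}

check_binary <- function(m, what) {
  if (!all(m %in% c(0, 1))) {
    stop(what, " must contain only 0/1 entries")
  }
  invisible(TRUE)
}

#' F1 score from a precision/recall pair
#'
#' The harmonic mean `2 * p * r / (p + r)`, with the zero-denominator
#' convention `F1 = 0` when `p + r = 0`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(0.904, 0.761)  # 0.826 to 3 decimals
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from confusion counts
#'
#' Micro mode applies `tp/(tp+fp)`, `tp/(tp+fn)` and the harmonic mean to
#' the pooled counts; macro mode averages per-class values. A zero
#' denominator yields 0 for that quantity (flagged per class in the
#' attribute `zero_denominator`).
#'
#' @param counts a [confusion_counts()] object.
#' @param mode `"micro"` (default) or `"macro"`.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  if (mode == "micro") {
    p <- counts$pooled
    prec <- safe_div(p[["tp"]], p[["tp"]] + p[["fp"]])
    rec <- safe_div(p[["tp"]], p[["tp"]] + p[["fn"]])
    out <- c(precision = prec, recall = rec, f1 = f1_score(prec, rec))
  } else {
    pc <- counts$per_class
    prec <- safe_div(pc[, "tp"], pc[, "tp"] + pc[, "fp"])
    rec <- safe_div(pc[, "tp"], pc[, "tp"] + pc[, "fn"])
    out <- c(precision = mean(prec), recall = mean(rec),
             f1 = mean(f1_score(prec, rec)))
  }
  flagged <- counts$per_class[, "tp"] + counts$per_class[, "fn"] == 0 |
    counts$per_class[, "tp"] + counts$per_class[, "fp"] == 0
  attr(out, "zero_denominator") <- flagged
  out
}

#' Hamming loss
#'
#' Fraction of label slots where prediction and truth differ (mean XOR over
#' the `N x L` matrix).
#'
#' @param y_true,y_pred binary matrices of identical shape.
#' @return Value in `[0, 1]`.
#' @export
hamming_loss <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!identical(dim(y_true), dim(y_pred))) {
    stop("hamming_loss: shape mismatch")
  }
  check_binary(y_true, "y_true")
  check_binary(y_pred, "y_pred")
  mean(y_true != y_pred)
}

#' Repeated k-fold evaluation of the multi-label classifier
#'
#' For every (repeat, fold): fit the single-layer sigmoid classifier on the
#' other folds, predict the held-out fold, and compute precision, recall,
#' F1 and Hamming loss. Features are standardized with training-fold means
#' and standard deviations. Per-(repeat, fold) classifier seeds are derived
#' from `seed`, so the whole report is deterministic.
#'
#' @param features numeric matrix `(N, F)`.
#' @param labels binary matrix `(N, L)`.
#' @param plan a [plan_repeated_kfold()] for the same `N`.
#' @param epochs,lr,batch_size classifier training settings (see
#'   [train_classifier()]).
#' @param threshold decision threshold.
#' @param mode metric averaging, `"micro"` (default) or `"macro"`.
#' @param standardize z-score features using training-fold statistics.
#' @param seed base RNG seed.
#' @return A `metrics_report`: list with `per_fold` (data.frame: repeat,
#'   fold, precision, recall, f1, hamming), `mean`, `sd`, `mode`, and
#'   `zero_denominator_folds` (folds where some class had an empty
#'   denominator).
#' @export
evaluate_cv <- function(features, labels, plan, epochs = 40L, lr = 1e-3,
                        batch_size = 32L, threshold = 0.5,
                        mode = c("micro", "macro"), standardize = TRUE,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "fold_plan"))
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != plan$n || nrow(labels) != plan$n) {
    stop("evaluate_cv: features/labels rows (", nrow(features), "/",
         nrow(labels), ") do not match the fold plan (n = ", plan$n, ")")
  }
  rows_out <- list()
  flagged <- character(0)
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      test_idx <- plan$assignments[[r]][[f]]
      train_idx <- setdiff(seq_len(plan$n), test_idx)
      Xtr <- features[train_idx, , drop = FALSE]
      Xte <- features[test_idx, , drop = FALSE]
      if (standardize) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2, stats::sd)
        sdv[sdv == 0 | !is.finite(sdv)] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
      }
      fit <- train_classifier(Xtr, labels[train_idx, , drop = FALSE],
                              epochs = epochs, lr = lr,
                              batch_size = batch_size,
                              seed = seed + 1000L * r + f)
      pred <- predict_labels(fit, Xte, threshold = threshold)
      truth <- labels[test_idx, , drop = FALSE]
      cc <- confusion_counts(truth, pred)
      prf <- precision_recall_f1(cc, mode = mode)
      if (any(attr(prf, "zero_denominator"))) {
        flagged <- c(flagged, paste0("repeat", r, "/fold", f))
      }
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(repeat_ = r, fold = f,
                   precision = prf[["precision"]],
                   recall = prf[["recall"]], f1 = prf[["f1"]],
                   hamming = hamming_loss(truth, pred))
    }
  }
  per_fold <- do.call(rbind, rows_out)
  metric_cols <- c("precision", "recall", "f1", "hamming")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd),
                 mode = mode,
                 zero_denominator_folds = unique(flagged)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Repeated k-fold metrics (", x$mode, " averaging, ",
      max(x$per_fold$repeat_), " repeats x ", max(x$per_fold$fold),
      " folds)\n", sep = "")
  for (m in c("precision", "recall", "f1", "hamming")) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  if (length(x$zero_denominator_folds)) {
    cat("  zero-denominator convention applied in:",
        paste(x$zero_denominator_folds, collapse = ", "), "\n")
  }
  invisible(x)
}
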