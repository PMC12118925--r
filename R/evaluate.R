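#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled over every
#' (instance, label) cell before computing the scores, so frequent labels
#' dominate. Division by zero (no predicted positives, or no true
#' positives anywhere) yields 0 with a warning.
#'
#' @param y_true,y_pred binary matrices of identical shape.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' micro_scores(rbind(c(1, 0), c(0, 1)), rbind(c(1, 1), c(0, 0)))
#' @export
micro_scores <- function(y_true, y_pred) {
  y_true <- check_binary_matrix(as.matrix(y_true), "y_true")
  y_pred <- check_binary_matrix(as.matrix(y_pred), "y_pred")
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred must have identical dimensions")
  tp <- sum(y_true * y_pred)
  fp <- sum((1 - y_true) * y_pred)
  fn <- sum(y_true * (1 - y_pred))
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; returning 0")
    return(0)
  }
  num / den
}

#' Macro-averaged precision, recall and F1
#'
#' Per-label scores averaged with equal weight per label, so rare labels
#' count as much as frequent ones. Labels with no positive instance in
#' `y_true` are skipped and counted in the `n_labels_skipped` attribute;
#' within a retained label, an empty prediction gives precision 0.
#'
#' @inheritParams micro_scores
#' @return Named numeric vector `c(precision, recall, f1)` with attributes
#'   `per_label_f1` (per retained label) and `n_labels_skipped`.
#' @export
macro_scores <- function(y_true, y_pred) {
  y_true <- check_binary_matrix(as.matrix(y_true), "y_true")
  y_pred <- check_binary_matrix(as.matrix(y_pred), "y_pred")
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred must have identical dimensions")
  support <- colSums(y_true)
  keep <- which(support > 0)
  per <- vapply(keep, function(j) {
    tp <- sum(y_true[, j] * y_pred[, j])
    fp <- sum((1 - y_true[, j]) * y_pred[, j])
    fn <- sum(y_true[, j] * (1 - y_pred[, j]))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))
  if (length(keep) == 0L) stop("no label has a positive instance in y_true")
  out <- c(precision = mean(per[1, ]), recall = mean(per[2, ]),
           f1 = mean(per[3, ]))
  per_f1 <- per[3, ]
  names(per_f1) <- colnames(y_true)[keep] %||% paste0("label", keep)
  attr(out, "per_label_f1") <- per_f1
  attr(out, "n_labels_skipped") <- ncol(y_true) - length(keep)
  out
}

# rank-statistic (Mann-Whitney) AUC with midrank tie handling
auc_rank <- function(truth, score) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged area under the ROC curve
#'
#' Per-label AUROC via the midrank statistic, averaged over labels for
#' which both classes are present; single-class labels are skipped and
#' counted in the `n_labels_skipped` attribute. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param y_true binary matrix.
#' @param y_prob numeric score matrix of the same shape.
#' @return A single number in `[0, 1]` (or `NA` if every label is
#'   single-class) with attributes `per_label_auc` and `n_labels_skipped`.
#' @export
auroc_macro <- function(y_true, y_prob) {
  y_true <- check_binary_matrix(as.matrix(y_true), "y_true")
  y_prob <- as.matrix(y_prob)
  if (!identical(dim(y_true), dim(y_prob)))
    stop("y_true and y_prob must have identical dimensions")
  per <- vapply(seq_len(ncol(y_true)), function(j)
    auc_rank(y_true[, j], y_prob[, j]), numeric(1))
  names(per) <- colnames(y_true) %||% paste0("label", seq_len(ncol(y_true)))
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_label_auc") <- per
  attr(out, "n_labels_skipped") <- sum(is.na(per))
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of label-proportion profiles
#'
#' Compares two vectors of per-label proportions (e.g. the label frequency
#' profiles of a dataset and of a subset) by the two-sample K-S statistic
#' D = sup |ECDF_a - ECDF_b| with the asymptotic p-value. A small D and a
#' large p indicate the subset's label distribution is representative of
#' the full dataset's.
#'
#' @param props_a,props_b numeric vectors of per-label proportions.
#' @return List with `statistic` (D) and `p_value`.
#' @examples
#' ks_compare(c(0, 1), c(0.5, 1))$statistic  # 0.5
#' @export
ks_compare <- function(props_a, props_b) {
  stopifnot(is.numeric(props_a), is.numeric(props_b),
            length(props_a) > 0, length(props_b) > 0)
  kt <- suppressWarnings(stats::ks.test(props_a, props_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Evaluate multi-label probability predictions
#'
#' Computes the micro- and macro-averaged scores, per-label F1, and the
#' macro- and micro-averaged AUROC in one report.
#'
#' @param y_true binary label matrix.
#' @param y_prob probability matrix of the same shape.
#' @param threshold decision threshold applied to `y_prob` for the
#'   classification metrics.
#' @return An object of class `evaluation_report`: list with `micro_f1`,
#'   `micro_precision`, `micro_recall`, `macro_f1`, `macro_precision`,
#'   `macro_recall`, `per_label_f1`, `auroc_macro`, `auroc_micro` (AUC on
#'   the pooled label cells) and `n_labels_skipped` (labels without both
#'   classes, skipped by the macro/AUROC averages).
#' @export
evaluate_predictions <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- check_binary_matrix(as.matrix(y_true), "y_true")
  y_prob <- as.matrix(y_prob)
  y_pred <- apply_threshold(y_prob, threshold)
  mi <- suppressWarnings(micro_scores(y_true, y_pred))
  ma <- macro_scores(y_true, y_pred)
  au <- auroc_macro(y_true, y_prob)
  structure(list(
    micro_f1 = unname(mi["f1"]),
    micro_precision = unname(mi["precision"]),
    micro_recall = unname(mi["recall"]),
    macro_f1 = unname(ma["f1"]),
    macro_precision = unname(ma["precision"]),
    macro_recall = unname(ma["recall"]),
    per_label_f1 = attr(ma, "per_label_f1"),
    auroc_macro = as.numeric(au),
    auroc_micro = auc_rank(as.numeric(y_true), as.numeric(y_prob)),
    n_labels_skipped = attr(au, "n_labels_skipped"),
    threshold = threshold), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report>\n")
  v <- c(`micro-F1` = x$micro_f1, `micro-P` = x$micro_precision,
         `micro-R` = x$micro_recall, `macro-F1` = x$macro_f1,
         `AUROC(macro)` = x$auroc_macro, `AUROC(micro)` = x$auroc_micro)
  print(round(v, digits))
  if (x$n_labels_skipped > 0)
    cat(sprintf("  (%d single-class label(s) skipped in macro averages)\n",
                x$n_labels_skipped))
  invisible(x)
}
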