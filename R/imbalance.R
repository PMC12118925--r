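#' Per-label imbalance ratio (IRLbl)
#'
#' For each label, the positive count of the most frequent label divided by
#' that label's own positive count. The most frequent label scores exactly 1;
#' rarer labels score higher.
#'
#' @param Y binary label matrix or [multilabel_dataset()].
#' @param zero_count how to treat labels with no positive instance (possible
#'   after splitting or undersampling): `"exclude"` returns `NA` for them with
#'   a warning, `"error"` aborts.
#' @return Named numeric vector of length `ncol(Y)`; `NA` marks excluded
#'   labels.
#' @examples
#' Y <- cbind(a = c(1, 1, 1, 1, 0), b = c(1, 1, 0, 0, 0), c = c(1, 0, 0, 0, 0))
#' irlbl(Y)  # 1, 2, 4
#' @export
irlbl <- function(Y, zero_count = c("exclude", "error")) {
  zero_count <- match.arg(zero_count)
  Y <- label_matrix_of(Y)
  counts <- colSums(Y)
  if (any(counts == 0)) {
    if (zero_count == "error")
      stop("label(s) with zero positives: ",
           paste(colnames(Y)[counts == 0], collapse = ", "))
    warning("excluding ", sum(counts == 0),
            " label(s) with zero positives from IRLbl")
  }
  out <- max(counts) / counts
  out[counts == 0] <- NA_real_
  names(out) <- colnames(Y)
  out
}

#' Mean imbalance ratio (MeanIR)
#'
#' Mean of [irlbl()] over all labels (those with at least one positive).
#'
#' @inheritParams irlbl
#' @return A single number, at least 1.
#' @export
mean_ir <- function(Y, zero_count = c("exclude", "error")) {
  mean(irlbl(Y, zero_count), na.rm = TRUE)
}

#' Coefficient of variation of IRLbl (CVIR)
#'
#' Sample standard deviation of the per-label imbalance ratios (divisor
#' `L - 1`) divided by their mean. Zero for perfectly balanced labels; large
#' when imbalance is concentrated in a few labels.
#'
#' @inheritParams irlbl
#' @return A single non-negative number.
#' @export
cvir <- function(Y, zero_count = c("exclude", "error")) {
  ir <- irlbl(Y, zero_count)
  ir <- ir[!is.na(ir)]
  if (length(ir) < 2L)
    stop("CVIR is undefined for fewer than two labels with positives")
  stats::sd(ir) / mean(ir)
}

#' Label cardinality and density
#'
#' Cardinality (`card`) is the mean number of labels per instance; density
#' (`dens`) is cardinality divided by the number of labels.
#'
#' @inheritParams irlbl
#' @return Named numeric vector `c(card = ..., dens = ...)`.
#' @export
card_dens <- function(Y) {
  Y <- label_matrix_of(Y)
  card <- mean(rowSums(Y))
  c(card = card, dens = card / ncol(Y))
}

#' Full imbalance report for a multi-label dataset
#'
#' Computes the descriptive imbalance measures used to characterize
#' multi-label odor datasets: Card, Dens, per-label IRLbl, MeanIR, MaxIR and
#' CVIR.
#'
#' @inheritParams irlbl
#' @return An object of class `imbalance_report`: list with `card`, `dens`,
#'   `irlbl`, `mean_ir`, `max_ir`, `cvir`, `n_labels`, `n_excluded`.
#' @examples
#' Y <- matrix(rbinom(200, 1, 0.3), 50)
#' imbalance_report(Y)
#' @export
imbalance_report <- function(Y, zero_count = c("exclude", "error")) {
  Y <- label_matrix_of(Y)
  ir <- irlbl(Y, zero_count)
  ok <- !is.na(ir)
  cd <- card_dens(Y)
  structure(list(
    card = unname(cd["card"]),
    dens = unname(cd["dens"]),
    irlbl = ir,
    mean_ir = mean(ir[ok]),
    max_ir = max(ir[ok]),
    cvir = if (sum(ok) >= 2L) stats::sd(ir[ok]) / mean(ir[ok]) else NA_real_,
    n_labels = ncol(Y),
    n_excluded = sum(!ok)
  ), class = "imbalance_report")
}

#' @export
print.imbalance_report <- function(x, digits = 3, ...) {
  cat("<imbalance_report>\n")
  v <- c(Card = x$card, Dens = x$dens, CVIR = x$cvir,
         MaxIR = x$max_ir, MeanIR = x$mean_ir)
  print(round(v, digits))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d label(s) with zero positives excluded)\n", x$n_excluded))
  invisible(x)
}

label_matrix_of <- function(Y) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  check_binary_matrix(Y)
}
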