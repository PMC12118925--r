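#' Construct a multi-label dataset
#'
#' The common currency of the pipeline: a feature matrix `X` paired row-wise
#' with a binary label matrix `Y` (molecules x odor descriptors).
#'
#' @param X numeric feature matrix (n x p). May be `NULL` for label-only work
#'   (e.g. imbalance measurement); a 0-column matrix is then stored.
#' @param Y binary label matrix (n x L), entries 0/1.
#' @param label_names character vector of length L. Defaults to `colnames(Y)`
#'   or `"label<j>"`.
#' @param ids molecule identifiers, length n. Defaults to `rownames(Y)` or
#'   `"mol<i>"`.
#' @return An object of class `multilabel_dataset`: a list with elements
#'   `X`, `Y`, `label_names`, `ids`.
#' @details Rows of `Y` with no positive label are permitted at construction
#'   but flagged with a warning, since downstream resampling and stratification
#'   assume every instance carries at least one label.
#' @examples
#' d <- multilabel_dataset(matrix(rnorm(20), 10), cbind(a = rep(1, 10), b = rbinom(10, 1, 0.5)))
#' d
#' @export
multilabel_dataset <- function(X, Y, label_names = NULL, ids = NULL) {
  Y <- check_binary_matrix(Y)
  n <- nrow(Y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n)
    stop(sprintf("X has %d rows but Y has %d", nrow(X), n))
  label_names <- label_names %||% colnames(Y) %||%
    paste0("label", seq_len(ncol(Y)))
  if (length(label_names) != ncol(Y))
    stop("length(label_names) must equal ncol(Y)")
  ids <- as.character(ids %||% rownames(Y) %||% paste0("mol", seq_len(n)))
  if (length(ids) != n) stop("length(ids) must equal nrow(Y)")
  if (n > 0 && any(rowSums(Y) == 0))
    warning(sum(rowSums(Y) == 0), " instance(s) carry no label")
  colnames(Y) <- label_names
  rownames(Y) <- ids
  if (ncol(X) > 0) rownames(X) <- ids
  structure(list(X = X, Y = Y, label_names = label_names, ids = ids),
            class = "multilabel_dataset")
}

#' @export
print.multilabel_dataset <- function(x, ...) {
  cat(sprintf("<multilabel_dataset> %d instances, %d features, %d labels\n",
              nrow(x$Y), ncol(x$X), ncol(x$Y)))
  cat(sprintf("  cardinality %.3f; most frequent label '%s' (%.1f%%)\n",
              mean(rowSums(x$Y)),
              x$label_names[which.max(colSums(x$Y))],
              100 * max(colMeans(x$Y))))
  invisible(x)
}

#' @export
dim.multilabel_dataset <- function(x) dim(x$Y)

#' Subset a multi-label dataset by instance
#'
#' @param x a [multilabel_dataset()].
#' @param i integer or logical row index.
#' @param ... ignored.
#' @return A `multilabel_dataset` with the selected instances.
#' @export
`[.multilabel_dataset` <- function(x, i, ...) {
  suppressWarnings(multilabel_dataset(
    X = x$X[i, , drop = FALSE],
    Y = x$Y[i, , drop = FALSE],
    label_names = x$label_names,
    ids = x$ids[i]
  ))
}
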