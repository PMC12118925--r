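# Problem-transformation multi-label classifiers: Binary Relevance and
# Classifier Chains over pluggable binary base learners.

# ---- base learners -------------------------------------------------------

fit_base <- function(kind, x, y01, ntree = 100, ...) {
  if (length(unique(y01)) == 1L)
    return(list(kind = "constant", value = y01[1]))
  switch(kind,
    logistic = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x), y01, family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      list(kind = "logistic", beta = beta)
    },
    rf = {
      fit <- randomForest::randomForest(
        x, factor(y01, levels = c(0, 1)), ntree = ntree, ...)
      list(kind = "rf", fit = fit)
    },
    knn1 = list(kind = "knn1", x = x, y = y01),
    stop("unknown base learner: ", kind))
}

predict_base <- function(model, x) {
  switch(model$kind,
    constant = rep(model$value, nrow(x)),
    logistic = as.numeric(stats::plogis(cbind(1, x) %*% model$beta)),
    rf = {
      pr <- stats::predict(model$fit, x, type = "prob")
      as.numeric(pr[, "1"])
    },
    knn1 = {
      # label of the nearest training row (Euclidean)
      d2 <- outer(rowSums(x^2), rowSums(model$x^2), "+") -
        2 * tcrossprod(x, model$x)
      model$y[max.col(-d2, ties.method = "first")]
    })
}

# ---- binary relevance ----------------------------------------------------

#' Binary Relevance multi-label classifier
#'
#' Decomposes the multi-label problem into one independent binary
#' classification problem per label and concatenates the per-label
#' decisions. With `base_learner = "rf"` this is the bagged-tree ensemble
#' baseline (one random forest per label).
#'
#' @param x feature matrix (n x p), or a [multilabel_dataset()].
#' @param y binary label matrix (n x C); taken from `x` when it is a
#'   dataset.
#' @param base_learner `"logistic"` (default), `"rf"` (random forest) or
#'   `"knn1"` (1-nearest-neighbour memorizer, useful for sanity checks).
#' @param threshold default decision threshold for `predict`.
#' @param seed RNG seed (matters for `"rf"`).
#' @param ntree trees per forest when `base_learner = "rf"`.
#' @param ... passed to the base learner.
#' @return An object of class `ml_br`. Labels with no positive training
#'   instance get a constant-negative classifier with a warning.
#' @examples
#' x <- matrix(rnorm(100), 50)
#' y <- cbind(a = as.numeric(x[, 1] > 0), b = rbinom(50, 1, 0.3))
#' m <- binary_relevance(x, y)
#' dim(predict(m, x))
#' @export
binary_relevance <- function(x, y = NULL,
                             base_learner = c("logistic", "rf", "knn1"),
                             threshold = 0.5, seed = NULL, ntree = 100,
                             ...) {
  base_learner <- match.arg(base_learner)
  if (inherits(x, "multilabel_dataset")) { y <- x$Y; x <- x$X }
  x <- as.matrix(x); y <- check_binary_matrix(y, "y")
  stopifnot(nrow(x) == nrow(y))
  if (any(colSums(y) == 0))
    warning("label(s) with no positives get a constant-negative classifier: ",
            paste(colnames(y)[colSums(y) == 0], collapse = ", "))
  with_seed(seed, {
    models <- lapply(seq_len(ncol(y)), function(j)
      fit_base(base_learner, x, y[, j], ntree = ntree, ...))
    structure(list(models = models, p = ncol(x),
                   label_names = colnames(y) %||%
                     paste0("label", seq_len(ncol(y))),
                   base_learner = base_learner, threshold = threshold),
              class = "ml_br")
  })
}

#' @export
predict.ml_br <- function(object, newdata, type = c("prob", "class"),
                          threshold = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multilabel_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), object$p))
  P <- vapply(object$models, predict_base, numeric(nrow(newdata)),
              x = newdata)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  colnames(P) <- object$label_names
  if (type == "class") apply_threshold(P, threshold %||% object$threshold)
  else P
}

#' @export
print.ml_br <- function(x, ...) {
  cat(sprintf("<ml_br> %d labels, base learner '%s'\n",
              length(x$models), x$base_learner))
  invisible(x)
}

# ---- classifier chain ----------------------------------------------------

#' Classifier Chain multi-label classifier
#'
#' Like Binary Relevance, but classifier j sees the feature matrix
#' augmented with the 0/1 relevances of the j-1 labels earlier in the
#' chain, so correlations between labels can be exploited. Training uses
#' the true earlier labels; prediction feeds each classifier the chain's
#' own thresholded outputs.
#'
#' @inheritParams binary_relevance
#' @param chain_order integer permutation of the labels; default is dataset
#'   order, or a seeded shuffle when `shuffle_order = TRUE`.
#' @param shuffle_order randomly permute the chain order (seeded).
#' @return An object of class `ml_cc`; `$chain_order` records the order
#'   used.
#' @export
classifier_chain <- function(x, y = NULL,
                             base_learner = c("logistic", "rf", "knn1"),
                             chain_order = NULL, shuffle_order = FALSE,
                             threshold = 0.5, seed = NULL, ntree = 100,
                             ...) {
  base_learner <- match.arg(base_learner)
  if (inherits(x, "multilabel_dataset")) { y <- x$Y; x <- x$X }
  x <- as.matrix(x); y <- check_binary_matrix(y, "y")
  stopifnot(nrow(x) == nrow(y))
  C <- ncol(y)
  with_seed(seed, {
    chain_order <- chain_order %||%
      (if (shuffle_order) sample.int(C) else seq_len(C))
    stopifnot(length(chain_order) == C,
              setequal(chain_order, seq_len(C)))
    if (any(colSums(y) == 0))
      warning("label(s) with no positives get a constant-negative ",
              "classifier: ",
              paste(colnames(y)[colSums(y) == 0], collapse = ", "))
    models <- vector("list", C)
    aug <- x
    for (j in seq_len(C)) {
      l <- chain_order[j]
      models[[j]] <- fit_base(base_learner, aug, y[, l], ntree = ntree, ...)
      aug <- cbind(aug, y[, l])   # true relevances during training
    }
    structure(list(models = models, p = ncol(x),
                   chain_order = chain_order,
                   label_names = colnames(y) %||% paste0("label", seq_len(C)),
                   base_learner = base_learner, threshold = threshold),
              class = "ml_cc")
  })
}

#' @export
predict.ml_cc <- function(object, newdata, type = c("prob", "class"),
                          threshold = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multilabel_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), object$p))
  thr <- threshold %||% object$threshold
  C <- length(object$models)
  P <- matrix(NA_real_, nrow(newdata), C)
  aug <- newdata
  for (j in seq_len(C)) {
    pj <- predict_base(object$models[[j]], aug)
    P[, object$chain_order[j]] <- pj
    aug <- cbind(aug, as.numeric(pj >= thr))   # chain's own relevances
  }
  colnames(P) <- object$label_names
  if (type == "class") apply_threshold(P, thr) else P
}

#' @export
print.ml_cc <- function(x, ...) {
  cat(sprintf("<ml_cc> %d labels, base learner '%s', order %s...\n",
              length(x$models), x$base_learner,
              paste(utils::head(x$chain_order, 5), collapse = ",")))
  invisible(x)
}
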