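#' Shapley-value feature attribution
#'
#' Attributes each prediction to the input features by Shapley values,
#' treating features as players of a cooperative game whose value for a
#' coalition S is the model output with the features in S taken from the
#' explained instance and the rest imputed from background rows. For
#' `K <= 12` features (or `exact = TRUE`) the sum over all coalitions is
#' enumerated; otherwise a Monte-Carlo estimate over sampled feature
#' orderings is used (one background row drawn per ordering), which
#' converges to the exact value as `n_permutations` grows.
#'
#' The base value `phi0` is the mean model output over the background, so
#' under exact enumeration `phi0 + sum(phi)` reconstructs each prediction
#' (efficiency); the residual is reported as `efficiency_gap` and is
#' Monte-Carlo noise under sampling.
#'
#' @param model a fitted model (anything `predict_fn` understands).
#' @param x instances to explain: matrix (n x K) or a single numeric
#'   vector.
#' @param background non-empty matrix of reference rows used to impute
#'   absent features (typically held-out test rows).
#' @param n_permutations sampled feature orderings per instance (ignored
#'   under exact enumeration).
#' @param seed RNG seed; estimates are deterministic given the seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   enumerates when `K <= 12`.
#' @param predict_fn `function(model, X)` returning an `nrow(X) x C`
#'   probability matrix (a returned vector is treated as one output).
#'   Defaults to `predict(model, X, type = "prob")`.
#' @return An object of class `shapley_attribution`: list with `phi`
#'   (array n x K x C), `phi0` (length-C base values), `efficiency_gap`
#'   (n x C), `exact`, and the feature/label names.
#' @examples
#' f <- function(m, X) cbind(X[, 1] + X[, 2])
#' sh <- shapley_values(NULL, c(2, 3), matrix(0, 4, 2), predict_fn = f)
#' sh$phi[1, , 1]  # 2 3
#' @export
shapley_values <- function(model, x, background, n_permutations = 100,
                           seed = NULL, exact = NULL, predict_fn = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be non-empty")
  if (ncol(background) != ncol(x))
    stop("x and background must have the same number of features")
  K <- ncol(x)
  exact <- exact %||% (K <= 12)
  if (!exact && n_permutations < 1) stop("n_permutations must be >= 1")
  predict_fn <- predict_fn %||%
    function(m, X) stats::predict(m, X, type = "prob")
  pf <- function(X) {
    out <- predict_fn(model, X)
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(X))
    as.matrix(out)
  }
  bg_pred <- pf(background)
  C <- ncol(bg_pred)
  phi0 <- colMeans(bg_pred)
  fx <- pf(x)
  phi <- if (exact) shapley_exact(pf, x, background, C)
         else with_seed(seed,
                shapley_sample(pf, x, background, C, n_permutations))
  gap <- fx - matrix(phi0, nrow(x), C, byrow = TRUE) -
    apply(phi, c(1, 3), sum)
  dimnames(phi) <- list(rownames(x),
                        colnames(x) %||% paste0("f", seq_len(K)),
                        colnames(fx) %||% paste0("y", seq_len(C)))
  structure(list(phi = phi, phi0 = phi0, efficiency_gap = gap,
                 exact = exact, feature_names = dimnames(phi)[[2]],
                 label_names = dimnames(phi)[[3]]),
            class = "shapley_attribution")
}

# exact enumeration over all 2^K coalitions
shapley_exact <- function(pf, x, background, C) {
  K <- ncol(x); nx <- nrow(x); nb <- nrow(background)
  nS <- 2L^K
  sizes <- vapply(0:(nS - 1L), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(K - 1L))) != 0), numeric(1))
  # v[[s+1]]: nx x C coalition values
  v <- vector("list", nS)
  for (s in 0:(nS - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(K - 1L))) != 0)
    # hybrids: every background row per explained instance
    Z <- background[rep(seq_len(nb), times = nx), , drop = FALSE]
    if (length(members)) {
      xi <- x[rep(seq_len(nx), each = nb), members, drop = FALSE]
      Z[, members] <- xi
    }
    pred <- pf(Z)
    grp <- rep(seq_len(nx), each = nb)
    v[[s + 1L]] <- rowsum(pred, grp) / nb
  }
  w <- factorial(0:(K - 1L)) * factorial(K - (0:(K - 1L)) - 1L) / factorial(K)
  phi <- array(0, c(nx, K, C))
  for (s in 0:(nS - 1L)) {
    for (i in seq_len(K)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(s, bit) == 0) {
        diffv <- v[[s + bit + 1L]] - v[[s + 1L]]
        phi[, i, ] <- phi[, i, ] + w[sizes[s + 1L] + 1L] *
          array(diffv, c(nx, C))
      }
    }
  }
  phi
}

# Monte-Carlo over feature orderings, one background row per ordering
shapley_sample <- function(pf, x, background, C, n_permutations) {
  K <- ncol(x); nx <- nrow(x); nb <- nrow(background)
  phi <- array(0, c(nx, K, C))
  for (i in seq_len(nx)) {
    acc <- matrix(0, K, C)
    for (t in seq_len(n_permutations)) {
      perm <- sample.int(K)
      b <- background[sample.int(nb, 1L), ]
      # walk the ordering: row j has the first j features of perm set to x
      Z <- matrix(b, K + 1L, K, byrow = TRUE)
      for (j in seq_len(K))
        Z[(j + 1L):(K + 1L), perm[j]] <- x[i, perm[j]]
      pred <- pf(Z)
      acc[perm, ] <- acc[perm, ] +
        (pred[2:(K + 1L), , drop = FALSE] - pred[1:K, , drop = FALSE])
    }
    phi[i, , ] <- acc / n_permutations
  }
  phi
}

#' @export
print.shapley_attribution <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf(
    "<shapley_attribution> %d instance(s), %d features, %d label(s); %s\n",
    d[1], d[2], d[3],
    if (x$exact) "exact enumeration"
    else sprintf("sampled (max |efficiency gap| %.3g)",
                 max(abs(x$efficiency_gap)))))
  invisible(x)
}

#' Per-label top-k features and frequency-weighted union
#'
#' Ranks features for each label by the mean absolute Shapley value over
#' the explained instances, keeps each label's top k, and weights every
#' feature in the union of these top-k sets proportionally to the number
#' of labels whose top-k contains it (weights normalized to sum 1).
#'
#' @param phi a [shapley_values()] result, or an n x K x C array.
#' @param k features retained per label.
#' @return An object of class `attribution_summary`: list with
#'   `importance` (K x C matrix of mean |phi|), `top_features` (per-label
#'   integer vectors), and `weights` (named, over the union, summing
#'   to 1).
#' @export
aggregate_top_features <- function(phi, k = 20) {
  if (inherits(phi, "shapley_attribution")) phi <- phi$phi
  stopifnot(length(dim(phi)) == 3, k >= 1)
  importance <- apply(abs(phi), c(2, 3), mean)
  K <- nrow(importance)
  kk <- min(k, K)
  top <- lapply(seq_len(ncol(importance)), function(j)
    order(-importance[, j], seq_len(K))[seq_len(kk)])
  names(top) <- colnames(importance)
  counts <- table(unlist(top))
  weights <- as.numeric(counts) / sum(counts)
  names(weights) <- rownames(importance)[as.integer(names(counts))] %||%
    names(counts)
  structure(list(importance = importance, top_features = top,
                 weights = weights, k = kk),
            class = "attribution_summary")
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat(sprintf(
    "<attribution_summary> top-%d per label over %d label(s); union size %d\n",
    x$k, length(x$top_features), length(x$weights)))
  invisible(x)
}

#' Overlay feature-importance weights onto an averaged spectrum
#'
#' Builds the table behind importance-overlay plots: every grid position of
#' the mean spectrum with its intensity and the attribution weight of the
#' corresponding feature (0 where the feature is not in any top-k set).
#'
#' @param weights named weights from [aggregate_top_features()]; names must
#'   match the spectrum's feature names, or be integer bin indices.
#' @param mean_spectrum a `spectrum_vector` (see [smooth_vibrational()]) or
#'   a numeric vector of mean intensities.
#' @param grid bin positions when `mean_spectrum` is a bare vector.
#' @return A data.frame with columns `position`, `intensity`, `weight`.
#' @export
overlay_importance <- function(weights, mean_spectrum, grid = NULL) {
  if (inherits(mean_spectrum, "spectrum_vector")) {
    grid <- mean_spectrum$grid
    feat <- paste0(tolower(mean_spectrum$kind), "_", grid)
    mean_spectrum <- mean_spectrum$values
  } else {
    grid <- grid %||% seq_along(mean_spectrum)
    feat <- as.character(seq_along(mean_spectrum))
  }
  stopifnot(length(grid) == length(mean_spectrum))
  w <- numeric(length(grid))
  if (length(weights)) {
    stopifnot(!is.null(names(weights)))
    idx <- match(names(weights), feat)
    if (anyNA(idx)) {
      idx2 <- suppressWarnings(as.integer(names(weights)))
      idx[is.na(idx)] <- idx2[is.na(idx)]
    }
    if (anyNA(idx) || any(idx < 1 | idx > length(grid)))
      stop("weight names must match spectrum features or bin indices")
    w[idx] <- weights
  }
  data.frame(position = grid, intensity = as.numeric(mean_spectrum),
             weight = w)
}
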