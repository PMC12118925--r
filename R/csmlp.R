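#' Cost-sensitive multilayer perceptron for multi-label classification
#'
#' A fully connected feed-forward network with ReLU hidden activations,
#' inverted dropout, one sigmoid output per label, trained with the focal
#' loss ([focal_loss()]) by mini-batch Adam. Cost sensitivity comes entirely
#' from the focal loss: hard and minority-label entries dominate the
#' gradient as `gamma` grows. After each epoch the model is scored on a
#' held-out validation slice (an iterative stratified fraction of the
#' training data) and the weights from the epoch with the best validation
#' micro-F1 are kept.
#'
#' @param x feature matrix (n x p), or a [multilabel_dataset()] (then `y`
#'   is taken from it).
#' @param y binary label matrix (n x C).
#' @param hidden integer vector of hidden layer widths.
#' @param epochs number of passes over the training data.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param dropout dropout probability applied to hidden activations during
#'   training.
#' @param gamma,epsilon focal-loss parameters; see [focal_loss()].
#' @param threshold default decision threshold used by [predict.csmlp()].
#' @param validation_fraction fraction of rows held out (by iterative
#'   stratification) for best-epoch checkpointing; `0` disables
#'   checkpointing and keeps the final weights.
#' @param seed RNG seed; training is deterministic given the seed.
#' @param verbose print per-epoch loss and validation F1.
#' @return An object of class `csmlp` with elements `weights`, `biases`,
#'   `label_names`, `threshold`, `history` (per-epoch loss and validation
#'   micro-F1), `best_epoch` and the configuration.
#' @examples
#' x <- matrix(rnorm(200), 100)
#' y <- cbind(a = as.numeric(x[, 1] > 0), b = as.numeric(x[, 2] > 0))
#' m <- csmlp(x, y, hidden = 8, epochs = 20, seed = 1, verbose = FALSE)
#' head(predict(m, x))
#' @export
csmlp <- function(x, y = NULL, hidden = c(512, 256), epochs = 100,
                  batch_size = 32, learning_rate = 1e-3, dropout = 0.3,
                  gamma = 2, epsilon = 1e-7, threshold = 0.5,
                  validation_fraction = 0.1, seed = NULL, verbose = FALSE) {
  if (inherits(x, "multilabel_dataset")) {
    y <- x$Y
    x <- x$X
  }
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- check_binary_matrix(y, "y")
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2, epochs >= 1,
            threshold > 0, threshold < 1, dropout >= 0, dropout < 1,
            validation_fraction >= 0, validation_fraction < 1,
            all(hidden >= 1))
  if (any(colSums(y) == 0))
    warning("label(s) with no positive instance will emit near-constant ",
            "probabilities: ",
            paste(colnames(y)[colSums(y) == 0], collapse = ", "))

  p <- ncol(x); C <- ncol(y)
  sizes <- c(p, as.integer(hidden), C)
  nl <- length(sizes) - 1L   # number of weight layers

  with_seed(seed, {
    # validation slice for checkpointing
    if (validation_fraction > 0 && nrow(x) >= 10) {
      sp <- suppressWarnings(
        iterative_stratified_split(y, validation_fraction))
      tr <- sp$train; va <- sp$test
    } else {
      tr <- seq_len(nrow(x)); va <- integer(0)
    }
    xt <- x[tr, , drop = FALSE]; yt <- y[tr, , drop = FALSE]
    xv <- x[va, , drop = FALSE]; yv <- y[va, , drop = FALSE]

    # He initialization for the ReLU stack, Glorot-ish for the output
    W <- vector("list", nl); b <- vector("list", nl)
    for (k in seq_len(nl)) {
      sd_k <- if (k < nl) sqrt(2 / sizes[k]) else sqrt(1 / sizes[k])
      W[[k]] <- matrix(stats::rnorm(sizes[k] * sizes[k + 1], sd = sd_k),
                       sizes[k], sizes[k + 1])
      b[[k]] <- numeric(sizes[k + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0L

    best <- list(f1 = -Inf, epoch = 0L, W = W, b = b)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_micro_f1 = numeric(0))
    n_tr <- nrow(xt)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n_tr)]
        xb <- xt[idx, , drop = FALSE]; yb <- yt[idx, , drop = FALSE]
        # forward
        H <- vector("list", nl + 1L); H[[1]] <- xb
        Zs <- vector("list", nl); masks <- vector("list", nl)
        for (k in seq_len(nl)) {
          Z <- sweep(H[[k]] %*% W[[k]], 2, b[[k]], "+")
          Zs[[k]] <- Z
          if (k < nl) {
            A <- Z * (Z > 0)
            if (dropout > 0) {
              m <- matrix(stats::runif(length(A)) >= dropout,
                          nrow(A), ncol(A)) / (1 - dropout)
              A <- A * m
              masks[[k]] <- m
            }
            H[[k + 1]] <- A
          } else {
            H[[k + 1]] <- 1 / (1 + exp(-Z))
          }
        }
        P <- H[[nl + 1]]
        epoch_loss <- epoch_loss + focal_loss(yb, P, gamma, epsilon) *
          nrow(xb)
        # backward
        dZ <- focal_grad_z(yb, P, gamma, epsilon)
        for (k in rev(seq_len(nl))) {
          gW <- crossprod(H[[k]], dZ)
          gb <- colSums(dZ)
          if (k > 1L) {
            dH <- tcrossprod(dZ, W[[k]])
            if (dropout > 0) dH <- dH * masks[[k - 1L]]
            dZ <- dH * (Zs[[k - 1L]] > 0)
          }
          step_k <- step + 1L  # shared timestep; incremented once per batch
          mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gW
          vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gW^2
          mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gb
          vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gb^2
          mhW <- mW[[k]] / (1 - beta1^step_k)
          vhW <- vW[[k]] / (1 - beta2^step_k)
          mhb <- mb[[k]] / (1 - beta1^step_k)
          vhb <- vb[[k]] / (1 - beta2^step_k)
          W[[k]] <- W[[k]] - learning_rate * mhW / (sqrt(vhW) + adam_eps)
          b[[k]] <- b[[k]] - learning_rate * mhb / (sqrt(vhb) + adam_eps)
        }
        step <- step + 1L
      }
      val_f1 <- NA_real_
      if (length(va) > 0) {
        pv <- mlp_forward(xv, W, b)
        val_f1 <- suppressWarnings(
          unname(micro_scores(yv, (pv >= threshold) * 1)["f1"]))
        if (val_f1 > best$f1) {
          best <- list(f1 = val_f1, epoch = epoch, W = W, b = b)
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / n_tr,
        val_micro_f1 = val_f1))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  val micro-F1 %s", epoch,
                        epoch_loss / n_tr,
                        ifelse(is.na(val_f1), "-", sprintf("%.4f", val_f1))))
    }
    if (length(va) == 0 || !is.finite(best$f1)) {
      best <- list(f1 = NA_real_, epoch = epochs, W = W, b = b)
    }
    structure(list(
      weights = best$W, biases = best$b, sizes = sizes,
      label_names = colnames(y) %||% paste0("label", seq_len(C)),
      threshold = threshold, gamma = gamma, epsilon = epsilon,
      dropout = dropout, learning_rate = learning_rate,
      batch_size = batch_size, epochs = epochs,
      best_epoch = best$epoch, best_val_f1 = best$f1,
      history = history, seed = seed), class = "csmlp")
  })
}

mlp_forward <- function(x, W, b) {
  H <- as.matrix(x)
  nl <- length(W)
  for (k in seq_len(nl)) {
    Z <- sweep(H %*% W[[k]], 2, b[[k]], "+")
    H <- if (k < nl) Z * (Z > 0) else 1 / (1 + exp(-Z))
  }
  H
}

#' Predict from a fitted cost-sensitive MLP
#'
#' @param object a fitted [csmlp()] model.
#' @param newdata feature matrix or [multilabel_dataset()].
#' @param type `"prob"` for per-label probabilities, `"class"` for 0/1
#'   decisions at `threshold`.
#' @param threshold decision threshold; defaults to the model's.
#' @param ... ignored.
#' @return Matrix (n x C) of probabilities or 0/1 decisions, labels as
#'   column names.
#' @export
predict.csmlp <- function(object, newdata, type = c("prob", "class"),
                          threshold = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multilabel_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1])
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), object$sizes[1]))
  P <- mlp_forward(newdata, object$weights, object$biases)
  colnames(P) <- object$label_names
  if (type == "class")
    apply_threshold(P, threshold %||% object$threshold)
  else P
}

#' @export
print.csmlp <- function(x, ...) {
  cat(sprintf(
    "<csmlp> layers %s, gamma %.2g, dropout %.2g\n",
    paste(x$sizes, collapse = "-"), x$gamma, x$dropout))
  if (!is.na(x$best_val_f1))
    cat(sprintf("  best epoch %d/%d (validation micro-F1 %.4f)\n",
                x$best_epoch, x$epochs, x$best_val_f1))
  invisible(x)
}

#' Threshold a probability matrix into binary predictions
#'
#' @param prob probability matrix.
#' @param threshold decision threshold; an entry becomes 1 when its
#'   probability is `>= threshold`. Raising the threshold can only turn
#'   predictions off, never on.
#' @return 0/1 matrix of the same shape.
#' @export
apply_threshold <- function(prob, threshold = 0.5) {
  prob <- as.matrix(prob)
  out <- (prob >= threshold) * 1
  dimnames(out) <- dimnames(prob)
  out
}
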