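#' Focal loss for multi-label probability predictions
#'
#' Cross-entropy variant in which each term is down-weighted by how
#' confidently it is already classified:
#' \deqn{FL = -\frac{1}{N}\sum_{i=1}^{N}\sum_{j=1}^{C}
#'   \left[(1-p_{ij})^{\gamma} y_{ij} \log(p_{ij}+\epsilon) +
#'   p_{ij}^{\gamma} (1-y_{ij}) \log(1-p_{ij}+\epsilon)\right]}
#' so easy examples (confident, correct) contribute little and hard or
#' minority-label examples dominate the gradient. With `gamma = 0` this is
#' exactly binary cross-entropy (with the `epsilon` stabilizer).
#'
#' @param y_true binary matrix (N x C).
#' @param y_pred probability matrix in `[0, 1]`, same shape.
#' @param gamma focusing parameter, `>= 0`. Larger values focus the loss
#'   harder on poorly-classified entries.
#' @param epsilon small stability constant added inside the logarithms.
#' @return A single non-negative number: the mean over the N samples of the
#'   summed per-class focal terms.
#' @examples
#' focal_loss(matrix(1), matrix(0.5), gamma = 2, epsilon = 0)  # 0.25 * log(2)
#' @export
focal_loss <- function(y_true, y_pred, gamma = 2, epsilon = 1e-7) {
  y_true <- check_binary_matrix(as.matrix(y_true), "y_true")
  y_pred <- as.matrix(y_pred)
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred must have identical dimensions")
  if (anyNA(y_pred) || any(y_pred < 0) || any(y_pred > 1))
    stop("y_pred must contain probabilities in [0, 1]")
  stopifnot(gamma >= 0, epsilon >= 0, epsilon < 1e-3)
  pos <- (1 - y_pred)^gamma * y_true * log(y_pred + epsilon)
  neg <- y_pred^gamma * (1 - y_true) * log(1 - y_pred + epsilon)
  -sum(pos + neg) / nrow(y_true)
}

# d(FL)/dz for z the pre-sigmoid logits, p = sigmoid(z); includes the 1/N
# factor. Probabilities are clamped away from 0/1 so the gamma < 1 powers
# stay finite; the loss itself is computed unclamped.
focal_grad_z <- function(y, p, gamma, epsilon) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (gamma == 0) {
    dA <- 1 / (pc + epsilon)
    dB <- -1 / (1 - pc + epsilon)
  } else {
    dA <- -gamma * (1 - pc)^(gamma - 1) * log(pc + epsilon) +
      (1 - pc)^gamma / (pc + epsilon)
    dB <- gamma * pc^(gamma - 1) * log(1 - pc + epsilon) -
      pc^gamma / (1 - pc + epsilon)
  }
  -(y * dA + (1 - y) * dB) * pc * (1 - pc) / nrow(as.matrix(y))
}
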