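#' Construct a peak list
#'
#' A raw spectrum for one molecule: positions (wavenumbers in cm^-1 for
#' vibrational spectra, integer m/z for mass spectra) with non-negative
#' intensities.
#'
#' @param positions numeric vector of strictly positive positions.
#' @param intensities numeric vector of non-negative intensities, same length.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(positions, intensities) {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (anyNA(positions) || anyNA(intensities))
    stop("peak list must not contain NA")
  if (any(positions <= 0)) stop("peak positions must be strictly positive")
  if (any(intensities < 0)) stop("peak intensities must be non-negative")
  structure(list(positions = positions, intensities = intensities),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks", length(x$positions)))
  if (length(x$positions))
    cat(sprintf(", positions in [%.4g, %.4g]",
                min(x$positions), max(x$positions)))
  cat("\n")
  invisible(x)
}

#' Smoothing configuration for vibrational spectra
#'
#' Parameters of the Gaussian smearing that projects discrete vibrational
#' peaks onto a bounded frequency scale (BFS). The defaults (sigma = 10 cm^-1,
#' sampling step L = 5 cm^-1, BFS 1-4000 cm^-1) give 800 descriptor values,
#' computed as floor(bfs_hi / L).
#'
#' @param sigma Gaussian kernel width in cm^-1.
#' @param L sampling increment in cm^-1.
#' @param bfs_lo,bfs_hi endpoints of the bounded frequency scale in cm^-1.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(sigma = 10, L = 5, bfs_lo = 1, bfs_hi = 4000) {
  stopifnot(sigma > 0, L > 0, bfs_lo < bfs_hi)
  structure(list(sigma = sigma, L = L, bfs_lo = bfs_lo, bfs_hi = bfs_hi),
            class = "smoothing_config")
}

bfs_grid <- function(cfg) cfg$L * seq_len(floor(cfg$bfs_hi / cfg$L))

#' Gaussian smoothing of a vibrational peak list onto the BFS grid
#'
#' Each peak contributes a Gaussian of unit area scaled by its intensity:
#' s(x) = sum_k I_k / (sigma sqrt(2 pi)) exp(-(x - pos_k)^2 / (2 sigma^2)),
#' evaluated at grid points L, 2L, ..., floor(bfs_hi/L)*L. The kernel is
#' evaluated exactly (no truncation); peaks just outside the BFS contribute
#' through the kernel tail. The sampled vector is then max-normalized to
#' [0, 1] (per spectrum) unless `normalize = FALSE`.
#'
#' @param peaks a [peak_list()] (or a list with `positions`/`intensities`).
#' @param cfg a [smoothing_config()].
#' @param normalize divide by the maximum sampled value (default). An
#'   all-zero spectrum (empty peak list) stays all-zero.
#' @return An object of class `spectrum_vector`: list with `values` (length
#'   `floor(bfs_hi / L)`), `kind = "VS"` and `grid`.
#' @examples
#' sv <- smooth_vibrational(peak_list(2000, 1))
#' length(sv$values)  # 800
#' @export
smooth_vibrational <- function(peaks, cfg = smoothing_config(),
                               normalize = TRUE) {
  if (!inherits(peaks, "peak_list"))
    peaks <- peak_list(peaks$positions, peaks$intensities)
  grid <- bfs_grid(cfg)
  if (length(peaks$positions) == 0L) {
    v <- numeric(length(grid))
  } else {
    # grid x peaks kernel matrix; exact evaluation is cheap at this scale
    K <- stats::dnorm(outer(grid, peaks$positions, "-"), sd = cfg$sigma)
    v <- as.numeric(K %*% peaks$intensities)
    if (normalize && max(v) > 0) v <- v / max(v)
  }
  structure(list(values = v, kind = "VS", grid = grid),
            class = "spectrum_vector")
}

#' Window and normalize a mass spectrum
#'
#' Keeps intensities at integer m/z within `[lo, hi]` (inclusive on both
#' ends; the default 50-262 window gives 213 bins), zero elsewhere, and
#' divides by the maximum intensity within the windowed spectrum so values
#' lie in [0, 1]. A spectrum with no peak in the window stays all-zero.
#'
#' @param peaks a [peak_list()] with integer m/z positions.
#' @param lo,hi integer window endpoints in m/z.
#' @param non_integer `"round"` (default): round non-integer m/z to the
#'   nearest integer with a warning; `"error"`: reject.
#' @return An object of class `spectrum_vector` with `kind = "MS"` and a
#'   `grid` of the integers `lo:hi`.
#' @examples
#' sv <- window_mass_spectrum(peak_list(c(100, 150), c(500, 1000)))
#' sv$values[sv$grid %in% c(100, 150)]  # 0.5 1.0
#' @export
window_mass_spectrum <- function(peaks, lo = 50, hi = 262,
                                 non_integer = c("round", "error")) {
  non_integer <- match.arg(non_integer)
  if (!inherits(peaks, "peak_list"))
    peaks <- peak_list(peaks$positions, peaks$intensities)
  stopifnot(lo == round(lo), hi == round(hi), lo < hi)
  pos <- peaks$positions
  if (any(pos != round(pos))) {
    if (non_integer == "error") stop("non-integer m/z positions")
    warning("rounding non-integer m/z positions to nearest integer")
    pos <- round(pos)
  }
  grid <- lo:hi
  v <- numeric(length(grid))
  keep <- pos >= lo & pos <= hi
  if (any(keep)) {
    idx <- pos[keep] - lo + 1
    # co-incident m/z accumulate
    acc <- tapply(peaks$intensities[keep], idx, sum)
    v[as.integer(names(acc))] <- acc
    if (max(v) > 0) v <- v / max(v)
  }
  structure(list(values = v, kind = "MS", grid = grid),
            class = "spectrum_vector")
}

#' @export
print.spectrum_vector <- function(x, ...) {
  cat(sprintf("<spectrum_vector> kind %s, %d bins, max %.3g\n",
              x$kind, length(x$values), if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Stack spectrum vectors into a feature matrix
#'
#' @param spectra list of `spectrum_vector` objects on identical grids, or a
#'   list of [peak_list()]s together with `featurizer`.
#' @param featurizer optional function mapping a peak list to a
#'   `spectrum_vector` (e.g. `smooth_vibrational` or `window_mass_spectrum`);
#'   applied when `spectra` holds peak lists.
#' @param ... passed on to `featurizer`.
#' @return Numeric matrix, one row per molecule.
#' @export
spectrum_matrix <- function(spectra, featurizer = NULL, ...) {
  if (!is.null(featurizer))
    spectra <- lapply(spectra, featurizer, ...)
  stopifnot(length(spectra) > 0)
  p <- length(spectra[[1]]$values)
  out <- t(vapply(spectra, function(s) {
    if (length(s$values) != p) stop("spectrum vectors differ in length")
    s$values
  }, numeric(p)))
  colnames(out) <- paste0(tolower(spectra[[1]]$kind), "_",
                          spectra[[1]]$grid)
  rownames(out) <- names(spectra)
  out
}

#' Daylight-style path fingerprint from SMILES
#'
#' Hashes all linear fragments of the molecular graph into a fixed-width
#' binary vector (OpenBabel's FP2 path fingerprint, 1024 bits). The
#' fingerprint depends only on the molecular structure, so different SMILES
#' spellings of the same molecule produce identical vectors.
#'
#' @param smiles character vector of valid SMILES strings.
#' @param n_bits fingerprint width; 1024 natively, smaller powers dividing
#'   1024 are obtained by OR-folding.
#' @return If one SMILES is given, an integer 0/1 vector of length `n_bits`;
#'   otherwise a matrix with one row per molecule.
#' @examples
#' \donttest{
#' fp <- smiles_to_fingerprint("CCO")
#' length(fp)  # 1024
#' }
#' @export
smiles_to_fingerprint <- function(smiles, n_bits = 1024) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (n_bits > 1024 || 1024 %% n_bits != 0)
    stop("n_bits must divide 1024")
  names(smiles) <- paste0("m", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparsable SMILES among: ",
                             paste(smiles, collapse = ", "), call. = FALSE)
  )
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid))
    stop("unparsable SMILES: ",
         paste(unname(smiles[!valid]), collapse = ", "), call. = FALSE)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  m <- ChemmineR::as.matrix(fp)
  storage.mode(m) <- "integer"
  if (n_bits < 1024) {
    folds <- split(seq_len(1024), rep(seq_len(n_bits), length.out = 1024))
    m <- vapply(folds, function(j) as.integer(rowSums(m[, j, drop = FALSE]) > 0),
                integer(nrow(m)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  }
  dimnames(m) <- list(NULL, paste0("fp_", seq_len(ncol(m))))
  if (length(smiles) == 1L) m[1, ] else m
}

#' Fuse feature blocks by column-wise concatenation
#'
#' @param blocks named or unnamed list of feature matrices with equal row
#'   counts (one row per molecule).
#' @return A single matrix; the attribute `"blocks"` records each block's
#'   name and column range so fused features can be traced back to their
#'   modality.
#' @examples
#' f <- fuse_features(list(vs = matrix(1, 2, 3), ms = matrix(0, 2, 2)))
#' attr(f, "blocks")
#' @export
fuse_features <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  blocks <- lapply(blocks, as.matrix)
  n <- vapply(blocks, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("feature blocks disagree on row count: ",
         paste(n, collapse = ", "))
  out <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, integer(1)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  attr(out, "blocks") <- data.frame(
    block = names(blocks) %||% paste0("block", seq_along(blocks)),
    start = starts, end = ends, row.names = NULL)
  out
}
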