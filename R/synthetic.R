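#' Configuration for the synthetic odor-dataset generator
#'
#' Defines the statistical shape of a generated multi-label odor dataset:
#' a long-tailed label-frequency distribution (interpolated between a head
#' and a tail frequency, calibrated so the expected number of labels per
#' molecule matches `cardinality_target`), label-specific diagnostic peak
#' positions and fingerprint bits planted with probability `signal_strength`,
#' and uninformative noise peaks. Defaults mirror a 2606-molecule, 109-odor
#' dataset with the most frequent odor on ~27% of molecules, the rarest on
#' <1%, and ~3.16 labels per molecule.
#'
#' @param n_molecules number of molecules to generate.
#' @param n_labels number of odor labels.
#' @param cardinality_target mean number of labels per molecule.
#' @param head_frequency marginal frequency of the most frequent label.
#' @param tail_frequency marginal frequency of the rarest label.
#' @param signal_strength probability that a carried label's diagnostic peak
#'   or fingerprint bit appears in a molecule.
#' @param noise_peaks number of random (label-independent) peaks added per
#'   molecule, and of random fingerprint bits set per molecule.
#' @param n_diag_vs,n_diag_ms,n_diag_fp diagnostic vibrational peaks, mass
#'   peaks and fingerprint bits owned by each label.
#' @param seed RNG seed governing all draws (labels use `seed`, spectra
#'   `seed + 1`, fingerprints `seed + 2`, SMILES assignment `seed + 3`);
#'   `NULL` uses the current RNG stream.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 2606, n_labels = 109,
                         cardinality_target = 3.16,
                         head_frequency = 0.27, tail_frequency = 0.01,
                         signal_strength = 0.9, noise_peaks = 3,
                         n_diag_vs = 3, n_diag_ms = 1, n_diag_fp = 5,
                         seed = NULL) {
  n_molecules <- check_count(n_molecules, "n_molecules")
  n_labels <- check_count(n_labels, "n_labels")
  noise_peaks <- check_count(noise_peaks, "noise_peaks", min = 0L)
  stopifnot(tail_frequency > 0, tail_frequency <= head_frequency,
            head_frequency <= 1,
            cardinality_target >= 1,
            signal_strength >= 0, signal_strength <= 1,
            n_diag_vs >= 1, n_diag_ms >= 1, n_diag_fp >= 1)
  if (cardinality_target > n_labels)
    stop("infeasible config: cardinality_target exceeds n_labels")
  cfg <- structure(list(
    n_molecules = n_molecules, n_labels = n_labels,
    cardinality_target = cardinality_target,
    head_frequency = head_frequency, tail_frequency = tail_frequency,
    signal_strength = signal_strength, noise_peaks = noise_peaks,
    n_diag_vs = n_diag_vs, n_diag_ms = n_diag_ms, n_diag_fp = n_diag_fp,
    seed = seed), class = "synth_config")
  # fail fast on marginals that cannot meet the cardinality target
  label_marginals(cfg)
  cfg
}

# Marginal frequencies: a warped geometric interpolation between head and
# tail, p_l = head * (tail/head)^(((l-1)/(L-1))^theta). theta is solved so
# that sum(p) equals cardinality_target, keeping the head and tail
# frequencies exact and the decay monotone non-increasing.
label_marginals <- function(cfg) {
  L <- cfg$n_labels
  head <- cfg$head_frequency
  tail <- cfg$tail_frequency
  if (L == 1L) return(head)
  if (head == tail) return(rep(head, L))
  f <- function(log_theta) {
    w <- (seq(0, 1, length.out = L))^exp(log_theta)
    sum(head * (tail / head)^w) - cfg$cardinality_target
  }
  lo <- f(-8); hi <- f(8)
  if (sign(lo) == sign(hi))
    stop(sprintf(paste0(
      "infeasible config: cardinality_target %.3g not attainable with ",
      "head %.3g, tail %.3g, %d labels (range ~[%.3g, %.3g])"),
      cfg$cardinality_target, head, tail, L,
      min(lo, hi) + cfg$cardinality_target,
      max(lo, hi) + cfg$cardinality_target))
  theta <- exp(stats::uniroot(f, c(-8, 8), tol = 1e-10)$root)
  head * (tail / head)^((seq(0, 1, length.out = L))^theta)
}

#' Generate a binary label matrix with a long-tailed frequency profile
#'
#' Labels are sampled independently per molecule from the calibrated
#' marginals (see [synth_config()]); molecules that come out with no label
#' are redrawn. Columns are then ordered by realized frequency (stable in
#' design rank) so marginal frequencies are non-increasing in column order.
#'
#' @param cfg a [synth_config()].
#' @return An `n_molecules` x `n_labels` 0/1 matrix with label names
#'   `label001, label002, ...` in decreasing-frequency order and molecule
#'   ids as row names. Deterministic given `cfg$seed`.
#' @examples
#' Y <- generate_label_matrix(synth_config(200, 20, 2.5, 0.4, 0.02, seed = 1))
#' colMeans(Y)
#' @export
generate_label_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- label_marginals(cfg)
  n <- cfg$n_molecules
  L <- cfg$n_labels
  with_seed(cfg$seed, {
    Y <- matrix(as.numeric(stats::runif(n * L) < rep(p, each = n)), n, L)
    repeat {
      empty <- which(rowSums(Y) == 0)
      if (length(empty) == 0L) break
      Y[empty, ] <- as.numeric(
        stats::runif(length(empty) * L) < rep(p, each = length(empty)))
    }
    ord <- order(-colSums(Y), seq_len(L))
    Y <- Y[, ord, drop = FALSE]
    dimnames(Y) <- list(sprintf("mol%04d", seq_len(n)),
                        sprintf("label%03d", seq_len(L)))
    Y
  })
}

#' Generate peak-list spectra with planted label signal
#'
#' Each label owns fixed diagnostic positions (vibrational: wavenumbers in
#' [1, 4000] cm^-1; mass: integer m/z in [50, 262]). A molecule carrying a
#' label includes each of that label's peaks with probability
#' `signal_strength`, plus `noise_peaks` random peaks unrelated to any label.
#' Diagnostic peaks get intensities in [0.5, 1], noise peaks in [0.05, 0.5],
#' so planted signal is present but not trivially separable by intensity
#' alone.
#'
#' @param labels binary label matrix from [generate_label_matrix()].
#' @param cfg the same [synth_config()].
#' @return List with `vs_peaks` and `ms_peaks` (lists of [peak_list()], one
#'   per molecule) and `truth`: per-label diagnostic positions (`$vs`, `$ms`)
#'   for recovery tests.
#' @export
generate_spectra <- function(labels, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- check_binary_matrix(labels)
  n <- nrow(labels); L <- ncol(labels)
  spectra_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1
  with_seed(spectra_seed, {
    vs_cand <- seq(105, 3895, by = 10)  # on the 5 cm^-1 grid, inside the BFS
    ms_cand <- 50:262
    vs_pos <- sample_positions(vs_cand, L * cfg$n_diag_vs)
    ms_pos <- sample_positions(ms_cand, L * cfg$n_diag_ms)
    truth <- list(
      vs = split(vs_pos, rep(seq_len(L), each = cfg$n_diag_vs)),
      ms = split(ms_pos, rep(seq_len(L), each = cfg$n_diag_ms)))
    names(truth$vs) <- names(truth$ms) <- colnames(labels)
    vs_peaks <- vector("list", n)
    ms_peaks <- vector("list", n)
    for (i in seq_len(n)) {
      carried <- which(labels[i, ] == 1)
      vs_p <- unlist(truth$vs[carried], use.names = FALSE)
      ms_p <- unlist(truth$ms[carried], use.names = FALSE)
      vs_p <- vs_p[stats::runif(length(vs_p)) < cfg$signal_strength]
      ms_p <- ms_p[stats::runif(length(ms_p)) < cfg$signal_strength]
      vs_i <- stats::runif(length(vs_p), 0.5, 1)
      ms_i <- stats::runif(length(ms_p), 0.5, 1)
      if (cfg$noise_peaks > 0) {
        vs_p <- c(vs_p, stats::runif(cfg$noise_peaks, 1, 4000))
        ms_p <- c(ms_p, sample(ms_cand, cfg$noise_peaks, replace = TRUE))
        vs_i <- c(vs_i, stats::runif(cfg$noise_peaks, 0.05, 0.5))
        ms_i <- c(ms_i, stats::runif(cfg$noise_peaks, 0.05, 0.5))
      }
      vs_peaks[[i]] <- dedup_peaks(vs_p, vs_i)
      ms_peaks[[i]] <- dedup_peaks(ms_p, ms_i)
    }
    names(vs_peaks) <- names(ms_peaks) <- rownames(labels)
    list(vs_peaks = vs_peaks, ms_peaks = ms_peaks, truth = truth)
  })
}

sample_positions <- function(candidates, k) {
  if (k <= length(candidates)) return(sample(candidates, k))
  warning("more diagnostic positions requested than available; reusing some")
  sample(candidates, k, replace = TRUE)
}

# collapse repeated positions (shared diagnostic peaks) keeping the
# strongest intensity
dedup_peaks <- function(pos, int) {
  if (length(pos) == 0L) return(peak_list(numeric(0), numeric(0)))
  keep <- tapply(int, pos, max)
  peak_list(as.numeric(names(keep)), as.numeric(keep))
}

#' Generate planted binary fingerprints
#'
#' Each label owns `n_diag_fp` fingerprint bits out of 1024; a molecule
#' carrying the label sets each owned bit with probability
#' `signal_strength`, and `noise_peaks` random bits are additionally set per
#' molecule. With `signal_strength = 1` and no noise, a bit is set exactly
#' when some owning label is present.
#'
#' @inheritParams generate_spectra
#' @return An `n x 1024` 0/1 matrix; the attribute `"truth"` holds the
#'   per-label diagnostic bit indices.
#' @export
generate_fingerprints <- function(labels, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- check_binary_matrix(labels)
  n <- nrow(labels); L <- ncol(labels)
  fp_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 2
  with_seed(fp_seed, {
    bits <- sample_positions(seq_len(1024), L * cfg$n_diag_fp)
    truth <- split(bits, rep(seq_len(L), each = cfg$n_diag_fp))
    names(truth) <- colnames(labels)
    FP <- matrix(0, n, 1024)
    for (i in seq_len(n)) {
      carried <- which(labels[i, ] == 1)
      b <- unlist(truth[carried], use.names = FALSE)
      b <- b[stats::runif(length(b)) < cfg$signal_strength]
      if (cfg$noise_peaks > 0)
        b <- c(b, sample(1024, cfg$noise_peaks))
      FP[i, unique(b)] <- 1
    }
    dimnames(FP) <- list(rownames(labels), paste0("fp_", seq_len(1024)))
    attr(FP, "truth") <- truth
    FP
  })
}

# Small built-in vocabulary of valid SMILES (esters, alcohols, ketones,
# aromatics, terpenoid fragments) reused with replacement; the planted
# signal lives in the generated spectra/bits, not in these structures.
smiles_vocabulary <- function() {
  c("CCO", "CCCO", "CCCCO", "CC(C)O", "CC(C)CO", "CCC(C)O",
    "CC(=O)C", "CCC(=O)C", "CCCC(=O)C", "CCC(=O)CC",
    "CC(=O)OC", "CC(=O)OCC", "CC(=O)OCCC", "CCC(=O)OC", "CCC(=O)OCC",
    "OC(=O)C", "OC(=O)CC", "OC(=O)CCC", "OC(=O)CCCC",
    "O=CC", "O=CCC", "O=CCCC", "O=CCCCC",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "COc1ccccc1",
    "Oc1ccccc1", "Cc1ccc(C)cc1", "Cc1ccc(O)cc1", "O=Cc1ccccc1",
    "OCc1ccccc1", "CC(=O)c1ccccc1", "COC(=O)c1ccccc1",
    "CC(C)=CCO", "CC(C)=CCCC(C)=O", "CC1=CCC(CC1)C(C)C",
    "CC(C)C1CCC(C)CC1O", "CCCCCC(=O)OCC", "CCCCC(=O)OC",
    "CCOC(=O)CC", "CCCOC(=O)C", "CCCCOC(=O)C",
    "OCC(O)CO", "CCCCCCO", "CCCCCC=O", "CCCCCCC(=O)C",
    "CC(O)c1ccccc1", "CCOc1ccccc1", "CC(C)Cc1ccccc1")
}

#' Generate a complete synthetic odor study
#'
#' Runs [generate_label_matrix()], [generate_spectra()] and
#' [generate_fingerprints()] under one configuration and attaches SMILES
#' drawn from a built-in vocabulary, producing every input the downstream
#' pipeline needs plus the planted ground truth.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `synthetic_study`: list with `smiles`,
#'   `vs_peaks`, `ms_peaks`, `labels`, `fingerprints` and `truth`
#'   (`$vs`, `$ms`, `$fp` diagnostic positions per label).
#' @examples
#' study <- synthetic_study(synth_config(100, 10, 2, 0.5, 0.05, seed = 1))
#' study$labels[1:3, 1:4]
#' @export
synthetic_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- generate_label_matrix(cfg)
  sp <- generate_spectra(labels, cfg)
  FP <- generate_fingerprints(labels, cfg)
  truth <- list(vs = sp$truth$vs, ms = sp$truth$ms, fp = attr(FP, "truth"))
  attr(FP, "truth") <- NULL
  smiles_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 3
  smiles <- with_seed(smiles_seed,
    sample(smiles_vocabulary(), cfg$n_molecules, replace = TRUE))
  structure(list(smiles = smiles, vs_peaks = sp$vs_peaks,
                 ms_peaks = sp$ms_peaks, labels = labels,
                 fingerprints = FP, truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d molecules, %d labels ",
                     "(head %.1f%%, cardinality %.2f)\n"),
              nrow(x$labels), ncol(x$labels),
              100 * max(colMeans(x$labels)), mean(rowSums(x$labels))))
  invisible(x)
}
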