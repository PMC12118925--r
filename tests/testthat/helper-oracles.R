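# From-scratch oracles, written independently of the package internals.

# per-label imbalance ratio straight from the definition, by explicit loops
irlbl_brute <- function(Y) {
  counts <- vapply(seq_len(ncol(Y)), function(j) sum(Y[, j] == 1), numeric(1))
  vapply(counts, function(cnt) max(counts) / cnt, numeric(1))
}

meanir_brute <- function(Y) mean(irlbl_brute(Y))

cvir_brute <- function(Y) {
  ir <- irlbl_brute(Y)
  m <- mean(ir)
  sqrt(sum((ir - m)^2) / (length(ir) - 1)) / m
}

# random binary label matrix in which every label has >= 1 positive and
# every instance >= 1 label
rand_label_matrix <- function(n, L, p = runif(1, 0.15, 0.6)) {
  Y <- matrix(rbinom(n * L, 1, p), n, L)
  for (j in which(colSums(Y) == 0)) Y[sample.int(n, 1), j] <- 1
  for (i in which(rowSums(Y) == 0)) Y[i, sample.int(L, 1)] <- 1
  Y
}

# exact Shapley values by subset enumeration (single-output model),
# organized differently from the package's bitmask enumeration
shapley_brute <- function(f, x, background) {
  K <- length(x)
  v <- function(S) {
    Z <- background
    if (length(S))
      Z[, S] <- matrix(x[S], nrow(background), length(S), byrow = TRUE)
    mean(f(Z))
  }
  phi <- numeric(K)
  for (i in seq_len(K)) {
    others <- setdiff(seq_len(K), i)
    for (s in 0:length(others)) {
      subsets <- if (s == 0) list(integer(0))
                 else utils::combn(others, s, simplify = FALSE)
      w <- factorial(s) * factorial(K - s - 1) / factorial(K)
      for (S in subsets)
        phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# small planted-signal study reused by the model/attribution tests
make_recovery_study <- function(n = 600, L = 10, seed = 11,
                                signal_strength = 1, noise_peaks = 0) {
  cfg <- synth_config(n, L, cardinality_target = max(1.2, 0.22 * L),
                      head_frequency = 0.4, tail_frequency = 0.05,
                      signal_strength = signal_strength,
                      noise_peaks = noise_peaks, n_diag_ms = 2, seed = seed)
  synthetic_study(cfg)
}
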