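lin_fn <- function(coefs) function(m, X) cbind(as.numeric(X %*% coefs))

test_that("exact Shapley values satisfy the classical axioms", {
  bg <- matrix(0, 5, 3)
  # null player: a feature the model ignores gets exactly zero
  f_ignore <- function(m, X) cbind(X[, 1] * 2 + X[, 3])
  sh <- shapley_values(NULL, c(1, 7, 2), bg, predict_fn = f_ignore)
  expect_true(sh$exact)
  expect_identical(sh$phi[1, 2, 1], 0)
  # additive model over a zero background: phi recovers the addends
  f_add <- function(m, X) cbind(X[, 1] + X[, 2])
  sh2 <- shapley_values(NULL, c(3, -4), matrix(0, 4, 2),
                        predict_fn = f_add)
  expect_equal(unname(sh2$phi[1, , 1]), c(3, -4), tolerance = 1e-12)
  # symmetry: interchangeable features at equal values share credit
  f_mult <- function(m, X) cbind(X[, 1] * X[, 2])
  sh3 <- shapley_values(NULL, c(2, 2), matrix(0.5, 6, 2),
                        predict_fn = f_mult)
  expect_equal(sh3$phi[1, 1, 1], sh3$phi[1, 2, 1], tolerance = 1e-12)
})

test_that("exact enumeration matches an independent brute-force oracle", {
  set.seed(12)
  coefs <- rnorm(4)
  f <- function(X) as.numeric(X %*% coefs) + 0.3 * X[, 1] * X[, 2]
  bg <- matrix(rnorm(20), 5, 4)
  x <- rnorm(4)
  sh <- shapley_values(NULL, x, bg,
                       predict_fn = function(m, X) cbind(f(X)))
  expect_equal(unname(sh$phi[1, , 1]), shapley_brute(f, x, bg),
               tolerance = 1e-10)
})

test_that("efficiency holds exactly under enumeration", {
  set.seed(13)
  f <- function(m, X) cbind(tanh(X[, 1]) + X[, 2] * X[, 3],
                            X[, 1] - exp(-abs(X[, 2])))
  bg <- matrix(rnorm(18), 6, 3)
  x <- matrix(rnorm(6), 2, 3)
  sh <- shapley_values(NULL, x, bg, predict_fn = f)
  expect_lt(max(abs(sh$efficiency_gap)), 1e-6)
  # base value is the mean background prediction
  expect_equal(sh$phi0, colMeans(f(NULL, bg)), tolerance = 1e-12)
})

test_that("background-averaged contributions are centered", {
  # explaining the background rows themselves: per-feature mean phi is 0
  # for an additive model
  set.seed(14)
  coefs <- rnorm(3)
  f <- lin_fn(coefs)
  bg <- matrix(rnorm(15), 5, 3)
  sh <- shapley_values(NULL, bg, bg, predict_fn = f)
  centered <- apply(sh$phi[, , 1], 2, mean)
  expect_equal(unname(centered), rep(0, 3), tolerance = 1e-10)
})

test_that("the sampling estimator converges to the enumerated value", {
  set.seed(15)
  K <- 8
  coefs <- rnorm(K)
  f <- function(m, X) cbind(as.numeric(X %*% coefs) +
                              0.5 * X[, 1] * X[, 2])
  bg <- matrix(rnorm(5 * K), 5, K)
  x <- rnorm(K)
  exact <- shapley_values(NULL, x, bg, predict_fn = f)$phi[1, , 1]
  err <- vapply(c(5, 50, 500), function(np) {
    est <- shapley_values(NULL, x, bg, n_permutations = np, seed = 99,
                          exact = FALSE, predict_fn = f)$phi[1, , 1]
    sqrt(mean((est - exact)^2))
  }, numeric(1))
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.1)
  # deterministic given the seed
  a <- shapley_values(NULL, x, bg, n_permutations = 20, seed = 7,
                      exact = FALSE, predict_fn = f)
  b <- shapley_values(NULL, x, bg, n_permutations = 20, seed = 7,
                      exact = FALSE, predict_fn = f)
  expect_identical(a$phi, b$phi)
  expect_error(shapley_values(NULL, x, bg, n_permutations = 0,
                              exact = FALSE, predict_fn = f),
               "n_permutations")
})

test_that("top-k aggregation weights features by cross-label frequency", {
  # two labels with identical importance profiles
  phi <- array(0, c(4, 6, 2))
  for (l in 1:2) phi[, , l] <- matrix(rep(c(6, 5, 4, 3, 2, 1), each = 4), 4)
  agg <- aggregate_top_features(phi, k = 3)
  expect_equal(agg$top_features[[1]], 1:3)
  expect_equal(agg$top_features[[2]], 1:3)
  expect_length(agg$weights, 3L)          # union collapses
  expect_equal(sum(agg$weights), 1)
  expect_true(all(agg$weights == 1 / 3))
  # one label: uniform weights over its top-k
  agg1 <- aggregate_top_features(phi[, , 1, drop = FALSE], k = 4)
  expect_true(all(agg1$weights == 1 / 4))
  # ranking uses mean |phi|: sign must not matter
  phi2 <- phi
  phi2[, 1, 1] <- -phi2[, 1, 1]
  expect_equal(aggregate_top_features(phi2, k = 3)$top_features[[1]], 1:3)
})

test_that("importance overlays align weights with spectrum bins", {
  ms <- window_mass_spectrum(peak_list(c(60, 100), c(1, 2)))
  empty <- overlay_importance(numeric(0), ms)
  expect_equal(empty$intensity, ms$values)
  expect_true(all(empty$weight == 0))
  w <- c(ms_60 = 0.7, ms_100 = 0.3)
  ov <- overlay_importance(w, ms)
  expect_equal(nrow(ov), 213L)
  expect_equal(ov$weight[ov$position == 60], 0.7)
  expect_equal(sum(ov$weight > 0), 2L)
  expect_error(overlay_importance(c(ms_9999 = 1), ms), "match")
})
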