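test_that("focal loss reproduces hand-computed values and reduces to BCE", {
  # single sample, single class, y = 1, p = 0.5, gamma = 2, eps = 0
  expect_equal(focal_loss(matrix(1), matrix(0.5), gamma = 2, epsilon = 0),
               0.25 * log(2), tolerance = 1e-12)
  expect_equal(0.25 * log(2), 0.17329, tolerance = 1e-4)
  # gamma = 0 equals binary cross-entropy with the same epsilon
  set.seed(1)
  for (rep in 1:20) {
    y <- matrix(rbinom(40, 1, 0.4), 8)
    p <- matrix(runif(40), 8)
    eps <- 1e-7
    bce <- -sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) / nrow(y)
    expect_equal(focal_loss(y, p, gamma = 0, epsilon = eps), bce,
                 tolerance = 1e-10)
  }
  # perfect prediction gives (numerically) zero loss
  y <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(focal_loss(y, y, gamma = 2), 1e-6)
  expect_error(focal_loss(matrix(1), matrix(c(0.2, 0.3), 1)), "dimensions")
  expect_error(focal_loss(matrix(1), matrix(1.2)), "probabilities")
})

test_that("focal modulation only ever shrinks the loss, never below zero", {
  set.seed(2)
  for (rep in 1:20) {
    y <- matrix(rbinom(60, 1, 0.5), 10)
    p <- matrix(runif(60, 0.01, 0.99), 10)
    l0 <- focal_loss(y, p, gamma = 0, epsilon = 0)
    l2 <- focal_loss(y, p, gamma = 2, epsilon = 0)
    expect_gte(l2, 0)
    expect_lte(l2, l0)
  }
})

test_that("the focal-loss gradient matches central finite differences", {
  set.seed(3)
  for (gamma in c(0, 0.5, 2)) {
    z <- matrix(rnorm(12, sd = 2), 3)
    y <- matrix(rbinom(12, 1, 0.5), 3)
    eps <- 1e-7
    p <- 1 / (1 + exp(-z))
    g <- odorclass:::focal_grad_z(y, p, gamma, eps)
    h <- 1e-5
    for (k in seq_along(z)) {
      zp <- z; zp[k] <- zp[k] + h
      zm <- z; zm[k] <- zm[k] - h
      num <- (focal_loss(y, 1 / (1 + exp(-zp)), gamma, eps) -
                focal_loss(y, 1 / (1 + exp(-zm)), gamma, eps)) / (2 * h)
      expect_equal(g[k], num, tolerance = 1e-5)
    }
  }
})

test_that("CSMLP learns planted noiseless signal to high micro-F1", {
  st <- make_recovery_study(n = 400, L = 8, seed = 17)
  X <- spectrum_matrix(st$ms_peaks, window_mass_spectrum)
  sp <- iterative_stratified_split(st$labels, 0.2, seed = 1)
  m <- csmlp(X[sp$train, ], st$labels[sp$train, ], hidden = c(48, 24),
             epochs = 40, seed = 2)
  ev <- evaluate_predictions(st$labels[sp$test, ],
                             predict(m, X[sp$test, ]))
  expect_gt(ev$micro_f1, 0.9)
  # training is deterministic given the seed
  m2 <- csmlp(X[sp$train, ], st$labels[sp$train, ], hidden = c(48, 24),
              epochs = 40, seed = 2)
  expect_identical(m$weights, m2$weights)
  expect_equal(m$best_epoch, m2$best_epoch)
})

test_that("best-epoch checkpointing keeps the stronger weights", {
  st <- make_recovery_study(n = 250, L = 6, seed = 23)
  X <- spectrum_matrix(st$ms_peaks, window_mass_spectrum)
  m1 <- csmlp(X, st$labels, hidden = 16, epochs = 1, seed = 5)
  m40 <- csmlp(X, st$labels, hidden = 16, epochs = 40, seed = 5)
  expect_gte(m40$best_val_f1, m1$best_val_f1)
  expect_gte(m40$best_epoch, 1L)
  # the recorded best epoch attains the historical maximum
  expect_equal(m40$best_val_f1, max(m40$history$val_micro_f1))
})

test_that("prediction thresholds behave monotonically at the extremes", {
  st <- make_recovery_study(n = 120, L = 5, seed = 29)
  X <- spectrum_matrix(st$ms_peaks, window_mass_spectrum)
  m <- csmlp(X, st$labels, hidden = 8, epochs = 3, seed = 1,
             validation_fraction = 0)
  pr <- predict(m, X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(apply_threshold(pr, 1e-12) == 1))
  expect_true(all(apply_threshold(pr, 1 + 1e-9) == 0))
  t1 <- apply_threshold(pr, 0.3)
  t2 <- apply_threshold(pr, 0.7)
  expect_true(all(t2 <= t1))  # raising threshold never switches 0 -> 1
})

test_that("binary relevance with one label matches the bare base learner", {
  set.seed(7)
  x <- matrix(rnorm(120), 60)
  y <- matrix(as.numeric(x[, 1] + 0.2 * rnorm(60) > 0), ncol = 1,
              dimnames = list(NULL, "only"))
  m <- binary_relevance(x, y, base_learner = "logistic")
  bare <- suppressWarnings(glm.fit(cbind(1, x), y[, 1],
                                   family = binomial()))
  expect_equal(unname(predict(m, x)[, 1]),
               unname(as.numeric(plogis(cbind(1, x) %*%
                                          bare$coefficients))),
               tolerance = 1e-8)
  expect_equal(dim(predict(m, x)), c(60L, 1L))
})

test_that("memorizing base learner reaches training micro-F1 of 1", {
  set.seed(8)
  x <- matrix(rnorm(200), 50)  # duplicate-free rows a.s.
  y <- rand_label_matrix(50, 4)
  for (fit in list(binary_relevance(x, y, base_learner = "knn1"),
                   classifier_chain(x, y, base_learner = "knn1"))) {
    pred <- predict(fit, x, type = "class")
    expect_equal(unname(micro_scores(y, pred)["f1"]), 1)
  }
})

test_that("classifier chains see an attribute space grown by one per link", {
  set.seed(9)
  x <- matrix(rnorm(150), 50)
  y <- rand_label_matrix(50, 4)
  m <- classifier_chain(x, y, base_learner = "logistic")
  widths <- vapply(m$models, function(mod) length(mod$beta) - 1L, integer(1))
  expect_equal(widths, 3L + 0:3)
  # one label: identical to binary relevance
  y1 <- y[, 1, drop = FALSE]
  pc <- predict(classifier_chain(x, y1, base_learner = "logistic"), x)
  pb <- predict(binary_relevance(x, y1, base_learner = "logistic"), x)
  expect_equal(pc, pb, tolerance = 1e-10)
})

test_that("chains exploit a duplicated label at least as well as BR", {
  set.seed(10)
  n <- 150
  x <- cbind(rnorm(n), matrix(rnorm(n * 3), n))
  l1 <- as.numeric(x[, 1] + 0.5 * rnorm(n) > 0)
  y <- cbind(a = l1, b = l1)
  te <- sample.int(n, 50)
  tr <- setdiff(seq_len(n), te)
  br <- binary_relevance(x[tr, ], y[tr, ], base_learner = "logistic")
  cc <- classifier_chain(x[tr, ], y[tr, ], base_learner = "logistic")
  acc <- function(p) mean((p[, "b"] >= 0.5) == y[te, "b"])
  expect_gte(acc(predict(cc, x[te, ])) + 0.02, acc(predict(br, x[te, ])))
})

test_that("zero-positive labels degrade to constant-negative classifiers", {
  set.seed(11)
  x <- matrix(rnorm(60), 30)
  y <- cbind(a = rep(1, 30), b = rep(0, 30))
  expect_warning(m <- binary_relevance(x, y, base_learner = "logistic"),
                 "constant-negative")
  p <- predict(m, x)
  expect_true(all(p[, "b"] == 0))
  expect_true(all(p[, "a"] == 1))
})

test_that("the random-forest baseline trains and predicts multi-label", {
  st <- make_recovery_study(n = 150, L = 4, seed = 37)
  X <- spectrum_matrix(st$ms_peaks, window_mass_spectrum)
  m <- binary_relevance(X, st$labels, base_learner = "rf", ntree = 50,
                        seed = 1)
  p <- predict(m, X)
  expect_equal(dim(p), c(150L, 4L))
  expect_true(all(p >= 0 & p <= 1))
  ev <- evaluate_predictions(st$labels, p)
  expect_gt(ev$micro_f1, 0.8)  # planted noiseless signal is learnable
})
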