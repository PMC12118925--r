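make_longtail <- function(n = 200, L = 12, seed = 3) {
  cfg <- synth_config(n, L, cardinality_target = min(2.5, 0.18 * L + 0.6),
                      head_frequency = 0.35, tail_frequency = 0.02,
                      seed = seed)
  Y <- generate_label_matrix(cfg)
  multilabel_dataset(matrix(rnorm(n * 3), n), Y)
}

test_that("ML-ROS appends exactly the prescribed number of clones", {
  d <- make_longtail(100)
  out <- ml_ros(d, percentage = 10, seed = 1)
  expect_equal(nrow(out$Y), 110L)
  # originals untouched, in order
  expect_identical(out$Y[1:100, ], d$Y)
  expect_identical(out$X[1:100, ], d$X)
  # clones are bit-identical copies with traceable ids
  for (i in 101:110) {
    src <- sub("\\.c[0-9]+$", "", out$ids[i])
    expect_true(grepl("\\.c[0-9]+$", out$ids[i]))
    expect_identical(out$Y[i, ], d$Y[which(d$ids == src), ])
  }
  expect_identical(ml_ros(d, 10, seed = 7)$ids, ml_ros(d, 10, seed = 7)$ids)
})

test_that("ML-ROS leaves balanced data unchanged with a warning", {
  Yb <- matrix(1, 30, 3)
  db <- multilabel_dataset(matrix(0, 30, 2), Yb)
  expect_warning(out <- ml_ros(db, 10), "no minority")
  expect_identical(out$Y, db$Y)
})

test_that("every ML-ROS clone carries a minority label of its draw time", {
  d <- make_longtail(150, seed = 9)
  minority0 <- which(irlbl(d$Y) > mean_ir(d$Y))
  out <- suppressWarnings(ml_ros(d, percentage = 20, seed = 2))
  clones <- out$Y[-seq_len(150), , drop = FALSE]
  # each clone must touch at least one label that was minority at some
  # point; the initial minority set is a superset check for the first clone
  expect_true(all(rowSums(clones) >= 1))
  expect_gt(sum(clones[, minority0]), 0)
})

test_that("ML-ROS reduces MeanIR and CVIR on long-tailed data", {
  d <- make_longtail(300, L = 20, seed = 13)
  r0 <- imbalance_report(d)
  out <- ml_ros(d, percentage = 10, seed = 4)
  r1 <- imbalance_report(out)
  expect_lt(r1$mean_ir, r0$mean_ir)
  expect_lt(r1$cvir, r0$cvir)
})

test_that("ML-RUS removes the quota without touching minority labels", {
  d <- make_longtail(100, seed = 5)
  minority0 <- which(irlbl(d$Y) > mean_ir(d$Y))
  out <- ml_rus(d, percentage = 10, seed = 1)
  expect_equal(nrow(out$Y), 90L)
  # undersampling never duplicates and keeps label sets intact
  expect_true(all(out$ids %in% d$ids))
  expect_identical(out$Y, d$Y[match(out$ids, d$ids), ])
  # positives of initially-minority labels are preserved
  expect_equal(colSums(out$Y[, minority0, drop = FALSE]),
               colSums(d$Y[, minority0, drop = FALSE]))
  expect_identical(ml_rus(d, 10, seed = 3)$ids, ml_rus(d, 10, seed = 3)$ids)
})

test_that("ML-RUS warns and stops when every instance is protected", {
  # perfectly balanced: no minority labels, so every row is deletable
  Y <- cbind(a = rep(1, 20), b = rep(1, 20))
  d <- multilabel_dataset(matrix(0, 20, 1), Y)
  out <- ml_rus(d, 10, seed = 1)
  expect_equal(nrow(out$Y), 18L)
  # every instance carries one of the two minority labels b or c
  Y2 <- cbind(a = rep(1, 20),
              b = rep(c(1, 0), each = 10),
              c = rep(c(0, 1), each = 10))
  d2 <- multilabel_dataset(matrix(0, 20, 1), Y2)
  expect_warning(out2 <- ml_rus(d2, 10, seed = 1), "deletable")
  expect_equal(nrow(out2$Y), 20L)
})

test_that("resampled sizes obey the floor formulas across a sweep", {
  # heavy tail of rare labels so the clone quota stays attainable: the
  # algorithm stops early by design once no label remains above the MeanIR
  # threshold
  for (n in c(37, 80, 123, 240)) {
    cfg <- synth_config(n, 30, 2.5, 0.4, 0.01, seed = n)
    d <- multilabel_dataset(NULL, generate_label_matrix(cfg))
    for (P in c(5, 10)) {
      expect_equal(nrow(ml_ros(d, P, seed = 1)$Y), n + floor(n * P / 100))
    }
    for (P in c(5, 10, 25)) {
      expect_equal(nrow(suppressWarnings(ml_rus(d, P, seed = 1))$Y),
                   n - floor(n * P / 100))
    }
  }
})

test_that("ML-ROS stops early with a warning when no minority label is left", {
  # one head label everywhere plus a single rare label: the rare label
  # crosses the fixed MeanIR threshold after very few clones
  Y <- cbind(a = rep(1, 60), b = c(rep(1, 2), rep(0, 58)))
  d <- multilabel_dataset(matrix(0, 60, 1), Y)
  expect_warning(out <- ml_ros(d, percentage = 30, seed = 1), "exhausted")
  expect_lt(nrow(out$Y), 60 + 18)
  expect_gt(nrow(out$Y), 60)
  # the clones it did make all carry the rare label
  clones <- out$Y[-seq_len(60), , drop = FALSE]
  expect_true(all(clones[, "b"] == 1))
})

test_that("ML-ROS never increases MeanIR on imbalanced datasets", {
  # on long-tailed label distributions (the regime oversampling targets)
  # cloning minority carriers can only even out the ratios; near-balanced
  # data may legitimately drift when clones co-carry the majority label
  set.seed(202)
  for (rep in 1:30) {
    L <- sample(8L:20L, 1)
    d <- make_longtail(sample(60:200, 1), L = L, seed = rep)
    out <- suppressWarnings(ml_ros(d, percentage = 20, seed = rep))
    expect_lte(meanir_brute(out$Y), meanir_brute(d$Y) + 1e-12)
  }
})

test_that("iterative stratification balances per-label proportions", {
  d <- make_longtail(400, L = 15, seed = 31)
  sp <- iterative_stratified_split(d, 0.2, seed = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(400))
  expect_lt(abs(length(sp$test) / 400 - 0.2), 0.05)
  # deterministic
  sp2 <- iterative_stratified_split(d, 0.2, seed = 1)
  expect_identical(sp, sp2)
  # per-label train/test gap beats the median of seeded random splits
  gap <- function(tr, te) {
    max(abs(colMeans(d$Y[tr, , drop = FALSE]) -
              colMeans(d$Y[te, , drop = FALSE])))
  }
  g_strat <- gap(sp$train, sp$test)
  set.seed(99)
  g_rand <- replicate(100, {
    te <- sample.int(400, 80)
    gap(setdiff(seq_len(400), te), te)
  })
  expect_lt(g_strat, median(g_rand))
})

test_that("single-label stratification reduces to a plain stratified split", {
  Y <- matrix(rep(1, 50), ncol = 1)
  sp <- iterative_stratified_split(Y, 0.2, seed = 2)
  expect_lte(abs(length(sp$test) - 10), 1)
  # a label with one positive goes to train, with a warning
  Y2 <- cbind(a = rep(1, 40), b = c(1, rep(0, 39)))
  expect_warning(sp2 <- iterative_stratified_split(Y2, 0.25, seed = 3),
                 "single positive")
  expect_true(1 %in% sp2$train)
})
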