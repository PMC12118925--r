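#' Multi-label random oversampling (ML-ROS)
#'
#' Appends `floor(n * percentage / 100)` clones of instances that carry a
#' minority label (a label whose IRLbl exceeds the MeanIR of the input
#' dataset). MeanIR is computed once at the start; the per-label IRLbl is
#' refreshed as cloning proceeds, so a label that crosses the MeanIR
#' threshold stops driving further clones. Each clone is drawn uniformly at
#' random from the bag of (instance, minority-label) pairs. Cloned
#' instances keep their source's features and label set and get ids
#' suffixed `.c1, .c2, ...`.
#'
#' @param d a [multilabel_dataset()].
#' @param percentage size increment as a percentage of `nrow(d$Y)` (10 gives
#'   a 10\% larger dataset).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param recompute_every refresh IRLbl/MeanIR after this many clones
#'   (default 1, i.e. after every clone; larger values trade fidelity for
#'   speed).
#' @return A `multilabel_dataset` with the clones appended. If no minority
#'   label exists at the start the input is returned unchanged with a
#'   warning; if the minority set empties mid-run, cloning stops early with
#'   a warning.
#' @examples
#' Y <- cbind(a = rep(1, 20), b = c(rep(1, 2), rep(0, 18)))
#' d <- multilabel_dataset(matrix(rnorm(20), 20), Y)
#' dim(ml_ros(d, percentage = 10, seed = 1))
#' @export
ml_ros <- function(d, percentage = 10, seed = NULL, recompute_every = 1L) {
  stopifnot(inherits(d, "multilabel_dataset"), percentage > 0)
  recompute_every <- check_count(recompute_every, "recompute_every")
  n0 <- nrow(d$Y)
  quota <- floor(n0 * percentage / 100)
  if (quota == 0L) return(d)
  with_seed(seed, {
    Y <- d$Y
    counts <- colSums(Y)
    origin <- seq_len(n0)         # original source row of every current row
    src <- integer(quota)         # original source row of each clone
    made <- 0L
    meanir0 <- mean_ir_counts(counts)   # fixed threshold, computed once
    minority <- minority_labels(counts, meanir0)
    if (length(minority) == 0L) {
      warning("no minority labels (IRLbl > MeanIR); dataset unchanged")
      return(d)
    }
    while (made < quota) {
      if (made %% recompute_every == 0L)
        minority <- minority_labels(counts, meanir0)
      if (length(minority) == 0L) {
        warning(sprintf(
          "minority labels exhausted after %d of %d clones", made, quota))
        break
      }
      # bag of (instance, minority label) pairs, uniform draw
      sub <- Y[, minority, drop = FALSE]
      bag_rows <- row(sub)[sub == 1]
      pick <- bag_rows[sample.int(length(bag_rows), 1L)]
      made <- made + 1L
      src[made] <- origin[pick]
      origin <- c(origin, origin[pick])
      counts <- counts + Y[pick, ]
      Y <- rbind(Y, Y[pick, , drop = FALSE])
    }
    src <- src[seq_len(made)]
    clone_ids <- paste0(d$ids[src], ".c",
                        stats::ave(src, src, FUN = seq_along))
    suppressWarnings(multilabel_dataset(
      X = rbind(d$X, d$X[src, , drop = FALSE]),
      Y = rbind(d$Y, d$Y[src, , drop = FALSE]),
      label_names = d$label_names,
      ids = c(d$ids, clone_ids)))
  })
}

#' Multi-label random undersampling (ML-RUS)
#'
#' Removes `floor(n * percentage / 100)` instances drawn uniformly at random
#' from those carrying no minority label (IRLbl above the input dataset's
#' MeanIR, computed once at the start). IRLbl is refreshed after each
#' deletion, so instances of labels pushed over the threshold become
#' protected. Minority-label instances are never deleted.
#'
#' @inheritParams ml_ros
#' @param percentage size decrement as a percentage of `nrow(d$Y)`.
#' @return A `multilabel_dataset` with the selected instances removed. If
#'   the deletable pool empties before the quota is met, as many instances
#'   as possible are removed and a warning is issued.
#' @export
ml_rus <- function(d, percentage = 10, seed = NULL, recompute_every = 1L) {
  stopifnot(inherits(d, "multilabel_dataset"), percentage > 0)
  recompute_every <- check_count(recompute_every, "recompute_every")
  n0 <- nrow(d$Y)
  quota <- floor(n0 * percentage / 100)
  if (quota == 0L) return(d)
  with_seed(seed, {
    Y <- d$Y
    counts <- colSums(Y)
    alive <- rep(TRUE, n0)
    removed <- 0L
    meanir0 <- mean_ir_counts(counts)   # fixed threshold, computed once
    minority <- minority_labels(counts, meanir0)
    while (removed < quota) {
      if (removed %% recompute_every == 0L)
        minority <- minority_labels(counts, meanir0)
      protected <- rowSums(Y[, minority, drop = FALSE]) > 0
      pool <- which(alive & !protected)
      if (length(pool) == 0L) {
        warning(sprintf(
          "only %d of %d instances deletable without touching minority labels",
          removed, quota))
        break
      }
      pick <- pool[sample.int(length(pool), 1L)]
      alive[pick] <- FALSE
      counts <- counts - Y[pick, ]
      removed <- removed + 1L
    }
    d[alive]
  })
}

mean_ir_counts <- function(counts) {
  pos <- counts > 0
  mean(max(counts[pos]) / counts[pos])
}

# labels whose current IRLbl strictly exceeds the reference MeanIR
# (zero-count labels excluded)
minority_labels <- function(counts, meanir) {
  pos <- counts > 0
  ir <- rep(NA_real_, length(counts))
  ir[pos] <- max(counts[pos]) / counts[pos]
  which(!is.na(ir) & ir > meanir)
}

#' Iterative stratified train/test split
#'
#' Greedy iterative stratification: labels are processed rarest-first, and
#' each instance carrying the current label is assigned to the partition
#' whose desired count for that label is largest (ties broken by the
#' partition with the larger overall deficit, then by seeded coin flip).
#' This keeps each label's train/test proportions close to its global
#' proportion, which a plain random split cannot guarantee for rare labels.
#'
#' @param d a [multilabel_dataset()] or binary label matrix.
#' @param test_fraction fraction of instances assigned to the test set.
#' @param seed RNG seed; the partition is deterministic given the seed.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' Y <- matrix(rbinom(300, 1, 0.2), 100)
#' Y[rowSums(Y) == 0, 1] <- 1
#' sp <- iterative_stratified_split(Y, 0.2, seed = 1)
#' length(sp$test)
#' @export
iterative_stratified_split <- function(d, test_fraction = 0.2, seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  Y <- label_matrix_of(d)
  n <- nrow(Y); L <- ncol(Y)
  if (any(colSums(Y) == 1L))
    warning("label(s) with a single positive instance go to the training set")
  with_seed(seed, {
    frac <- c(train = 1 - test_fraction, test = test_fraction)
    desired_total <- n * frac
    desired_label <- outer(colSums(Y), frac)   # L x 2
    assigned <- rep(NA_integer_, n)
    repeat {
      remaining <- colSums(Y[is.na(assigned), , drop = FALSE])
      active <- which(remaining > 0)
      if (length(active) == 0L) break
      l <- active[which.min(remaining[active])]
      cand <- which(is.na(assigned) & Y[, l] == 1)
      for (i in cand[sample.int(length(cand))]) {
        dl <- desired_label[l, ]
        best <- which(dl == max(dl))
        if (length(best) > 1L) {
          dt <- desired_total[best]
          best <- best[dt == max(dt)]
          if (length(best) > 1L) best <- sample(best, 1L)
        }
        assigned[i] <- best
        pos <- which(Y[i, ] == 1)
        desired_label[pos, best] <- desired_label[pos, best] - 1
        desired_total[best] <- desired_total[best] - 1
      }
    }
    # label-free instances (none if every row has a label): fill by deficit
    for (i in which(is.na(assigned))) {
      best <- which.max(desired_total)
      assigned[i] <- best
      desired_total[best] <- desired_total[best] - 1
    }
    list(train = which(assigned == 1L), test = which(assigned == 2L))
  })
}
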