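test_that("accuracy is the percentage of matching labels", {
  expect_equal(accuracy(c(0, 1, 2, 2), c(0, 1, 2, 0)), 75)
  expect_equal(accuracy(1:5, 1:5), 100)
  expect_equal(accuracy(c(1, 1), c(0, 0)), 0)
  expect_error(accuracy(integer(0), integer(0)), "empty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("mean IoU reproduces the worked confusion-count example", {
  pred <- matrix(c(0, 1, 0, 1), 2)      # [[0,0],[1,1]] row-wise
  truth <- matrix(c(0, 1, 1, 1), 2)     # [[0,1],[1,1]]
  expect_equal(as.numeric(mean_iou(pred, truth, C = 2)), 7 / 12,
               tolerance = 1e-15)
  expect_equal(as.numeric(mean_iou(truth, truth, C = 2)), 1)
  # completely disjoint binary masks
  a <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(as.numeric(mean_iou(a, 1 - a, C = 2)), 0)
  expect_error(mean_iou(matrix(2, 1), matrix(0, 1), C = 2), "labels")
})

test_that("mean IoU matches a brute-force confusion oracle on random maps", {
  set.seed(1)
  brute <- function(preds, truths, C) {
    tp <- fp <- fn <- numeric(C)
    for (m in seq_along(preds)) {
      p <- preds[[m]]; t <- truths[[m]]
      for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
        for (cl in 0:(C - 1)) {
          if (p[i, j] == cl && t[i, j] == cl) tp[cl + 1] <- tp[cl + 1] + 1
          if (p[i, j] == cl && t[i, j] != cl) fp[cl + 1] <- fp[cl + 1] + 1
          if (p[i, j] != cl && t[i, j] == cl) fn[cl + 1] <- fn[cl + 1] + 1
        }
      }
    }
    d <- tp + fp + fn
    mean((tp / d)[d > 0])
  }
  for (trial in 1:1000) {
    C <- sample(2:4, 1)
    p <- matrix(sample(0:(C - 1), 64, replace = TRUE), 8)
    t <- matrix(sample(0:(C - 1), 64, replace = TRUE), 8)
    expect_equal(as.numeric(mean_iou(p, t, C)), brute(list(p), list(t), C),
                 tolerance = 1e-12)
  }
  # dataset-level aggregation over several maps at once
  ps <- lapply(1:5, function(i) matrix(sample(0:2, 64, TRUE), 8))
  ts <- lapply(1:5, function(i) matrix(sample(0:2, 64, TRUE), 8))
  expect_equal(as.numeric(mean_iou(ps, ts, 3)), brute(ps, ts, 3),
               tolerance = 1e-12)
})

test_that("mean IoU is invariant to map order and joint relabeling", {
  set.seed(2)
  ps <- lapply(1:4, function(i) matrix(sample(0:2, 36, TRUE), 6))
  ts <- lapply(1:4, function(i) matrix(sample(0:2, 36, TRUE), 6))
  ord <- c(3, 1, 4, 2)
  expect_equal(as.numeric(mean_iou(ps, ts, 3)),
               as.numeric(mean_iou(ps[ord], ts[ord], 3)))
  perm <- c(2L, 0L, 1L)   # class permutation applied to both sides
  pp <- lapply(ps, function(m) matrix(perm[m + 1], nrow(m)))
  tt <- lapply(ts, function(m) matrix(perm[m + 1], nrow(m)))
  expect_equal(as.numeric(mean_iou(pp, tt, 3)),
               as.numeric(mean_iou(ps, ts, 3)), tolerance = 1e-12)
})

test_that("empty classes are excluded from the mean and recorded", {
  p <- matrix(c(0, 0, 1, 1), 2)
  t <- matrix(c(0, 1, 1, 1), 2)
  m <- mean_iou(p, t, C = 4)              # classes 2 and 3 absent everywhere
  expect_equal(attr(m, "excluded"), c(2, 3))
  expect_equal(as.numeric(m), (1 / 2 + 2 / 3) / 2)
  # bounds
  expect_gte(as.numeric(m), 0)
  expect_lte(as.numeric(m), 1)
})
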