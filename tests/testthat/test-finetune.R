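test_that("classification focal loss matches its closed forms", {
  # perfect prediction
  expect_equal(focal_loss_classification(c(1, 0), 0L), 0, tolerance = 1e-6)
  # alpha = 1, gamma = 0 reduces exactly to cross-entropy
  set.seed(1)
  for (i in 1:1000) {
    T <- sample(2:6, 1)
    p <- runif(T); p <- p / sum(p)
    t <- sample(0:(T - 1), 1)
    expect_equal(focal_loss_classification(p, t, alpha = 1, gamma = 0),
                 -log(p[t + 1]), tolerance = 1e-10)
  }
  # p_t = 0.5, alpha = 0.25, gamma = 2 -> 0.25 * 0.25 * ln 2
  expect_equal(focal_loss_classification(c(0.5, 0.5), 0L),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_error(focal_loss_classification(c(0.5, 0.5), 2L), "true_class")
})

test_that("segmentation focal loss is the pixel mean of the classification loss", {
  # constant field at p_t = 0.5
  pm <- array(0.5, c(3, 3, 2))
  tm <- matrix(sample(0:1, 9, replace = TRUE), 3)
  expect_equal(focal_loss_segmentation(pm, tm), 0.25 * 0.25 * log(2),
               tolerance = 1e-12)
  # perfect prediction
  ph <- array(0, c(2, 2, 2))
  th <- matrix(c(0L, 1L, 1L, 0L), 2)
  for (i in 1:2) for (j in 1:2) ph[i, j, th[i, j] + 1] <- 1
  expect_equal(focal_loss_segmentation(ph, th), 0, tolerance = 1e-6)
  # reduction oracle on random small maps
  set.seed(2)
  for (rep in 1:50) {
    T <- sample(2:4, 1)
    pm <- array(runif(4 * 4 * T), c(4, 4, T))
    for (i in 1:4) for (j in 1:4) pm[i, j, ] <- pm[i, j, ] / sum(pm[i, j, ])
    tm <- matrix(sample(0:(T - 1), 16, replace = TRUE), 4)
    per_pixel <- mean(sapply(1:16, function(k) {
      i <- (k - 1) %% 4 + 1; j <- (k - 1) %/% 4 + 1
      focal_loss_classification(pm[i, j, ], tm[i, j])
    }))
    expect_equal(focal_loss_segmentation(pm, tm), per_pixel,
                 tolerance = 1e-12)
  }
  expect_error(focal_loss_segmentation(array(0.5, c(2, 2, 2)),
                                       matrix(0L, 3, 3)), "match")
})

test_that("focal loss is non-negative, decreasing in p_t, bounded by CE", {
  pt <- seq(0.01, 0.99, by = 0.01)
  l <- vapply(pt, function(p)
    focal_loss_classification(c(p, 1 - p), 0L, alpha = 1, gamma = 2),
    numeric(1))
  expect_true(all(l >= 0))
  expect_true(all(diff(l) < 0))
  ce <- -log(pt)
  expect_true(all(l <= ce + 1e-12))
})

test_that("stratified splitting partitions the data deterministically", {
  labels <- rep(0:1, each = 50)
  s <- split_dataset(labels, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(s), c(train = 60L, val = 20L, test = 20L))
  expect_identical(s, split_dataset(labels, c(0.6, 0.2, 0.2), seed = 1))
  # partition property over many random cases
  set.seed(3)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    lb <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (min(table(lb)) < 5) next
    sp <- split_dataset(lb, c(0.6, 0.2, 0.2), seed = i)
    all_idx <- sort(c(sp$train, sp$val, sp$test))
    expect_identical(all_idx, seq_len(n))
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$val, sp$test), 0)
  }
  expect_error(split_dataset(c(0, 0, 1), c(0.6, 0.2, 0.2), seed = 1),
               "too few")
})

test_that("head replacement transfers the backbone bit for bit", {
  set.seed(4)
  bb <- build_csat(tiny_csat_config(), head = "none")
  before <- rckd:::flatten_params(bb)
  m_cls <- replace_head(bb, "classification", classes = 4)
  m_seg <- replace_head(bb, "segmentation", classes = 2)
  expect_identical(rckd:::flatten_params(m_cls$children$backbone), before)
  expect_identical(rckd:::flatten_params(m_seg$children$backbone), before)
  expect_error(replace_head(bb, "classification", classes = 1), "2 classes")
  # classification head: probability vector over T summing to 1
  p <- nn_forward(m_cls, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  expect_length(p, 4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # segmentation head: per-pixel softmax over T channels
  q <- nn_forward(m_seg, array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  expect_equal(dim(q), c(32L, 32L, 2L, 1L))
  expect_equal(apply(q[, , , 1], c(1, 2), sum),
               matrix(1, 32, 32), tolerance = 1e-12)
})

test_that("the fold protocol respects patience and fold counts", {
  set.seed(5)
  ds <- make_downstream_dataset("cls", n_per_class = 6L,
                                params = slide_params(width = 32L,
                                                      height = 32L,
                                                      n_blobs = 4,
                                                      radius_range = c(2, 4)),
                                n_classes = 2L, seed = 9L)
  bb <- build_csat(csat_config(stem_channels = 4L,
                               stage_depths = c(1L, 1L, 1L, 1L),
                               stage_transformers = c(0L, 0L, 0L, 0L),
                               stage_channels = c(4L, 6L, 8L, 10L),
                               pooled_size = 2L, conv_expansion = 2L,
                               sat_qk_dim = 2L, num_classes = 2L,
                               heads = 2L), head = "none")
  m <- replace_head(bb, "classification", classes = 2)
  # patience = 0: exactly one epoch per fold
  cfg0 <- finetune_config(input_resolution = 32L, learning_rate = 0.01,
                          batch_size = 4L, max_epochs = 10L, patience = 0L,
                          n_folds = 2L, seed = 1L)
  r0 <- finetune(m, ds, cfg0)
  expect_true(all(r0$folds$epochs == 1L))
  expect_equal(nrow(r0$folds), 2L)
  # n_folds fold records, per-fold seeds = base + fold - 1
  expect_equal(r0$folds$seed, c(1L, 2L))
  expect_true(is.finite(r0$mean_metric))
})

test_that("a Bayes-separable two-class task is learned to high accuracy", {
  set.seed(33)
  m <- replace_head(build_csat(tiny_csat_config(), head = "none"),
                    "classification", classes = 2)
  ds <- make_downstream_dataset("cls", n_per_class = 30L,
                                params = slide_params(width = 64L,
                                                      height = 64L,
                                                      n_blobs = 5,
                                                      radius_range = c(3, 5)),
                                n_classes = 2L, seed = 11L, effect = 3)
  r <- finetune(m, ds, desk_finetune_config(n_folds = 2L))
  expect_gte(r$mean_metric, 95)
})

test_that("segmentation fine-tuning runs end to end and reports mIoU", {
  set.seed(6)
  ds <- make_downstream_dataset("seg", n_per_class = 8L,
                                params = slide_params(width = 32L,
                                                      height = 32L,
                                                      n_blobs = 5,
                                                      radius_range = c(2, 4)),
                                n_classes = 2L, seed = 13L)
  bb <- build_csat(csat_config(stem_channels = 4L,
                               stage_depths = c(1L, 1L, 1L, 1L),
                               stage_transformers = c(0L, 0L, 0L, 0L),
                               stage_channels = c(4L, 6L, 8L, 10L),
                               pooled_size = 2L, conv_expansion = 2L,
                               sat_qk_dim = 2L, num_classes = 2L,
                               heads = 2L), head = "none")
  m <- replace_head(bb, "segmentation", classes = 2)
  cfg <- finetune_config(input_resolution = 32L, learning_rate = 0.005,
                         head_lr_multiplier = 100, batch_size = 4L,
                         max_epochs = 4L, patience = 4L, n_folds = 2L,
                         seed = 1L)
  r <- finetune(m, ds, cfg)
  expect_equal(nrow(r$folds), 2L)
  expect_true(all(r$folds$test_metric >= 0 & r$folds$test_metric <= 1))
})
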