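test_that("pseudo-label thresholding is inclusive and idempotent", {
  expect_equal(binarize(matrix(0.5), 0.5), matrix(1L))
  expect_equal(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
  expect_equal(binarize(matrix(c(0.2, 0.49, 0.7, 0.51), 2), 0.5),
               matrix(c(0L, 0L, 1L, 1L), 2))
  expect_error(binarize(matrix(c(0.2, 1.3), 1)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:20) {
    y <- matrix(runif(25), 5)
    a <- runif(1, 0.05, 1)
    b <- binarize(y, a)
    expect_identical(binarize(b, a), b)
  }
})

test_that("distillation loss matches closed forms and direct evaluation", {
  ps <- matrix(0.5, 4, 4)
  expect_equal(kd_loss(ps, matrix(c(0, 1), 4, 4)), log(2), tolerance = 1e-12)
  # perfect mimicry at the clamp limits
  t <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(kd_loss(ifelse(t == 1, 1 - 1e-7, 1e-7), t), 1e-6)
  # 2x2 worked example, oracle = direct formula evaluation
  probs <- matrix(c(0.9, 0.8, 0.1, 0.6), 2)
  pseudo <- matrix(c(1, 1, 0, 1), 2)
  oracle <- mean(c(-log(0.9), -log(0.8), -log(0.9), -log(0.6)))
  expect_equal(kd_loss(probs, pseudo), oracle, tolerance = 1e-12)
  expect_gte(kd_loss(probs, pseudo), 0)
  expect_error(kd_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("LARS trust ratio matches its closed form", {
  p <- array(1 / sqrt(4), c(2, 2))          # ||p|| = 1
  g <- array(1 / sqrt(4), c(2, 2))          # ||g|| = 1
  r <- lars_step(p, g, global_lr = 1, trust_coefficient = 0.001,
                 weight_decay = 0, eps = 0)
  expect_equal(r$local_lr, 0.001, tolerance = 1e-15)
  # zero gradient, no decay: parameters unchanged
  r0 <- lars_step(p, array(0, c(2, 2)), global_lr = 1, weight_decay = 0)
  expect_equal(r0$param, p)
  # trust ratio is invariant to joint rescaling of parameters and gradients
  set.seed(2)
  for (i in 1:50) {
    pb <- array(rnorm(12), c(3, 4)); gb <- array(rnorm(12), c(3, 4))
    a <- lars_step(pb, gb, 1, 0.001, 0, eps = 0)
    b <- lars_step(10 * pb, 10 * gb, 1, 0.001, 0, eps = 0)
    expect_equal(a$local_lr, b$local_lr, tolerance = 1e-12)
    # closed form to 1e-12 relative error
    expect_equal(a$local_lr, 0.001 * sqrt(sum(pb^2)) / sqrt(sum(gb^2)),
                 tolerance = 1e-12)
  }
  # zero parameter norm: pass-through local lr of 1, no division error
  rz <- lars_step(array(0, c(2, 2)), g, 1, 0.001, 0)
  expect_equal(rz$local_lr, 1)
})

test_that("pretraining resize is bilinear for images, nearest for masks", {
  img <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  out <- resize_for_pretraining(img, 8L)
  expect_equal(dim(out), c(8L, 8L, 3L))
  # identity resize keeps pixels untouched
  expect_identical(resize_for_pretraining(img, 16L), img)
  # constant image stays constant at any size
  cst <- array(123, c(12, 12, 3))
  expect_true(all(resize_for_pretraining(cst, 20L) == 123))
  # masks stay binary under nearest-neighbour resizing
  msk <- matrix(rbinom(256, 1, 0.3), 16)
  pr <- resize_for_pretraining(img, 8L, mask = msk)
  expect_true(all(pr$mask %in% c(0L, 1L)))
})

test_that("zero-epoch pretraining returns the initial weights unchanged", {
  set.seed(3)
  bb <- build_csat(tiny_csat_config(), head = "none")
  before <- rckd:::flatten_params(bb)
  patches <- make_pretraining_patches(4, tiny_slide_params(), seed = 7)
  pr <- pretrain(bb, teacher_mock(), patches,
                 distill_config(input_size = 64L, epochs = 0L,
                                warmup_epochs = 0L, seed = 1L))
  expect_identical(rckd:::flatten_params(pr$backbone), before)
  expect_equal(nrow(pr$log), 0L)
})

test_that("pretraining is deterministic and reduces the distillation loss", {
  set.seed(4)
  bb <- build_csat(tiny_csat_config(), head = "none")
  patches <- make_pretraining_patches(12, tiny_slide_params(), seed = 7)
  cfg <- distill_config(input_size = 64L, batch_size = 4L, epochs = 14L,
                        warmup_epochs = 3L, peak_lr = 1,
                        trust_coefficient = 0.01, seed = 11L)
  a <- pretrain(bb, teacher_mock(), patches, cfg)
  b <- pretrain(bb, teacher_mock(), patches, cfg)
  expect_identical(a$log, b$log)
  expect_identical(rckd:::flatten_params(a$backbone),
                   rckd:::flatten_params(b$backbone))
  expect_lt(tail(a$log$mean_loss, 1), a$log$mean_loss[1])
})

test_that("pretraining validates its inputs", {
  set.seed(5)
  bb <- build_csat(tiny_csat_config(), head = "none")
  expect_error(pretrain(bb, teacher_mock(), list(),
                        distill_config(input_size = 64L)), "empty image set")
  bad_teacher <- list(predict = function(image) matrix(0.5, 2, 2))
  patches <- make_pretraining_patches(2, tiny_slide_params(), seed = 1)
  expect_error(pretrain(bb, bad_teacher, patches,
                        distill_config(input_size = 64L)),
               "teacher output shape")
  expect_error(distill_config(threshold_alpha = 1.2), "threshold_alpha")
  expect_error(distill_config(epochs = 5, warmup_epochs = 10), "warmup")
})
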