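test_that("patch extraction floor-tiles from the origin in row-major order", {
  img <- array(runif(2048 * 3072 * 3) * 255, c(2048, 3072, 3))
  ps <- extract_patches(img, patch_spec(patch_size = 1024L))
  expect_length(ps, 6)
  expect_equal(vapply(ps, attr, 1L, "row"), rep(1:2, each = 3))
  expect_equal(vapply(ps, attr, 1L, "col"), rep(1:3, times = 2))
  # a single exact tile is the image itself
  one <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- extract_patches(one, patch_spec(patch_size = 32L))
  expect_length(p1, 1)
  expect_equal(as.numeric(p1[[1]]), as.numeric(one))
  # margins are discarded, not padded
  big <- array(runif(1100 * 1100 * 3), c(1100, 1100, 3))
  pm <- extract_patches(big, patch_spec(patch_size = 1024L))
  expect_length(pm, 1)
  expect_equal(dim(pm[[1]])[1:2], c(1024L, 1024L))
  # smaller than one patch: empty with a warning, not an error
  expect_warning(res <- extract_patches(one, patch_spec(patch_size = 64L)),
                 "smaller")
  expect_length(res, 0)
})

test_that("patches reassemble to the covered region", {
  img <- array(runif(64 * 96 * 3) * 255, c(64, 96, 3))
  ps <- extract_patches(img, patch_spec(patch_size = 32L))
  rec <- array(0, c(64, 96, 3))
  for (p in ps) {
    r <- attr(p, "row"); cc <- attr(p, "col")
    rec[(r - 1) * 32 + 1:32, (cc - 1) * 32 + 1:32, ] <- p
  }
  expect_equal(rec, img)
})

test_that("the tissue filter applies inclusive mean-intensity bounds", {
  spec <- patch_spec()
  white <- array(255, c(8, 8, 3))
  expect_false(tissue_filter(white, spec))
  gray <- array(128, c(8, 8, 3))
  expect_true(tissue_filter(gray, spec))
  # half black / half 100: mean exactly 50, kept by the inclusive bound
  half <- array(c(rep(0, 96), rep(100, 96)), c(8, 8, 3))
  expect_equal(mean(half), 50)
  expect_true(tissue_filter(half, spec))
  # exact upper bound is kept too
  hi <- array(245, c(4, 4, 3))
  expect_true(tissue_filter(hi, spec))
  expect_warning(tissue_filter(array(0.5, c(4, 4, 3)), spec), "8-bit")
})

test_that("patch sampling is uniform, without replacement, seed-stable", {
  ps <- lapply(1:10, function(i) array(i, c(2, 2, 3)))
  all10 <- sample_patches(ps, 10, seed = 4)
  expect_setequal(vapply(all10, function(p) p[1], numeric(1)), 1:10)
  expect_identical(sample_patches(ps, 3, seed = 9),
                   sample_patches(ps, 3, seed = 9))
  expect_warning(res <- sample_patches(ps, 12, seed = 1), "taking all")
  expect_length(res, 10)
  # inclusion frequency of each item within 3 sigma of 3/10
  counts <- numeric(10)
  for (i in 1:10000) {
    s <- sample_patches(ps, 3, seed = i)
    ids <- vapply(s, function(p) p[1], numeric(1))
    counts[ids] <- counts[ids] + 1
  }
  p <- 0.3; s3 <- 3 * sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(counts / 10000 - p) < s3 + 1e-9))
})

test_that("the pipeline filters before sampling and reports counts", {
  set.seed(1)
  img <- array(128, c(64, 64, 3))
  img[1:32, , ] <- 255                      # top half is background-white
  img <- img + array(rnorm(64 * 64 * 3), dim(img))
  spec <- patch_spec(patch_size = 32L, sample_n = 2L)
  out <- run_patch_pipeline(img, spec, seed = 5)
  expect_equal(out$n_tiles, 4L)
  expect_equal(out$n_kept, 2L)              # only the bottom-half tiles
  expect_equal(out$n_sampled, 2L)
  expect_true(all(vapply(out$patches, mean, numeric(1)) <= 245))
  expect_equal(sum(out$manifest$kept), 2L)
})

test_that("slide generation is seeded and matches its geometry oracle", {
  p <- slide_params(width = 96L, height = 96L, n_blobs = 10,
                    radius_range = c(3, 6))
  a <- generate_slide(p, seed = 42)
  b <- generate_slide(p, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$nuclei_mask %in% c(0L, 1L)))
  expect_equal(dim(a$image)[1:2], dim(a$nuclei_mask))
  # zero blobs: empty mask, image = background + noise
  z <- generate_slide(slide_params(width = 32L, height = 32L, n_blobs = 0),
                      seed = 1)
  expect_true(all(z$nuclei_mask == 0L))
  expect_error(slide_params(width = 16L, height = 16L,
                            radius_range = c(10, 12)), "radius")
  # Monte-Carlo oracle for the foreground fraction: sample random pixels and
  # an independent draw of the blob process, test coverage analytically
  set.seed(7)
  mc_cover <- replicate(4000, {
    n <- rpois(1, p$n_blobs)
    if (n == 0) return(0)
    px <- runif(1, 1, 96); py <- runif(1, 1, 96)
    cx <- runif(n, 1, 96); cy <- runif(n, 1, 96)
    aa <- runif(n, 3, 6); bb <- runif(n, 3, 6); th <- runif(n, 0, pi)
    u <- (px - cx) * cos(th) + (py - cy) * sin(th)
    v <- -(px - cx) * sin(th) + (py - cy) * cos(th)
    as.numeric(any((u / aa)^2 + (v / bb)^2 <= 1))
  })
  frac <- vapply(1:20, function(i)
    mean(generate_slide(p, seed = 100 + i)$nuclei_mask), numeric(1))
  se <- sqrt(sd(mc_cover)^2 / length(mc_cover) + sd(frac)^2 / length(frac))
  expect_lt(abs(mean(frac) - mean(mc_cover)), 3 * se + 0.01)
})

test_that("downstream datasets respect their label and effect contracts", {
  ds <- make_downstream_dataset("cls", n_per_class = 50L,
                                params = slide_params(width = 32L,
                                                      height = 32L,
                                                      n_blobs = 4,
                                                      radius_range = c(2, 3)),
                                n_classes = 3L, seed = 21L, effect = 3)
  expect_length(ds$items, 150)
  expect_equal(table(vapply(ds$items, function(i) i$label, integer(1))),
               table(rep(0:2, each = 50)))
  # class-conditional blob density rises with the configured effect size:
  # mask fractions must be ordered and well separated between classes
  fr <- vapply(0:2, function(k) {
    idx <- which(vapply(ds$items, function(i) i$label, integer(1)) == k)
    mean(vapply(ds$items[idx],
                function(i) mean(attr(i$image, "nuclei_prob")), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  sg <- make_downstream_dataset("seg", n_per_class = 5L,
                                params = slide_params(width = 32L,
                                                      height = 32L,
                                                      n_blobs = 4,
                                                      radius_range = c(2, 3)),
                                n_classes = 3L, seed = 3L)
  for (it in sg$items) {
    expect_true(all(it$mask >= 0L & it$mask < 3L))
    expect_equal(dim(it$mask), dim(it$image)[1:2])
  }
})
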