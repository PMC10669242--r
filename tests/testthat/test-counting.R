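test_that("parameter counting is exact on closed-form cases", {
  set.seed(1)
  expect_equal(count_parameters(layer_linear(10, 5)), 55)
  expect_equal(count_parameters(layer_conv2d(3, 16, 3)), 9 * 3 * 16 + 16)
  expect_equal(count_parameters(layer_dwconv(8, 7)), 49 * 8 + 8)
  expect_equal(count_parameters(new_sat_module()), 129)
})

test_that("per-layer symbolic parameter formulas agree with the tree count", {
  set.seed(2)
  cfg <- csat_config()
  bb <- build_csat(cfg, head = "none")
  ch <- cfg$stage_channels
  e <- cfg$conv_expansion
  block <- function(D, e) 2 * e * D^2 + (51 + 3 * e) * D + 129
  trans <- function(D, r) (4 + 2 * r) * D^2 + (6 + r) * D
  want <- (3 * 32 * 16 + 32 + 64) +                       # patchify stem + LN
    2 * block(ch[1], e[1]) + 2 * block(ch[2], e[2]) +
    6 * block(ch[3], e[3]) + 4 * block(ch[4], e[4]) +
    2 * trans(ch[3], 3) + 2 * trans(ch[4], 6) +
    9 * ch[1] * ch[2] + 9 * ch[2] * ch[3] +               # downsample convs
    9 * ch[3]^2 + ch[3] * ch[4]                           # stage 3 -> 4
  expect_equal(count_parameters(bb), want)
})

test_that("MAC counting matches hand-derived convolution costs", {
  set.seed(3)
  m <- nn_seq(conv = layer_conv2d(3, 16, 3, stride = 1, pad = 1))
  expect_equal(count_macs(m, c(3, 32, 32)), 9 * 3 * 16 * 32 * 32)  # 442368
  # stride-2 conv halves each output dimension
  m2 <- nn_seq(conv = layer_conv2d(3, 8, 3, stride = 2, pad = 1))
  expect_equal(count_macs(m2, c(3, 32, 32)), 9 * 3 * 8 * 16 * 16)
  expect_error(count_macs(m, c(4, 32, 32)), "channels")
})

test_that("MACs scale with the squared resolution ratio for the conv part", {
  set.seed(4)
  bb <- build_csat(csat_config(), head = "none")
  g224 <- count_macs(bb, c(3, 224, 224))
  g384 <- count_macs(bb, c(3, 384, 384))
  # up to the fixed-size attention-grid terms the network is convolutional
  expect_equal(g384 / g224, (384 / 224)^2, tolerance = 0.02)
  expect_gt(g384, g224)
})

test_that("MAC and parameter accounting degrade correctly without SAT", {
  set.seed(5)
  cfg <- tiny_csat_config()
  with_sat <- build_csat(cfg, head = "none", with_sat = TRUE)
  without <- build_csat(cfg, head = "none", with_sat = FALSE)
  n_blocks <- sum(cfg$stage_depths)
  # each SAT module costs 98 + 9 + (2 qk_dim + 1) + (2 qk_dim + 1) params
  per_mod <- 98 + 9 + 2 * (2 * cfg$sat_qk_dim + 1)
  expect_equal(count_parameters(with_sat) - count_parameters(without),
               n_blocks * per_mod)
  expect_gt(count_macs(with_sat, c(3, 64, 64)),
            count_macs(without, c(3, 64, 64)))
})
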