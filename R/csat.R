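# ---------------------------------------------------------------------------
# CSAT: lightweight hybrid convolution/attention backbone.
#
# Stage layout (384x384 input): patchify stem -> /4; stages run at /4, /8,
# /16, /32 with a stride-2 convolution closing each of stages 1-3 (the third
# one followed by a 1x1 projection to the stage-4 width), as in the
# lightweight hybrid family the design follows.  Stages 3 and 4 append
# pre-norm Transformer blocks after their SAT blocks.
# ---------------------------------------------------------------------------

#' CSAT architectural configuration
#'
#' Holds every architectural hyperparameter of the backbone. The defaults
#' are the published configuration: stage depths 2/2/6/4 with 0/0/2/2
#' trailing Transformer blocks, channels 32/48/96/176, a 7x7 pooled
#' attention grid, and calibrated inner dimensions (per-stage convolution
#' expansions 3/4/6/3, Transformer MLP ratios 3/6 for stages 3 and 4,
#' query/key dimension 5 in the SAT module) under which the full model
#' with a 1000-class head counts 3,065,078 trainable parameters with SAT
#' modules and 3,063,272 without.
#'
#' @param stem_channels channels produced by the patchify stem.
#' @param stage_depths integer vector (length 4): SAT blocks per stage.
#' @param stage_transformers integer vector (length 4): trailing Transformer
#'   blocks per stage.
#' @param stage_channels integer vector (length 4): stage widths.
#' @param pooled_size side length h' = w' of the reduced attention grid.
#' @param conv_expansion expansion ratio of the first 1x1 convolution in a
#'   SAT block; scalar or per-stage vector of length 4.
#' @param transformer_mlp_ratio hidden-width ratio of the Transformer
#'   feed-forward; scalar or one entry per Transformer-bearing stage.
#' @param sat_qk_dim query/key dimension of the SAT module self-attention.
#' @param num_classes classes of the optional classification head.
#' @param heads attention heads in the stage Transformer blocks.
#' @param attn_sigmoid squash the SAT attention map with a sigmoid
#'   (disabled by default; the map is applied as computed).
#' @return an object of class \code{csat_config}.
#' @export
csat_config <- function(stem_channels = 32L,
                        stage_depths = c(2L, 2L, 6L, 4L),
                        stage_transformers = c(0L, 0L, 2L, 2L),
                        stage_channels = c(32L, 48L, 96L, 176L),
                        pooled_size = 7L,
                        conv_expansion = c(3L, 4L, 6L, 3L),
                        transformer_mlp_ratio = c(3L, 6L),
                        sat_qk_dim = 5L,
                        num_classes = 1000L,
                        heads = 4L,
                        attn_sigmoid = FALSE) {
  if (length(stage_depths) != 4L || length(stage_transformers) != 4L ||
      length(stage_channels) != 4L)
    stop("stage_depths, stage_transformers and stage_channels must have length 4",
         call. = FALSE)
  if (pooled_size < 1L) stop("pooled_size must be >= 1", call. = FALSE)
  if (any(stage_channels < 1L) || any(stage_depths < 1L))
    stop("channel counts and depths must be >= 1", call. = FALSE)
  if (length(conv_expansion) == 1L) conv_expansion <- rep(conv_expansion, 4L)
  n_tr_stages <- sum(stage_transformers > 0L)
  if (length(transformer_mlp_ratio) == 1L)
    transformer_mlp_ratio <- rep(transformer_mlp_ratio, max(n_tr_stages, 1L))
  if (length(transformer_mlp_ratio) != n_tr_stages && n_tr_stages > 0L)
    stop("transformer_mlp_ratio needs one entry per Transformer-bearing stage",
         call. = FALSE)
  structure(list(stem_channels = as.integer(stem_channels),
                 stage_depths = as.integer(stage_depths),
                 stage_transformers = as.integer(stage_transformers),
                 stage_channels = as.integer(stage_channels),
                 pooled_size = as.integer(pooled_size),
                 conv_expansion = as.integer(conv_expansion),
                 transformer_mlp_ratio = as.integer(transformer_mlp_ratio),
                 sat_qk_dim = as.integer(sat_qk_dim),
                 num_classes = as.integer(num_classes),
                 heads = as.integer(heads),
                 attn_sigmoid = isTRUE(attn_sigmoid)),
            class = "csat_config")
}

#' @export
print.csat_config <- function(x, ...) {
  cat("CSAT configuration\n")
  cat("  stem:", x$stem_channels, "channels (4x4 patchify)\n")
  for (s in 1:4)
    cat(sprintf("  stage %d: %d SAT + %d Transformer blocks, D = %d\n",
                s, x$stage_depths[s], x$stage_transformers[s],
                x$stage_channels[s]))
  cat("  pooled attention grid:", x$pooled_size, "x", x$pooled_size,
      "| qk dim:", x$sat_qk_dim, "\n")
  invisible(x)
}

new_patchify_stem <- function(config) {
  nn_seq(conv = layer_conv2d(3L, config$stem_channels, 4L, stride = 4L,
                             pad = 0L, bias = TRUE),
         norm = layer_layernorm(config$stem_channels))
}

#' Patchify stem
#'
#' Embeds an RGB image into a 4x-downsampled feature grid via a
#' non-overlapping 4x4 (stride-4) convolution followed by channel-wise layer
#' normalisation. Weights are drawn from the current RNG unless a prebuilt
#' stem module is supplied.
#'
#' @param image array of dim \code{c(H, W, 3, N)} (or \code{c(H, W, 3)}).
#' @param config a [csat_config()].
#' @param stem optional prebuilt stem module (from repeated application).
#' @return feature map of dim \code{c(H/4, W/4, stem_channels, N)}.
#' @export
patchify_stem <- function(image, config = csat_config(), stem = NULL) {
  image <- as_tensor(image)
  d <- dim(image)
  if (d[1] %% 4L != 0L)
    stop(sprintf("height %d is not divisible by 4", d[1]), call. = FALSE)
  if (d[2] %% 4L != 0L)
    stop(sprintf("width %d is not divisible by 4", d[2]), call. = FALSE)
  if (is.null(stem)) stem <- new_patchify_stem(config)
  nn_forward(stem, image)
}

tr_ratio_for_stage <- function(config, stage) {
  idx <- cumsum(config$stage_transformers > 0L)
  config$transformer_mlp_ratio[idx[stage]]
}

new_csat_stage <- function(config, stage, with_sat = TRUE) {
  D <- config$stage_channels[stage]
  blocks <- list()
  for (b in seq_len(config$stage_depths[stage]))
    blocks[[sprintf("sat%d", b)]] <-
      new_sat_block(D, expansion = config$conv_expansion[stage],
                    pooled = config$pooled_size, qk_dim = config$sat_qk_dim,
                    with_sat = with_sat)
  if (config$stage_transformers[stage] > 0L) {
    r <- tr_ratio_for_stage(config, stage)
    for (b in seq_len(config$stage_transformers[stage]))
      blocks[[sprintf("tr%d", b)]] <-
        new_transformer_block(D, mlp_ratio = r, heads = config$heads)
  }
  nn_seq(blocks)
}

new_csat_backbone <- function(config, with_sat = TRUE) {
  ch <- config$stage_channels
  children <- list(
    stem   = new_patchify_stem(config),
    stage1 = new_csat_stage(config, 1L, with_sat),
    ds1    = layer_conv2d(ch[1], ch[2], 3L, stride = 2L, pad = 1L, bias = FALSE),
    stage2 = new_csat_stage(config, 2L, with_sat),
    ds2    = layer_conv2d(ch[2], ch[3], 3L, stride = 2L, pad = 1L, bias = FALSE),
    stage3 = new_csat_stage(config, 3L, with_sat),
    ds3a   = layer_conv2d(ch[3], ch[3], 3L, stride = 2L, pad = 1L, bias = FALSE),
    ds3b   = layer_conv2d(ch[3], ch[4], 1L, bias = FALSE),
    stage4 = new_csat_stage(config, 4L, with_sat)
  )
  new_module("csat_backbone", children = children,
             cfg = list(config = config, with_sat = with_sat))
}

# forward returning the intermediate taps used by U-Net style heads
backbone_fwd_taps <- function(mod, x, keep = FALSE) {
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop(sprintf("input resolution %dx%d must be divisible by 32", d[1], d[2]),
         call. = FALSE)
  ch <- mod$children
  caches <- list()
  o <- fwd(ch$stem, x, keep);   t0 <- o$y; caches$stem <- o$cache
  o <- fwd(ch$stage1, t0, keep); t1 <- o$y; caches$stage1 <- o$cache
  o <- fwd(ch$ds1, t1, keep);   h <- o$y;  caches$ds1 <- o$cache
  o <- fwd(ch$stage2, h, keep); t2 <- o$y; caches$stage2 <- o$cache
  o <- fwd(ch$ds2, t2, keep);   h <- o$y;  caches$ds2 <- o$cache
  o <- fwd(ch$stage3, h, keep); t3 <- o$y; caches$stage3 <- o$cache
  o <- fwd(ch$ds3a, t3, keep);  h <- o$y;  caches$ds3a <- o$cache
  o <- fwd(ch$ds3b, h, keep);   h <- o$y;  caches$ds3b <- o$cache
  o <- fwd(ch$stage4, h, keep); t4 <- o$y; caches$stage4 <- o$cache
  list(taps = list(t0 = t0, t1 = t1, t2 = t2, t3 = t3, t4 = t4),
       cache = if (keep) caches, input_dim = d)
}

backbone_bwd_taps <- function(mod, caches, dtaps) {
  ch <- mod$children
  g <- list()
  o <- bwd(ch$stage4, caches$stage4, dtaps$t4); g$stage4 <- o$grads
  o <- bwd(ch$ds3b, caches$ds3b, o$dx);         g$ds3b <- o$grads
  o <- bwd(ch$ds3a, caches$ds3a, o$dx);         g$ds3a <- o$grads
  dt3 <- o$dx + if (!is.null(dtaps$t3)) dtaps$t3 else 0
  o <- bwd(ch$stage3, caches$stage3, dt3);      g$stage3 <- o$grads
  o <- bwd(ch$ds2, caches$ds2, o$dx);           g$ds2 <- o$grads
  dt2 <- o$dx + if (!is.null(dtaps$t2)) dtaps$t2 else 0
  o <- bwd(ch$stage2, caches$stage2, dt2);      g$stage2 <- o$grads
  o <- bwd(ch$ds1, caches$ds1, o$dx);           g$ds1 <- o$grads
  dt1 <- o$dx + if (!is.null(dtaps$t1)) dtaps$t1 else 0
  o <- bwd(ch$stage1, caches$stage1, dt1);      g$stage1 <- o$grads
  dt0 <- o$dx + if (!is.null(dtaps$t0)) dtaps$t0 else 0
  o <- bwd(ch$stem, caches$stem, dt0);          g$stem <- o$grads
  list(dx = o$dx,
       grads = list(children = g[names(mod$children)]))
}

fwd_csat_backbone <- function(mod, x, keep) {
  o <- backbone_fwd_taps(mod, x, keep)
  list(y = o$taps$t4, cache = if (keep) o$cache)
}

#' Build the CSAT model
#'
#' Assembles stem, four stages (SAT blocks, then Transformer blocks in
#' stages 3 and 4), inter-stage stride-2 downsampling, and an optional task
#' head. The model accepts any input resolution divisible by 32; the pooled
#' attention grid and the convolutional positional encoding make one set of
#' weights applicable across resolutions.
#'
#' @param config a [csat_config()].
#' @param head \code{"none"} (backbone only), \code{"classification"}
#'   (global average pool + linear + softmax to \code{num_classes}), or
#'   \code{"segmentation"} (U-Net style decoder to \code{num_classes}
#'   channels with per-pixel softmax).
#' @param with_sat include SAT modules (\code{FALSE} builds the ablation
#'   variant with every SAT module replaced by the identity).
#' @return a model module; run it with [nn_forward()] or [model_predict()].
#' @examples
#' set.seed(1)
#' m <- build_csat(csat_config(num_classes = 10))
#' count_parameters(m)
#' @export
build_csat <- function(config = csat_config(),
                       head = c("classification", "none", "segmentation"),
                       with_sat = TRUE) {
  head <- match.arg(head)
  backbone <- new_csat_backbone(config, with_sat)
  if (head == "none") return(backbone)
  ch <- config$stage_channels
  hm <- switch(head,
    classification = nn_seq(
      gap = layer_gap(), flat = new_module("flatten"),
      fc = layer_linear(ch[4], config$num_classes, sd = 0.02),
      sm = new_module("softmax")),
    segmentation = new_unet_head(
      enc_channels = c(config$stem_channels, ch),
      out_channels = config$num_classes, out_act = "softmax"))
  hm$cfg$tag <- "head"
  new_module("backbone_with_head",
             children = list(backbone = backbone, head = hm),
             cfg = list(head = head))
}

fwd_backbone_with_head <- function(mod, x, keep) {
  o <- backbone_fwd_taps(mod$children$backbone, x, keep)
  if (mod$children$head$kind == "unet_head") {
    ho <- fwd_unet_head_taps(mod$children$head, o$taps, o$input_dim, keep)
  } else {
    ho <- fwd(mod$children$head, o$taps$t4, keep)
  }
  list(y = ho$y,
       cache = if (keep) list(bb = o$cache, head = ho$cache,
                              input_dim = o$input_dim))
}

bwd_backbone_with_head <- function(mod, cache, dy) {
  if (mod$children$head$kind == "unet_head") {
    ho <- bwd_unet_head_taps(mod$children$head, cache$head, dy)
    dtaps <- ho$dtaps
  } else {
    ho <- bwd(mod$children$head, cache$head, dy)
    dtaps <- list(t4 = ho$dx)
  }
  bo <- backbone_bwd_taps(mod$children$backbone, cache$bb, dtaps)
  list(dx = bo$dx,
       grads = list(children = list(backbone = bo$grads, head = ho$grads)))
}

#' Functional SAT module application
#'
#' Applies a freshly initialised SAT module (weights drawn from the current
#' RNG) to a feature map; mostly useful for inspection and testing. For a
#' persistent module use [new_sat_module()] with [nn_forward()].
#'
#' @param x feature map, dim \code{c(H, W, C, N)}.
#' @param config a [csat_config()] supplying \code{pooled_size} and
#'   \code{sat_qk_dim}.
#' @param module optional prebuilt module.
#' @return array of the same shape as \code{x}.
#' @export
sat_module <- function(x, config = csat_config(), module = NULL) {
  if (is.null(module))
    module <- new_sat_module(config$pooled_size, config$sat_qk_dim,
                             config$attn_sigmoid)
  nn_forward(module, as_tensor(x))
}

#' Functional SAT block application
#'
#' @inheritParams sat_module
#' @param stage which stage's width/expansion to use when building a fresh
#'   block (the input's channel count must equal that stage's width).
#' @param block optional prebuilt block from [new_sat_block()].
#' @return array of the same shape as \code{x}.
#' @export
sat_block <- function(x, config = csat_config(), stage = 1L, block = NULL) {
  x <- as_tensor(x)
  if (is.null(block))
    block <- new_sat_block(dim(x)[3],
                           expansion = config$conv_expansion[stage],
                           pooled = config$pooled_size,
                           qk_dim = config$sat_qk_dim)
  nn_forward(block, x)
}

#' Functional Transformer block application
#'
#' @inheritParams sat_module
#' @param stage Transformer-bearing stage whose MLP ratio to use.
#' @param block optional prebuilt block from [new_transformer_block()].
#' @return array of the same shape as \code{x}.
#' @export
transformer_block <- function(x, config = csat_config(), stage = 3L,
                              block = NULL) {
  x <- as_tensor(x)
  if (is.null(block))
    block <- new_transformer_block(dim(x)[3],
                                   mlp_ratio = tr_ratio_for_stage(config, stage),
                                   heads = min(config$heads, dim(x)[3]))
  nn_forward(block, x)
}

#' Run a model on a batch and return its output
#'
#' Convenience wrapper around [nn_forward()] that accepts images in
#' \code{[0, 255]} or \code{[0, 1]} and scales them to \code{[0, 1]}.
#'
#' @param model a model from [build_csat()] or with a replaced head.
#' @param x input array, dim \code{c(H, W, 3, N)}.
#' @return the model output (class-probability matrix or probability map).
#' @export
model_predict <- function(model, x) {
  x <- as_tensor(x)
  if (max(x) > 1.5) x <- x / 255
  nn_forward(model, x)
}
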