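# ---------------------------------------------------------------------------
# Task heads: U-Net style decoder (pretraining / segmentation) and the
# classification head, plus head replacement for transfer.
# ---------------------------------------------------------------------------

# channel concatenation along dim 3
ccat <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(a) dim(a)[3], numeric(1))
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (a in xs) {
    y[, , at + seq_len(dim(a)[3]), ] <- a
    at <- at + dim(a)[3]
  }
  y
}

csplit <- function(dy, cs) {
  out <- vector("list", length(cs))
  at <- 0L
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

upsample_to <- function(x, H, W) {
  d <- dim(x)
  bilinear_fwd_cpp(x, d[1], d[2], d[3], d[4], as.integer(H), as.integer(W))
}

downsample_grad <- function(dy, Hin, Win) {
  d <- dim(dy)
  bilinear_bwd_cpp(dy, d[1], d[2], d[3], d[4], as.integer(Hin), as.integer(Win))
}

# per-pixel softmax over the channel axis
smch_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(3, 1, 2, 4)), d[3])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  aperm(array(m, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

smch_bwd <- function(y, dy) {
  d <- dim(y)
  ym <- matrix(aperm(y, c(3, 1, 2, 4)), d[3])
  dm <- matrix(aperm(dy, c(3, 1, 2, 4)), d[3])
  dx <- ym * sweep(dm, 2, colSums(dm * ym))
  aperm(array(dx, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

#' Construct a U-Net style decoder head
#'
#' Decodes the backbone's multi-resolution taps back to input resolution:
#' each level bilinearly upsamples, concatenates the corresponding encoder
#' skip (stem and stages 1-3), and applies a 3x3 convolution with GELU;
#' a final 1x1 convolution produces \code{out_channels} maps with a sigmoid
#' (one channel) or per-pixel softmax activation.
#'
#' @param enc_channels encoder widths \code{c(stem, stage1..stage4)}.
#' @param out_channels output maps (1 for binary foreground probability).
#' @param out_act \code{"sigmoid"}, \code{"softmax"} or \code{"none"}.
#' @return a module usable as the head of a backbone.
#' @export
new_unet_head <- function(enc_channels, out_channels = 1L,
                          out_act = c("sigmoid", "softmax", "none")) {
  out_act <- match.arg(out_act)
  c0 <- enc_channels[1]; c1 <- enc_channels[2]; c2 <- enc_channels[3]
  c3 <- enc_channels[4]; c4 <- enc_channels[5]
  ch <- list(
    dec3 = layer_conv2d(c4 + c3, c3, 3L, bias = TRUE),
    dec2 = layer_conv2d(c3 + c2, c2, 3L, bias = TRUE),
    dec1 = layer_conv2d(c2 + c1 + c0, c1, 3L, bias = TRUE),
    dec0 = layer_conv2d(c1, c1, 3L, bias = TRUE),
    out  = layer_conv2d(c1, as.integer(out_channels), 1L, bias = TRUE)
  )
  new_module("unet_head", children = ch,
             cfg = list(enc = enc_channels, out_channels = out_channels,
                        out_act = out_act))
}

fwd_unet_head <- function(mod, x, keep) {
  stop("a U-Net head runs on backbone taps; apply the full model instead",
       call. = FALSE)
}
bwd_unet_head <- function(mod, cache, dy) fwd_unet_head(mod, NULL, FALSE)

fwd_unet_head_taps <- function(mod, taps, input_dim, keep) {
  ch <- mod$children
  gelu <- layer_gelu()
  cc <- list()
  dims <- lapply(taps, dim)
  u <- upsample_to(taps$t4, dims$t3[1], dims$t3[2])
  x3 <- ccat(u, taps$t3)
  o <- fwd(ch$dec3, x3, keep); cc$dec3 <- o$cache
  a <- fwd(gelu, o$y, keep);   cc$g3 <- a$cache
  u <- upsample_to(a$y, dims$t2[1], dims$t2[2]); d3dim <- dim(a$y)
  x2 <- ccat(u, taps$t2)
  o <- fwd(ch$dec2, x2, keep); cc$dec2 <- o$cache
  a <- fwd(gelu, o$y, keep);   cc$g2 <- a$cache
  u <- upsample_to(a$y, dims$t1[1], dims$t1[2]); d2dim <- dim(a$y)
  x1 <- ccat(u, taps$t1, taps$t0)
  o <- fwd(ch$dec1, x1, keep); cc$dec1 <- o$cache
  a <- fwd(gelu, o$y, keep);   cc$g1 <- a$cache
  u <- upsample_to(a$y, input_dim[1], input_dim[2]); d1dim <- dim(a$y)
  o <- fwd(ch$dec0, u, keep);  cc$dec0 <- o$cache
  a <- fwd(gelu, o$y, keep);   cc$g0 <- a$cache
  o <- fwd(ch$out, a$y, keep); cc$out <- o$cache
  y <- switch(mod$cfg$out_act,
              sigmoid = 1 / (1 + exp(-o$y)),
              softmax = smch_fwd(o$y),
              none = o$y)
  if (keep) {
    cc$y <- y; cc$dims <- dims
    cc$d3dim <- d3dim; cc$d2dim <- d2dim; cc$d1dim <- d1dim
    cc$input_dim <- input_dim
  }
  list(y = y, cache = if (keep) cc)
}

bwd_unet_head_taps <- function(mod, cc, dy) {
  ch <- mod$children
  gelu <- layer_gelu()
  dact <- switch(mod$cfg$out_act,
                 sigmoid = dy * cc$y * (1 - cc$y),
                 softmax = smch_bwd(cc$y, dy),
                 none = dy)
  g <- list()
  o <- bwd(ch$out, cc$out, dact);  g$out <- o$grads
  a <- bwd(gelu, cc$g0, o$dx)
  o <- bwd(ch$dec0, cc$dec0, a$dx); g$dec0 <- o$grads
  du <- downsample_grad(o$dx, cc$d1dim[1], cc$d1dim[2])
  a <- bwd(gelu, cc$g1, du)
  o <- bwd(ch$dec1, cc$dec1, a$dx); g$dec1 <- o$grads
  sp <- csplit(o$dx, c(cc$d2dim[3], cc$dims$t1[3], cc$dims$t0[3]))
  dt1 <- sp[[2]]; dt0 <- sp[[3]]
  du <- downsample_grad(sp[[1]], cc$d2dim[1], cc$d2dim[2])
  a <- bwd(gelu, cc$g2, du)
  o <- bwd(ch$dec2, cc$dec2, a$dx); g$dec2 <- o$grads
  sp <- csplit(o$dx, c(cc$d3dim[3], cc$dims$t2[3]))
  dt2 <- sp[[2]]
  du <- downsample_grad(sp[[1]], cc$d3dim[1], cc$d3dim[2])
  a <- bwd(gelu, cc$g3, du)
  o <- bwd(ch$dec3, cc$dec3, a$dx); g$dec3 <- o$grads
  sp <- csplit(o$dx, c(cc$dims$t4[3], cc$dims$t3[3]))
  dt3 <- sp[[2]]
  dt4 <- downsample_grad(sp[[1]], cc$dims$t4[1], cc$dims$t4[2])
  list(dtaps = list(t0 = dt0, t1 = dt1, t2 = dt2, t3 = dt3, t4 = dt4),
       grads = list(children = g[names(mod$children)]))
}

# swap the output activation for the identity so training can seed the
# backward pass with analytic logit gradients (numerically stable at
# saturation); restore_output_activation() undoes it.
strip_output_activation <- function(model) {
  h <- model$children$head
  if (h$kind == "unet_head") {
    model$children$head$cfg$stripped_act <- h$cfg$out_act
    model$children$head$cfg$out_act <- "none"
  } else if (h$kind == "seq" && h$children[[length(h$children)]]$kind
             %in% c("softmax", "sigmoid")) {
    model$children$head$cfg$stripped_act <-
      h$children[[length(h$children)]]$kind
    model$children$head$children[[length(h$children)]] <-
      new_module("identity")
  }
  model
}

restore_output_activation <- function(model) {
  h <- model$children$head
  act <- h$cfg$stripped_act
  if (is.null(act)) return(model)
  if (h$kind == "unet_head") {
    model$children$head$cfg$out_act <- act
  } else {
    model$children$head$children[[length(h$children)]] <- new_module(act)
  }
  model$children$head$cfg$stripped_act <- NULL
  model
}

#' Replace the task head of a pretrained student
#'
#' Carries the backbone weights over unchanged (bit-identical) and attaches a
#' freshly initialised task head: global pool + linear + softmax for
#' classification, or a U-Net style decoder with per-pixel softmax for
#' segmentation.
#'
#' @param pretrained_student a model with a \code{backbone} child (e.g. the
#'   result of [pretrain()]) or a bare backbone from
#'   \code{build_csat(head = "none")}.
#' @param task \code{"classification"} or \code{"segmentation"}.
#' @param classes number of target classes T (>= 2).
#' @return a model for the target task.
#' @export
replace_head <- function(pretrained_student,
                         task = c("classification", "segmentation"),
                         classes) {
  task <- match.arg(task)
  if (classes < 2L) stop("a task head needs at least 2 classes", call. = FALSE)
  backbone <- if (pretrained_student$kind == "backbone_with_head")
    pretrained_student$children$backbone else pretrained_student
  if (backbone$kind != "csat_backbone")
    stop("expected a CSAT backbone", call. = FALSE)
  config <- backbone$cfg$config
  ch <- config$stage_channels
  hm <- switch(task,
    classification = nn_seq(
      gap = layer_gap(), flat = new_module("flatten"),
      fc = layer_linear(ch[4], as.integer(classes), sd = 0.02),
      sm = new_module("softmax")),
    segmentation = new_unet_head(c(config$stem_channels, ch),
                                 out_channels = as.integer(classes),
                                 out_act = "softmax"))
  hm$cfg$tag <- "head"
  new_module("backbone_with_head",
             children = list(backbone = backbone, head = hm),
             cfg = list(head = task))
}
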