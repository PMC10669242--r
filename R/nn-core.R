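#' @useDynLib rckd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames pnorm dnorm
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode layer library.
#
# Tensors are R arrays with dim c(H, W, C, N): height, width, channels, batch
# (conceptually batch x channels x height x width; column-major R storage puts
# H fastest).  A module is a list with fields:
#   kind     - character, dispatched on in nn_forward()/nn_backward()
#   params   - named list of numeric arrays (trainable)
#   cfg      - named list of hyperparameters (kernel sizes, strides, tags...)
#   children - named list of sub-modules
# nn_forward() returns list(y, cache); nn_backward() consumes the cache and
# the upstream gradient and returns list(dx, grads) where grads mirrors the
# params/children structure, so optimisers can walk the two trees in lockstep.
# ---------------------------------------------------------------------------

new_module <- function(kind, params = list(), cfg = list(), children = list()) {
  structure(list(kind = kind, params = params, cfg = cfg, children = children),
            class = "rckd_module")
}

as_tensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("input must have rank <= 4", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# He-style fan-in init for conv/linear weights
init_w <- function(dims, fan_in, gain = 2) {
  array(rnorm(prod(dims), sd = sqrt(gain / fan_in)), dim = dims)
}

# ----- primitive constructors ----------------------------------------------

layer_conv2d <- function(cin, cout, k, stride = 1L, pad = NULL, bias = TRUE,
                         tag = NULL, pad_edge = FALSE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  params <- list(w = init_w(c(k, k, cin, cout), fan_in = k * k * cin))
  if (bias) params$b <- numeric(cout)
  new_module("conv2d", params,
             cfg = list(k = k, stride = stride, pad = pad, cin = cin,
                        cout = cout, tag = tag, edge = as.integer(pad_edge)))
}

layer_dwconv <- function(ch, k, stride = 1L, pad = NULL, bias = TRUE,
                         tag = NULL, pad_edge = FALSE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  params <- list(w = init_w(c(k, k, ch), fan_in = k * k))
  if (bias) params$b <- numeric(ch)
  new_module("dwconv", params,
             cfg = list(k = k, stride = stride, pad = pad, ch = ch, tag = tag,
                        edge = as.integer(pad_edge)))
}

layer_linear <- function(din, dout, bias = TRUE, sd = NULL) {
  w <- if (is.null(sd)) init_w(c(din, dout), fan_in = din, gain = 1)
       else array(rnorm(din * dout, sd = sd), dim = c(din, dout))
  params <- list(w = w)
  if (bias) params$b <- numeric(dout)
  new_module("linear", params, cfg = list(din = din, dout = dout))
}

# channel-wise layer norm: normalise over C at each (h, w, n)
layer_layernorm <- function(ch, eps = 1e-6) {
  new_module("layernorm", list(gamma = rep(1, ch), beta = numeric(ch)),
             cfg = list(ch = ch, eps = eps))
}

layer_gelu    <- function() new_module("gelu")
layer_relu    <- function() new_module("relu")
layer_sigmoid <- function() new_module("sigmoid")

layer_batchnorm <- function(ch, eps = 1e-5) {
  new_module("batchnorm", list(gamma = rep(1, ch), beta = numeric(ch)),
             cfg = list(ch = ch, eps = eps,
                        mean = numeric(ch), var = rep(1, ch)))
}

layer_maxpool <- function(k, stride, pad = 0L) {
  new_module("maxpool", cfg = list(k = k, stride = stride, pad = pad))
}

layer_gap <- function() new_module("gap")  # global average pool -> (1,1,C,N)

nn_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && is.null(ch[[1]]$kind))
    ch <- ch[[1]]
  if (is.null(names(ch)) || any(names(ch) == ""))
    names(ch) <- sprintf("l%02d", seq_along(ch))
  new_module("seq", children = ch)
}

# ----- forward / backward ---------------------------------------------------

#' Run a module forward
#'
#' Applies a network module to a feature-map array of dim \code{c(H, W, C, N)}
#' (a single \code{H x W x C} array is promoted to batch size 1).
#'
#' @param mod a module built by the package's constructors
#'   (e.g. [build_csat()], [new_sat_module()]).
#' @param x numeric array, dim \code{c(H, W, C, N)}.
#' @param cache logical; keep intermediate values for a backward pass.
#' @return if \code{cache} is \code{FALSE}, the output array; otherwise a
#'   list with elements \code{y} and \code{cache}.
#' @export
nn_forward <- function(mod, x, cache = FALSE) {
  out <- fwd(mod, as_tensor(x), keep = cache)
  if (cache) out else out$y
}

fwd <- function(mod, x, keep = FALSE) {
  switch(mod$kind,
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        o <- fwd(mod$children[[i]], x, keep)
        x <- o$y
        caches[[i]] <- o$cache
      }
      list(y = x, cache = if (keep) list(children = caches))
    },
    conv2d     = fwd_conv2d(mod, x, keep),
    dwconv     = fwd_dwconv(mod, x, keep),
    linear     = fwd_linear(mod, x, keep),
    layernorm  = fwd_layernorm(mod, x, keep),
    batchnorm  = fwd_batchnorm(mod, x, keep),
    gelu       = fwd_gelu(mod, x, keep),
    relu       = list(y = pmax(x, 0), cache = if (keep) list(mask = x > 0)),
    sigmoid    = { y <- 1 / (1 + exp(-x)); list(y = y, cache = if (keep) list(y = y)) },
    maxpool    = {
      d <- dim(x)
      y <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4],
                           mod$cfg$k, mod$cfg$stride, mod$cfg$pad)
      list(y = y, cache = NULL)
    },
    gap        = fwd_gap(mod, x, keep),
    identity   = list(y = x, cache = NULL),
    flatten    = {
      d <- dim(x)
      list(y = t(matrix(x, d[3], d[4])), cache = if (keep) list(d = d))
    },
    softmax    = {
      z <- exp(x - apply(x, 1, max))
      y <- z / rowSums(z)
      list(y = y, cache = if (keep) list(y = y))
    },
    grn        = fwd_grn(mod, x, keep),
    mhsa       = fwd_mhsa(mod, x, keep),
    sat_module = fwd_sat_module(mod, x, keep),
    sat_block  = fwd_sat_block(mod, x, keep),
    transformer_block = fwd_transformer_block(mod, x, keep),
    resblock   = fwd_resblock(mod, x, keep),
    unet_head  = fwd_unet_head(mod, x, keep),
    csat_backbone = fwd_csat_backbone(mod, x, keep),
    backbone_with_head = fwd_backbone_with_head(mod, x, keep),
    stop("unknown module kind: ", mod$kind)
  )
}

nn_backward <- function(mod, cache, dy) bwd(mod, cache, dy)

bwd <- function(mod, cache, dy) {
  switch(mod$kind,
    seq = {
      n <- length(mod$children)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        o <- bwd(mod$children[[i]], cache$children[[i]], dy)
        dy <- o$dx
        grads[i] <- list(o$grads)   # keep NULL grads without shrinking
      }
      names(grads) <- names(mod$children)
      list(dx = dy, grads = list(children = grads))
    },
    conv2d     = bwd_conv2d(mod, cache, dy),
    dwconv     = bwd_dwconv(mod, cache, dy),
    linear     = bwd_linear(mod, cache, dy),
    layernorm  = bwd_layernorm(mod, cache, dy),
    gelu       = bwd_gelu(mod, cache, dy),
    relu       = list(dx = dy * cache$mask, grads = NULL),
    sigmoid    = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
    gap        = bwd_gap(mod, cache, dy),
    identity   = list(dx = dy, grads = NULL),
    flatten    = list(dx = array(t(dy), cache$d), grads = NULL),
    softmax    = {
      y <- cache$y
      list(dx = y * (dy - rowSums(dy * y)), grads = NULL)
    },
    grn        = bwd_grn(mod, cache, dy),
    mhsa       = bwd_mhsa(mod, cache, dy),
    sat_module = bwd_sat_module(mod, cache, dy),
    sat_block  = bwd_sat_block(mod, cache, dy),
    transformer_block = bwd_transformer_block(mod, cache, dy),
    unet_head  = bwd_unet_head(mod, cache, dy),
    csat_backbone = backbone_bwd_taps(mod, cache, list(t4 = dy)),
    backbone_with_head = bwd_backbone_with_head(mod, cache, dy),
    stop("backward not implemented for kind: ", mod$kind)
  )
}

# ----- conv2d ---------------------------------------------------------------

fwd_conv2d <- function(mod, x, keep) {
  d <- dim(x); cfg <- mod$cfg
  if (d[3] != cfg$cin)
    stop(sprintf("conv2d: expected %d input channels, got %d", cfg$cin, d[3]),
         call. = FALSE)
  k <- cfg$k; s <- cfg$stride; p <- cfg$pad
  ho <- (d[1] + 2 * p - k) %/% s + 1L
  wo <- (d[2] + 2 * p - k) %/% s + 1L
  wmat <- matrix(mod$params$w, k * k * cfg$cin, cfg$cout)
  if (k == 1L && s == 1L && p == 0L) {
    x2 <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], cfg$cin)
    y2 <- x2 %*% wmat
    cols <- NULL
  } else {
    cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, k, s, s, p, p,
                       cfg$edge)
    y2 <- crossprod(cols, wmat)
    x2 <- NULL
  }
  if (!is.null(mod$params$b)) y2 <- sweep(y2, 2, mod$params$b, "+")
  y <- aperm(array(y2, c(ho, wo, d[4], cfg$cout)), c(1, 2, 4, 3))
  list(y = y, cache = if (keep) list(cols = cols, x2 = x2, din = d))
}

bwd_conv2d <- function(mod, cache, dy) {
  cfg <- mod$cfg; d <- cache$din
  ddy <- dim(dy)
  dy2 <- matrix(aperm(dy, c(1, 2, 4, 3)), ddy[1] * ddy[2] * ddy[4], cfg$cout)
  wmat <- matrix(mod$params$w, cfg$k^2 * cfg$cin, cfg$cout)
  if (!is.null(cache$x2)) {                      # 1x1 fast path
    dw <- crossprod(cache$x2, dy2)
    dx2 <- dy2 %*% t(wmat)
    dx <- aperm(array(dx2, c(d[1], d[2], d[4], cfg$cin)), c(1, 2, 4, 3))
  } else {
    dw <- cache$cols %*% dy2
    dcols <- wmat %*% t(dy2)
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4],
                     cfg$k, cfg$k, cfg$stride, cfg$stride, cfg$pad, cfg$pad,
                     cfg$edge)
  }
  g <- list(w = array(dw, dim(mod$params$w)))
  if (!is.null(mod$params$b)) g$b <- colSums(dy2)
  list(dx = dx, grads = list(params = g))
}

# ----- depthwise conv -------------------------------------------------------

fwd_dwconv <- function(mod, x, keep) {
  d <- dim(x); cfg <- mod$cfg
  if (d[3] != cfg$ch)
    stop(sprintf("dwconv: expected %d channels, got %d", cfg$ch, d[3]),
         call. = FALSE)
  b <- if (is.null(mod$params$b)) numeric(0) else mod$params$b
  y <- dwconv_fwd_cpp(x, d[1], d[2], d[3], d[4], mod$params$w,
                      cfg$k, cfg$k, cfg$stride, cfg$stride, cfg$pad, cfg$pad,
                      b, cfg$edge)
  list(y = y, cache = if (keep) list(x = x, din = d))
}

bwd_dwconv <- function(mod, cache, dy) {
  cfg <- mod$cfg; d <- cache$din
  o <- dwconv_bwd_cpp(cache$x, d[1], d[2], d[3], d[4], mod$params$w,
                      cfg$k, cfg$k, cfg$stride, cfg$stride, cfg$pad, cfg$pad,
                      dy, !is.null(mod$params$b), cfg$edge)
  g <- list(w = o$dw)
  if (!is.null(mod$params$b)) g$b <- as.numeric(o$db)
  list(dx = o$dx, grads = list(params = g))
}

# ----- linear (input: matrix rows x features, or rank-4 treated as tokens) --

fwd_linear <- function(mod, x, keep) {
  y <- x %*% mod$params$w
  if (!is.null(mod$params$b)) y <- sweep(y, 2, mod$params$b, "+")
  list(y = y, cache = if (keep) list(x = x))
}

bwd_linear <- function(mod, cache, dy) {
  g <- list(w = crossprod(cache$x, dy))
  if (!is.null(mod$params$b)) g$b <- colSums(dy)
  list(dx = dy %*% t(mod$params$w), grads = list(params = g))
}

# ----- channelwise layer norm ----------------------------------------------

fwd_layernorm <- function(mod, x, keep) {
  d <- dim(x); C <- d[3]; eps <- mod$cfg$eps
  xm <- matrix(aperm(x, c(3, 1, 2, 4)), C)     # C x (HWN)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, inv, "*")
  ym <- xn * mod$params$gamma + mod$params$beta
  y <- aperm(array(ym, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(y = y, cache = if (keep) list(xn = xn, inv = inv, d = d))
}

bwd_layernorm <- function(mod, cache, dy) {
  d <- cache$d; C <- d[3]
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), C)
  g <- list(gamma = rowSums(dym * cache$xn), beta = rowSums(dym))
  dxn <- dym * mod$params$gamma
  # standard layernorm backward over the C axis (columns are positions)
  t1 <- colMeans(dxn)
  t2 <- colMeans(dxn * cache$xn)
  dxm <- sweep(dxn, 2, t1) - sweep(cache$xn, 2, t2, "*")
  dxm <- sweep(dxm, 2, cache$inv, "*")
  dx <- aperm(array(dxm, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(dx = dx, grads = list(params = g))
}

# ----- batch norm (inference-style; reference net only) ---------------------

fwd_batchnorm <- function(mod, x, keep) {
  cfg <- mod$cfg
  scale <- mod$params$gamma / sqrt(cfg$var + cfg$eps)
  shift <- mod$params$beta - cfg$mean * scale
  d <- dim(x)
  y <- sweep(sweep(x, 3, scale, "*"), 3, shift, "+")
  list(y = y, cache = NULL)
}

# ----- activations ----------------------------------------------------------

fwd_gelu <- function(mod, x, keep) {
  Phi <- pnorm(x)
  list(y = x * Phi, cache = if (keep) list(x = x, Phi = Phi))
}

bwd_gelu <- function(mod, cache, dy) {
  x <- cache$x
  list(dx = dy * (cache$Phi + x * dnorm(x)), grads = NULL)
}

# ----- global average pool --------------------------------------------------

fwd_gap <- function(mod, x, keep) {
  d <- dim(x)
  y <- apply(x, c(3, 4), mean)                 # C x N
  dim(y) <- c(1, 1, d[3], d[4])
  list(y = y, cache = if (keep) list(d = d))
}

bwd_gap <- function(mod, cache, dy) {
  d <- cache$d
  g <- array(rep(as.numeric(dy) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  list(dx = g, grads = NULL)
}

# ----- parameter-tree utilities ---------------------------------------------

#' Count trainable parameters of a model
#'
#' Sums the lengths of every trainable array in the module tree; running
#' statistics of normalisation layers are not trainable and are not counted.
#'
#' @param model a module (e.g. from [build_csat()] or [build_resnet18()]).
#' @return integer-valued scalar count of trainable scalars.
#' @examples
#' set.seed(1)
#' fc <- layer_linear(10, 5)
#' count_parameters(fc)  # 10 * 5 + 5 = 55
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(model$params, length, numeric(1)))
  if (length(model$children))
    n <- n + sum(vapply(model$children, count_parameters, numeric(1)))
  n
}

# apply f(param, grad, state, tag) -> list(param, state) over the tree
step_tree <- function(mod, grads, state, f, tag = NULL) {
  tg <- if (!is.null(mod$cfg$tag)) mod$cfg$tag else tag
  if (length(mod$params)) {
    if (is.null(state$params)) state$params <- list()
    for (nm in names(mod$params)) {
      r <- f(mod$params[[nm]], grads$params[[nm]], state$params[[nm]], tg)
      mod$params[[nm]] <- r$param
      state$params[nm] <- list(r$state)
    }
  }
  if (length(mod$children)) {
    if (is.null(state$children)) state$children <- vector("list", length(mod$children))
    for (i in seq_along(mod$children)) {
      r <- step_tree(mod$children[[i]], grads$children[[i]],
                     state$children[[i]], f, tg)
      mod$children[[i]] <- r$mod
      state$children[i] <- list(r$state)
    }
  }
  list(mod = mod, state = state)
}

# elementwise sum of two gradient trees (for batch accumulation)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

grad_global_norm <- function(g) {
  s <- 0
  rec <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) { lapply(x, rec); return(invisible(NULL)) }
    s <<- s + sum(x^2)
    invisible(NULL)
  }
  rec(g)
  sqrt(s)
}

sanitize_grads <- function(g) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, sanitize_grads))
  g[!is.finite(g)] <- 0
  g
}

clip_grads <- function(g, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(g)
  n <- grad_global_norm(g)
  if (!is.finite(n)) {       # zero out overflowed entries, then re-measure
    g <- sanitize_grads(g)
    n <- grad_global_norm(g)
  }
  if (n > max_norm) scale_grads(g, max_norm / n) else g
}

scale_grads <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  g * s
}

# flatten all parameters into one numeric vector (checksums, transfer checks)
flatten_params <- function(mod) {
  out <- unlist(lapply(mod$params, as.numeric), use.names = FALSE)
  if (length(mod$children))
    out <- c(out, unlist(lapply(mod$children, flatten_params), use.names = FALSE))
  out
}

#' Stochastic gradient descent with momentum
#'
#' @param model,grads,state module tree, matching gradient tree, optimiser
#'   state (pass \code{list()} initially).
#' @param lr,momentum,weight_decay scalars.
#' @param freeze_tags character vector of module tags whose parameters are
#'   not updated (e.g. \code{"peg"} to freeze positional encodings).
#' @param lr_scale_tags named numeric vector of per-tag learning-rate
#'   multipliers (e.g. \code{c(head = 50)} to train a fresh head faster
#'   than the pretrained backbone).
#' @return list with updated \code{model} and \code{state}.
#' @export
sgd_step <- function(model, grads, state, lr, momentum = 0.9,
                     weight_decay = 0, freeze_tags = character(),
                     lr_scale_tags = NULL) {
  f <- function(p, g, st, tag) {
    if (!is.null(tag) && tag %in% freeze_tags) return(list(param = p, state = st))
    lri <- lr
    if (!is.null(tag) && !is.null(lr_scale_tags) && tag %in% names(lr_scale_tags))
      lri <- lr * lr_scale_tags[[tag]]
    if (weight_decay > 0) g <- g + weight_decay * p
    v <- if (is.null(st)) g else momentum * st + g
    list(param = p - lri * v, state = v)
  }
  step_tree(model, grads, state, f)
}

#' One LARS update for a single parameter block
#'
#' Layer-wise adaptive rate scaling: the local learning rate of a block is
#' \code{trust * ||p|| / (||g|| + wd * ||p|| + eps)} (1 when \code{||p||} is
#' zero), and the update applies momentum to the weight-decayed gradient.
#'
#' @param param_block,grad_block numeric arrays of identical shape.
#' @param global_lr learning rate from the warmup/decay schedule.
#' @param trust_coefficient LARS trust coefficient (eta).
#' @param weight_decay L2 coefficient.
#' @param momentum momentum coefficient.
#' @param velocity previous momentum buffer (NULL initially).
#' @param eps numerical floor in the trust-ratio denominator.
#' @return list(param, velocity, local_lr).
#' @export
lars_step <- function(param_block, grad_block, global_lr,
                      trust_coefficient = 0.001, weight_decay = 0,
                      momentum = 0.9, velocity = NULL, eps = 1e-9) {
  pn <- sqrt(sum(param_block^2))
  gn <- sqrt(sum(grad_block^2))
  local_lr <- if (pn == 0) 1 else trust_coefficient * pn /
    (gn + weight_decay * pn + eps)
  g <- grad_block + weight_decay * param_block
  v <- if (is.null(velocity)) global_lr * local_lr * g
       else momentum * velocity + global_lr * local_lr * g
  list(param = param_block - v, velocity = v, local_lr = local_lr)
}

lars_tree_step <- function(model, grads, state, global_lr,
                           trust_coefficient = 0.001, weight_decay = 1e-4,
                           momentum = 0.9, freeze_tags = character()) {
  f <- function(p, g, st, tag) {
    if (!is.null(tag) && tag %in% freeze_tags) return(list(param = p, state = st))
    r <- lars_step(p, g, global_lr, trust_coefficient, weight_decay,
                   momentum, st)
    list(param = r$param, state = r$velocity)
  }
  step_tree(model, grads, state, f)
}
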