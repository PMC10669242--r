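# ---------------------------------------------------------------------------
# Global response normalisation, multi-head self-attention, and the SAT
# (spatial attention by transformer) module and block.
# ---------------------------------------------------------------------------

layer_grn <- function(ch, eps = 1e-6) {
  # gamma = beta = 0 makes the layer the identity at initialisation
  new_module("grn", list(gamma = numeric(ch), beta = numeric(ch)),
             cfg = list(ch = ch, eps = eps))
}

fwd_grn <- function(mod, x, keep) {
  d <- dim(x); C <- d[3]; N <- d[4]; eps <- mod$cfg$eps
  if (C != mod$cfg$ch)
    stop(sprintf("grn: expected %d channels, got %d", mod$cfg$ch, C),
         call. = FALSE)
  xm <- matrix(x, d[1] * d[2], C * N)
  gx <- matrix(sqrt(colSums(xm^2)), C, N)        # per-channel spatial L2 norm
  mx <- colMeans(gx)                             # mean norm across channels
  nx <- sweep(gx, 2, mx + eps, "/")              # competition ratio
  nxf <- rep(as.numeric(nx), each = d[1] * d[2])
  s <- x * nxf
  y <- sweep(s, 3, mod$params$gamma, "*")
  y <- sweep(y, 3, mod$params$beta, "+") + x
  list(y = y, cache = if (keep) list(x = x, gx = gx, mx = mx, nx = nx, d = d))
}

bwd_grn <- function(mod, cache, dy) {
  d <- cache$d; C <- d[3]; N <- d[4]; hw <- d[1] * d[2]
  eps <- mod$cfg$eps
  x <- cache$x; nx <- cache$nx; gx <- cache$gx
  nxf <- rep(as.numeric(nx), each = hw)
  s <- x * nxf
  g <- list(gamma = as.numeric(apply(dy * s, 3, sum)),
            beta  = as.numeric(apply(dy, 3, sum)))
  ds <- sweep(dy, 3, mod$params$gamma, "*")
  dx <- dy + ds * nxf                            # residual + direct path
  # dnx[c,n] = sum_hw ds * x
  dnx <- matrix(colSums(matrix(ds * x, hw, C * N)), C, N)
  inv <- 1 / (cache$mx + eps)
  # nx_c = gx_c * inv(n); mx = mean_c gx
  dgx <- sweep(dnx, 2, inv, "*") -
         sweep(matrix(rep(colSums(dnx * gx), each = C), C, N), 2,
               inv^2 / C, "*")
  # dgx/dx = x / gx (0 where the norm vanishes)
  safe <- ifelse(gx > 0, dgx / gx, 0)
  dx <- dx + x * rep(as.numeric(safe), each = hw)
  list(dx = dx, grads = list(params = g))
}

#' Global response normalisation
#'
#' Channel-competition normalisation: each channel's global spatial L2 norm is
#' divided by the mean norm across channels, the input is scaled by that ratio
#' times \code{gamma}, shifted by \code{beta}, and added residually to the
#' input. With \code{gamma = beta = 0} the operation is the identity.
#'
#' @param x feature map, dim \code{c(H, W, C, N)} (or \code{c(H, W, C)}).
#' @param gamma,beta per-channel scale and shift (length C).
#' @param eps numerical floor in the denominator.
#' @return array of the same shape as \code{x}.
#' @export
grn <- function(x, gamma, beta, eps = 1e-6) {
  x <- as_tensor(x)
  C <- dim(x)[3]
  if (length(gamma) != C || length(beta) != C)
    stop(sprintf("gamma/beta must have one entry per channel (%d)", C),
         call. = FALSE)
  mod <- layer_grn(C, eps)
  mod$params$gamma <- as.numeric(gamma)
  mod$params$beta <- as.numeric(beta)
  fwd_grn(mod, x, keep = FALSE)$y
}

# ----- multi-head self-attention over flattened spatial tokens --------------

layer_mhsa <- function(dm, heads = 4L, qkv_bias = FALSE) {
  if (dm %% heads != 0L) stop("model dim must be divisible by heads", call. = FALSE)
  params <- list(wqkv = init_w(c(dm, 3L * dm), fan_in = dm, gain = 1),
                 wo = init_w(c(dm, dm), fan_in = dm, gain = 1),
                 bo = numeric(dm))
  if (qkv_bias) params$bqkv <- numeric(3L * dm)
  new_module("mhsa", params, cfg = list(dm = dm, heads = heads))
}

fwd_mhsa <- function(mod, x, keep) {
  d <- dim(x); C <- d[3]; N <- d[4]; T <- d[1] * d[2]
  hd <- mod$cfg$heads; dh <- C %/% hd; sc <- 1 / sqrt(dh)
  y <- array(0, d)
  cc <- if (keep) vector("list", N)
  for (n in seq_len(N)) {
    X <- matrix(x[, , , n], T, C)                # tokens x dim
    QKV <- X %*% mod$params$wqkv
    if (!is.null(mod$params$bqkv)) QKV <- sweep(QKV, 2, mod$params$bqkv, "+")
    O <- matrix(0, T, C)
    As <- vector("list", hd)
    for (h in seq_len(hd)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      Q <- QKV[, ix, drop = FALSE]
      K <- QKV[, C + ix, drop = FALSE]
      V <- QKV[, 2 * C + ix, drop = FALSE]
      S <- tcrossprod(Q, K) * sc
      S <- exp(S - apply(S, 1, max))
      A <- S / rowSums(S)
      O[, ix] <- A %*% V
      if (keep) As[[h]] <- A
    }
    Y <- sweep(O %*% mod$params$wo, 2, mod$params$bo, "+")
    y[, , , n] <- array(Y, c(d[1], d[2], C))
    if (keep) cc[[n]] <- list(X = X, QKV = QKV, O = O, As = As)
  }
  list(y = y, cache = if (keep) list(per = cc, d = d))
}

bwd_mhsa <- function(mod, cache, dy) {
  d <- cache$d; C <- d[3]; N <- d[4]; T <- d[1] * d[2]
  hd <- mod$cfg$heads; dh <- C %/% hd; sc <- 1 / sqrt(dh)
  dx <- array(0, d)
  gwqkv <- array(0, dim(mod$params$wqkv))
  gwo <- array(0, dim(mod$params$wo)); gbo <- numeric(C)
  gbqkv <- if (!is.null(mod$params$bqkv)) numeric(3 * C)
  for (n in seq_len(N)) {
    cc <- cache$per[[n]]
    dY <- matrix(dy[, , , n], T, C)
    gbo <- gbo + colSums(dY)
    gwo <- gwo + crossprod(cc$O, dY)
    dO <- dY %*% t(mod$params$wo)
    dQKV <- matrix(0, T, 3 * C)
    for (h in seq_len(hd)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      Q <- cc$QKV[, ix, drop = FALSE]
      K <- cc$QKV[, C + ix, drop = FALSE]
      V <- cc$QKV[, 2 * C + ix, drop = FALSE]
      A <- cc$As[[h]]
      dOh <- dO[, ix, drop = FALSE]
      dA <- tcrossprod(dOh, V)
      dV <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ <- dS %*% K * sc
      dK <- crossprod(dS, Q) * sc
      dQKV[, ix] <- dQ; dQKV[, C + ix] <- dK; dQKV[, 2 * C + ix] <- dV
    }
    if (!is.null(gbqkv)) gbqkv <- gbqkv + colSums(dQKV)
    gwqkv <- gwqkv + crossprod(cc$X, dQKV)
    dX <- dQKV %*% t(mod$params$wqkv)
    dx[, , , n] <- array(dX, c(d[1], d[2], C))
  }
  g <- list(wqkv = gwqkv, wo = gwo, bo = gbo)
  if (!is.null(gbqkv)) g$bqkv <- gbqkv
  list(dx = dx, grads = list(params = g))
}

# ----- adaptive average pooling (PyTorch bin convention) --------------------

adaptive_bins <- function(n_in, n_out) {
  lapply(seq_len(n_out), function(i) {
    s <- floor((i - 1) * n_in / n_out)
    e <- ceiling(i * n_in / n_out)
    (s + 1L):e
  })
}

aap_fwd <- function(x, p) {
  d <- dim(x)
  hb <- adaptive_bins(d[1], p); wb <- adaptive_bins(d[2], p)
  y <- array(0, c(p, p, d[3], d[4]))
  for (i in seq_len(p)) for (j in seq_len(p))
    y[i, j, , ] <- apply(x[hb[[i]], wb[[j]], , , drop = FALSE], c(3, 4), mean)
  list(y = y, hb = hb, wb = wb, din = d)
}

aap_bwd <- function(dy, cc) {
  d <- cc$din
  dx <- array(0, d)
  p <- dim(dy)[1]
  for (i in seq_len(p)) for (j in seq_len(p)) {
    nb <- length(cc$hb[[i]]) * length(cc$wb[[j]])
    g <- dy[i, j, , ] / nb
    dx[cc$hb[[i]], cc$wb[[j]], , ] <-
      dx[cc$hb[[i]], cc$wb[[j]], , , drop = FALSE] +
      aperm(array(g, c(d[3], d[4], length(cc$hb[[i]]), length(cc$wb[[j]]))),
            c(3, 4, 1, 2))
  }
  dx
}

# ----- SAT module -----------------------------------------------------------

#' Construct a SAT (spatial attention by transformer) module
#'
#' The module computes a spatial attention map from the global context at a
#' reduced resolution: channel-wise average and max pooling give a 2-channel
#' summary; adaptive average pooling reduces it to a \code{pooled x pooled}
#' grid; a 7x7 convolution abstracts it to one channel; a convolutional
#' positional encoding (PEG, depthwise 3x3) is added; single-head
#' self-attention over the grid tokens (query/key dimension \code{qk_dim},
#' scalar value) yields the attention map, which is bilinearly upsampled to
#' the input resolution and multiplied into the feature map.
#'
#' @param pooled side length of the reduced attention grid (h' = w').
#' @param qk_dim query/key dimension of the token self-attention.
#' @param attn_sigmoid apply a sigmoid to the upsampled map (off by default;
#'   the multiplicative map is used as computed).
#' @return a module; apply it with [nn_forward()].
#' @export
new_sat_module <- function(pooled = 7L, qk_dim = 5L, attn_sigmoid = FALSE) {
  # edge (replicate) padding on the small token grid keeps a constant
  # descriptor constant, so constant feature maps get constant attention
  ch <- list(
    conv7 = layer_conv2d(2L, 1L, 7L, bias = FALSE, pad_edge = TRUE),
    peg   = layer_dwconv(1L, 3L, bias = FALSE, tag = "peg", pad_edge = TRUE),
    qkv   = layer_linear(1L, 2L * qk_dim + 1L, bias = TRUE)
  )
  new_module("sat_module", children = ch,
             cfg = list(pooled = as.integer(pooled), d = as.integer(qk_dim),
                        attn_sigmoid = isTRUE(attn_sigmoid)))
}

fwd_sat_module <- function(mod, x, keep) {
  d <- dim(x); C <- d[3]; N <- d[4]; p <- mod$cfg$pooled
  hw <- d[1] * d[2]
  # channel-wise average and max pooling -> (H, W, 2, N)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), hw * N, C)
  avg <- rowMeans(xm)
  idx <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(nrow(xm)), idx)]
  z <- array(0, c(d[1], d[2], 2L, N))
  z[, , 1L, ] <- array(avg, c(d[1], d[2], N))
  z[, , 2L, ] <- array(mx, c(d[1], d[2], N))
  ap <- aap_fwd(z, p)
  o1 <- fwd(mod$children$conv7, ap$y, keep)       # (p, p, 1, N) descriptor
  o2 <- fwd(mod$children$peg, o1$y, keep)
  m <- o1$y + o2$y
  tok <- matrix(as.numeric(m), p * p * N, 1L)
  o3 <- fwd(mod$children$qkv, tok, keep)
  qd <- mod$cfg$d; sc <- 1 / sqrt(qd)
  att <- array(0, c(p, p, 1L, N))
  As <- if (keep) vector("list", N)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * p * p + 1):(n * p * p)
    Q <- o3$y[rows, 1:qd, drop = FALSE]
    K <- o3$y[rows, (qd + 1):(2 * qd), drop = FALSE]
    v <- o3$y[rows, 2 * qd + 1]
    S <- tcrossprod(Q, K) * sc
    S <- exp(S - apply(S, 1, max))
    A <- S / rowSums(S)
    att[, , 1L, n] <- A %*% v
    if (keep) As[[n]] <- A
  }
  up <- bilinear_fwd_cpp(att, p, p, 1L, N, d[1], d[2])
  sig <- NULL
  if (mod$cfg$attn_sigmoid) {
    sig <- 1 / (1 + exp(-up))
    up <- sig
  }
  att3 <- array(up, c(d[1], d[2], N))
  att4 <- aperm(array(att3, c(d[1], d[2], N, C)), c(1, 2, 4, 3))
  y <- x * att4
  list(y = y,
       cache = if (keep) list(x = x, d = d, idx = idx, ap = ap,
                              c1 = o1$cache, c2 = o2$cache, c3 = o3$cache,
                              qkv_out = o3$y, As = As, att = att,
                              att4 = att4, sig = sig))
}

bwd_sat_module <- function(mod, cache, dy) {
  d <- cache$d; C <- d[3]; N <- d[4]; p <- mod$cfg$pooled
  hw <- d[1] * d[2]; qd <- mod$cfg$d; sc <- 1 / sqrt(qd)
  dx <- dy * cache$att4
  datt4 <- dy * cache$x
  # reduce over channels -> (H, W, 1, N)
  datt3 <- colSums(matrix(aperm(datt4, c(3, 1, 2, 4)), C))
  dup <- array(datt3, c(d[1], d[2], 1L, N))
  if (!is.null(cache$sig)) dup <- dup * cache$sig * (1 - cache$sig)
  datt <- bilinear_bwd_cpp(dup, d[1], d[2], 1L, N, p, p)
  dqkv_out <- matrix(0, p * p * N, 2 * qd + 1)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * p * p + 1):(n * p * p)
    Q <- cache$qkv_out[rows, 1:qd, drop = FALSE]
    K <- cache$qkv_out[rows, (qd + 1):(2 * qd), drop = FALSE]
    v <- cache$qkv_out[rows, 2 * qd + 1]
    A <- cache$As[[n]]
    da <- matrix(datt[, , 1L, n], p * p, 1L)
    dA <- tcrossprod(da, matrix(v, ncol = 1))
    dv <- as.numeric(crossprod(A, da))
    dS <- A * (dA - rowSums(dA * A))
    dqkv_out[rows, 1:qd] <- dS %*% K * sc
    dqkv_out[rows, (qd + 1):(2 * qd)] <- crossprod(dS, Q) * sc
    dqkv_out[rows, 2 * qd + 1] <- dv
  }
  o3 <- bwd(mod$children$qkv, cache$c3, dqkv_out)
  dm <- array(o3$dx, c(p, p, 1L, N))
  o2 <- bwd(mod$children$peg, cache$c2, dm)
  dms <- dm + o2$dx
  o1 <- bwd(mod$children$conv7, cache$c1, dms)
  dz <- aap_bwd(o1$dx, cache$ap)
  # channel-pool backward
  davg <- matrix(dz[, , 1L, ], hw * N, 1L)
  dmax <- as.numeric(dz[, , 2L, ])
  dxm <- matrix(rep(davg / C, C), hw * N, C)
  dxm[cbind(seq_len(hw * N), cache$idx)] <-
    dxm[cbind(seq_len(hw * N), cache$idx)] + dmax
  dx <- dx + aperm(array(dxm, c(d[1], d[2], N, C)), c(1, 2, 4, 3))
  list(dx = dx,
       grads = list(children = list(conv7 = o1$grads, peg = o2$grads,
                                    qkv = o3$grads)))
}

# ----- SAT block ------------------------------------------------------------

#' Construct a SAT block
#'
#' \code{y = x + SAT(Conv1x1(GRN(GELU(Conv1x1(DWConv7x7(x))))))}: a depthwise
#' 7x7 convolution, an expanding 1x1 convolution (ratio \code{expansion}),
#' GELU, global response normalisation, a projecting 1x1 convolution, and the
#' SAT module, wrapped in a residual connection.
#'
#' @param ch block width D (input and output channels).
#' @param expansion channel expansion ratio of the first 1x1 convolution.
#' @param pooled,qk_dim SAT-module geometry; see [new_sat_module()].
#' @param with_sat include the SAT module (\code{FALSE} gives the ablation
#'   variant in which the module is the identity).
#' @return a module.
#' @export
new_sat_block <- function(ch, expansion = 4L, pooled = 7L, qk_dim = 5L,
                          with_sat = TRUE) {
  hidden <- as.integer(ch * expansion)
  children <- list(
    dw      = layer_dwconv(ch, 7L, bias = TRUE),
    expand  = layer_conv2d(ch, hidden, 1L, bias = TRUE),
    act     = layer_gelu(),
    grn     = layer_grn(hidden),
    project = layer_conv2d(hidden, ch, 1L, bias = TRUE)
  )
  if (with_sat) children$sat <- new_sat_module(pooled, qk_dim)
  new_module("sat_block", children = children,
             cfg = list(ch = ch, with_sat = with_sat))
}

fwd_sat_block <- function(mod, x, keep) {
  if (dim(x)[3] != mod$cfg$ch)
    stop(sprintf("sat_block: expected %d channels, got %d",
                 mod$cfg$ch, dim(x)[3]), call. = FALSE)
  caches <- list()
  h <- x
  for (nm in names(mod$children)) {
    o <- fwd(mod$children[[nm]], h, keep)
    h <- o$y
    caches[[nm]] <- o$cache
  }
  list(y = x + h, cache = if (keep) caches)
}

bwd_sat_block <- function(mod, cache, dy) {
  grads <- list()
  dh <- dy
  for (nm in rev(names(mod$children))) {
    o <- bwd(mod$children[[nm]], cache[[nm]], dh)
    dh <- o$dx
    grads[[nm]] <- o$grads
  }
  list(dx = dy + dh, grads = list(children = grads[names(mod$children)]))
}

# ----- Transformer block ----------------------------------------------------

#' Construct a pre-norm Transformer encoder block over spatial tokens
#'
#' Flattens the feature map into H*W tokens of dimension C, applies
#' layer norm + multi-head self-attention and layer norm + MLP (hidden ratio
#' \code{mlp_ratio}), each with a residual connection, and reshapes back.
#'
#' @param ch token dimension (stage channels).
#' @param mlp_ratio hidden-width ratio of the feed-forward network.
#' @param heads number of attention heads.
#' @return a module.
#' @export
new_transformer_block <- function(ch, mlp_ratio = 4L, heads = 4L) {
  hidden <- as.integer(ch * mlp_ratio)
  ch_list <- list(
    ln1  = layer_layernorm(ch),
    attn = layer_mhsa(ch, heads = heads, qkv_bias = FALSE),
    ln2  = layer_layernorm(ch),
    fc1  = layer_conv2d(ch, hidden, 1L, bias = TRUE),
    act  = layer_gelu(),
    fc2  = layer_conv2d(hidden, ch, 1L, bias = TRUE)
  )
  new_module("transformer_block", children = ch_list, cfg = list(ch = ch))
}

fwd_transformer_block <- function(mod, x, keep) {
  o1 <- fwd(mod$children$ln1, x, keep)
  o2 <- fwd(mod$children$attn, o1$y, keep)
  x2 <- x + o2$y
  o3 <- fwd(mod$children$ln2, x2, keep)
  o4 <- fwd(mod$children$fc1, o3$y, keep)
  o5 <- fwd(mod$children$act, o4$y, keep)
  o6 <- fwd(mod$children$fc2, o5$y, keep)
  list(y = x2 + o6$y,
       cache = if (keep) list(c1 = o1$cache, c2 = o2$cache, c3 = o3$cache,
                              c4 = o4$cache, c5 = o5$cache, c6 = o6$cache))
}

bwd_transformer_block <- function(mod, cache, dy) {
  o6 <- bwd(mod$children$fc2, cache$c6, dy)
  o5 <- bwd(mod$children$act, cache$c5, o6$dx)
  o4 <- bwd(mod$children$fc1, cache$c4, o5$dx)
  o3 <- bwd(mod$children$ln2, cache$c3, o4$dx)
  dx2 <- dy + o3$dx
  o2 <- bwd(mod$children$attn, cache$c2, dx2)
  o1 <- bwd(mod$children$ln1, cache$c1, o2$dx)
  list(dx = dx2 + o1$dx,
       grads = list(children = list(ln1 = o1$grads, attn = o2$grads,
                                    ln2 = o3$grads, fc1 = o4$grads,
                                    act = NULL, fc2 = o6$grads)))
}
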