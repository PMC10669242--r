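# ---------------------------------------------------------------------------
# Canonical 18-layer residual network (basic blocks, widths 64/128/256/512),
# used as the reference architecture for parameter and MAC accounting.
# ---------------------------------------------------------------------------

new_resblock <- function(cin, cout, stride = 1L, with_sat = FALSE,
                         pooled = 7L, qk_dim = 5L) {
  ch <- list(
    conv1 = layer_conv2d(cin, cout, 3L, stride = stride, pad = 1L, bias = FALSE),
    bn1   = layer_batchnorm(cout),
    conv2 = layer_conv2d(cout, cout, 3L, pad = 1L, bias = FALSE),
    bn2   = layer_batchnorm(cout)
  )
  if (stride != 1L || cin != cout) {
    ch$down_conv <- layer_conv2d(cin, cout, 1L, stride = stride, pad = 0L,
                                 bias = FALSE)
    ch$down_bn <- layer_batchnorm(cout)
  }
  if (with_sat) ch$sat <- new_sat_module(pooled, qk_dim)
  new_module("resblock", children = ch, cfg = list(cin = cin, cout = cout))
}

fwd_resblock <- function(mod, x, keep) {
  ch <- mod$children
  h <- fwd(ch$bn1, fwd(ch$conv1, x, FALSE)$y, FALSE)$y
  h <- pmax(h, 0)
  h <- fwd(ch$bn2, fwd(ch$conv2, h, FALSE)$y, FALSE)$y
  if (!is.null(ch$sat)) h <- fwd(ch$sat, h, FALSE)$y
  idn <- if (!is.null(ch$down_conv))
    fwd(ch$down_bn, fwd(ch$down_conv, x, FALSE)$y, FALSE)$y else x
  list(y = pmax(h + idn, 0), cache = NULL)
}

#' Build the 18-layer residual reference network
#'
#' The canonical ImageNet architecture: a 7x7/stride-2 stem with batch norm
#' and 3x3/stride-2 max pooling, four stages of two basic residual blocks at
#' widths 64/128/256/512, global average pooling and a linear head. With
#' \code{with_sat = TRUE} a SAT module is inserted before the residual
#' addition of every block (one of several possible layouts; parameter
#' counts do not depend on the insertion point).
#'
#' @param num_classes classes of the linear head.
#' @param with_sat insert a SAT module in each residual block.
#' @return a model module (forward pass runs in inference mode).
#' @examples
#' set.seed(1)
#' count_parameters(build_resnet18())  # 11,689,512
#' @export
build_resnet18 <- function(num_classes = 1000L, with_sat = FALSE) {
  widths <- c(64L, 128L, 256L, 512L)
  ch <- list(
    conv1 = layer_conv2d(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
    bn1   = layer_batchnorm(64L),
    relu  = layer_relu(),
    pool  = layer_maxpool(3L, 2L, 1L)
  )
  cin <- 64L
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    ch[[sprintf("layer%d_1", s)]] <- new_resblock(cin, widths[s], stride,
                                                  with_sat = with_sat)
    ch[[sprintf("layer%d_2", s)]] <- new_resblock(widths[s], widths[s], 1L,
                                                  with_sat = with_sat)
    cin <- widths[s]
  }
  ch$gap <- layer_gap()
  ch$flat <- new_module("flatten")
  ch$fc <- layer_linear(512L, as.integer(num_classes), sd = 0.01)
  nn_seq(ch)
}
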