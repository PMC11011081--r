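# Squeeze-excite channel attention (CA layer).
#
# Global average pooling summarizes each channel, two linear maps with a ReLU
# bottleneck (reduction r) produce per-channel gates, a sigmoid squashes them
# into (0, 1), and the input is rescaled channel-wise by the gates.

new_channel_attention <- function(C, reduction = 16L) {
  if (C %% reduction != 0L)
    stopf("channel attention: %d channels not divisible by reduction %d", C, reduction)
  Cr <- C %/% reduction
  new_layer("channel_attention", C = C, reduction = as.integer(reduction),
            params = list(W1 = he_init(Cr, C, C), b1 = numeric(Cr),
                          W2 = he_init(C, Cr, Cr), b2 = numeric(C)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-frame gate vector s in (0,1)^C for input x.
ca_gates <- function(layer, x) {
  z <- gap_forward(x)                                  # (C, N)
  h <- layer$params$W1 %*% z + layer$params$b1
  h <- h * (h > 0)
  s <- sigmoid(layer$params$W2 %*% h + layer$params$b2)
  list(z = z, h = h, s = s)
}

#' @export
layer_forward.channel_attention <- function(layer, x, train = FALSE) {
  d <- tensor_dims(x)
  if (d[1] != layer$C)
    stopf("channel attention built for %d channels, got %d", layer$C, d[1])
  g <- ca_gates(layer, x)
  y <- x * broadcast_cn(g$s, d)
  if (train) layer$cache <- c(g, list(x = x, dims = d))
  y
}

#' @export
layer_backward.channel_attention <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$dims
  HW <- d[2] * d[3]
  dx <- dout * broadcast_cn(cc$s, d)
  ds <- reduce_cn(dout * cc$x)                          # (C, N)
  da2 <- ds * cc$s * (1 - cc$s)
  layer$grads$W2 <- layer$grads$W2 + da2 %*% t(cc$h)
  layer$grads$b2 <- layer$grads$b2 + rowSums(da2)
  dh <- crossprod(layer$params$W2, da2) * (cc$h > 0)
  layer$grads$W1 <- layer$grads$W1 + dh %*% t(cc$z)
  layer$grads$b1 <- layer$grads$b1 + rowSums(dh)
  dz <- crossprod(layer$params$W1, dh)
  dx <- dx + broadcast_cn(dz, d) / HW
  layer$cache <- NULL
  dx
}

#' Apply channel attention to a single feature map
#'
#' Runs squeeze-excite channel gating on one C x H x W array: global average
#' pool, linear C -> C/r, ReLU, linear C/r -> C, sigmoid, and channel-wise
#' multiplication. The sigmoid keeps every gate strictly inside (0, 1), so
#' the output is always attenuated relative to the input.
#'
#' @param x a C x H x W array.
#' @param layer an existing layer, or `NULL` for a fresh seeded one.
#' @param reduction bottleneck reduction ratio r (default 16).
#' @param seed RNG seed for fresh weights.
#' @return list with `out` (C x H x W) and `gates` (length-C vector in (0,1)).
#' @export
channel_attention_map <- function(x, layer = NULL, reduction = 16L, seed = 1L) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[1]
  if (is.null(layer))
    layer <- with_seed(seed, new_channel_attention(C, reduction = reduction))
  x4 <- array(x, c(dim(x), 1L))
  g <- ca_gates(layer, x4)
  y <- layer_forward(layer, x4)
  list(out = array(y, dim(x)), gates = as.numeric(g$s))
}
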