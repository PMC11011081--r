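# Local 3x3 multi-head self-attention.
#
# This layer replaces the 3x3 convolution of the ResNet-50 bottleneck.
# Queries, keys and values come from learned 1x1 projections shared across
# all positions (the "global" attention matrices K1, K2, K3); for every
# output position the attention distribution runs over its 3x3 neighborhood
# (zero-padded at the borders), scored by a scaled dot product plus a learned
# per-head relative-position bias, softmax-normalized, and applied to the
# values. Channels are split into `heads` contiguous blocks.


new_local_attention <- function(C, heads = 4L, window = 3L) {
  if (window %% 2L == 0L) stopf("attention window must be odd, got %d", window)
  if (window != 3L) stopf("only the 3x3 attention window is implemented")
  if (C %% heads != 0L) stopf("%d channels not divisible by %d heads", C, heads)
  new_layer("local_attention", C = C, heads = as.integer(heads),
            dh = C %/% heads, window = 3L,
            params = list(Wq = he_init(C, C, C),
                          Wk = he_init(C, C, C),
                          Wv = he_init(C, C, C),
                          rel = matrix(0, 9, heads)))
}

#' @export
layer_forward.local_attention <- function(layer, x, train = FALSE) {
  d <- tensor_dims(x)
  C <- layer$C; nh <- layer$heads; dh <- layer$dh
  if (d[1] != C) stopf("attention built for %d channels, got %d", C, d[1])
  HW <- d[2] * d[3]; L <- HW * d[4]
  scale <- 1 / sqrt(dh)
  xm <- matrix(x, C, L)
  q <- layer$params$Wq %*% xm
  k <- layer$params$Wk %*% xm
  v <- layer$params$Wv %*% xm
  logits <- attn_logits_cpp(as.double(q), as.double(k), C, d[2], d[3], d[4],
                            dh, scale, layer$params$rel)
  m <- logits[1, ]
  for (j in 2:9) m <- pmax(m, logits[j, ])
  e <- exp(logits - rep(m, each = 9))
  wt <- e / rep(colSums(e), each = 9)                     # attention weights
  out <- attn_apply_cpp(as.double(v), wt, C, d[2], d[3], d[4], dh)
  if (train) layer$cache <- list(xm = xm, q = q, k = k, v = v, wt = wt, dims = d)
  array(out, d)
}

#' @export
layer_backward.local_attention <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$dims
  C <- layer$C; nh <- layer$heads; dh <- layer$dh
  L <- d[2] * d[3] * d[4]
  scale <- 1 / sqrt(dh)
  bw <- attn_dwt_dv_cpp(as.double(cc$v), cc$wt, as.double(dout),
                        C, d[2], d[3], d[4], dh)
  dwt <- bw$dwt
  dot <- colSums(cc$wt * dwt)
  dlog <- cc$wt * (dwt - rep(dot, each = 9))
  layer$grads$rel <- layer$grads$rel +
    rowSums(array(dlog, c(9L, nh, L)), dims = 2)
  qk <- attn_dqk_cpp(as.double(cc$q), as.double(cc$k), dlog,
                     C, d[2], d[3], d[4], dh, scale)
  dqm <- matrix(qk$dq, C, L); dkm <- matrix(qk$dk, C, L); dvm <- matrix(bw$dv, C, L)
  layer$grads$Wq <- layer$grads$Wq + tcrossprod(dqm, cc$xm)
  layer$grads$Wk <- layer$grads$Wk + tcrossprod(dkm, cc$xm)
  layer$grads$Wv <- layer$grads$Wv + tcrossprod(dvm, cc$xm)
  dx <- crossprod(layer$params$Wq, dqm) + crossprod(layer$params$Wk, dkm) +
    crossprod(layer$params$Wv, dvm)
  layer$cache <- NULL
  array(dx, d)
}

#' Local self-attention over a single frame
#'
#' Convenience wrapper applying a local attention layer (optionally followed
#' by stride-2 average pooling) to one C x H x W feature map. Mainly useful
#' for inspecting the layer in isolation; inside the backbone the layer runs
#' on whole frame batches.
#'
#' @param x a C x H x W array.
#' @param layer a layer built by the backbone, or `NULL` to build a fresh
#'   randomly initialized one with `heads` heads (seeded by `seed`).
#' @param stride 1 or 2; stride 2 average-pools the attended map 2x2.
#' @param heads,seed used only when `layer` is NULL.
#' @return a C x H' x W' array (H' = H / stride).
#' @export
local_attention_map <- function(x, layer = NULL, stride = 1L, heads = 4L,
                                seed = 1L) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[1]
  if (is.null(layer))
    layer <- with_seed(seed, new_local_attention(C, heads = heads))
  x4 <- array(x, c(dim(x), 1L))
  y <- layer_forward(layer, x4)
  if (stride == 2L) y <- avgpool2_forward(y)
  array(y, dim(y)[1:3])
}

# Attention weights for one frame, exposed for tests: a (9, heads, H*W)
# array of softmax-normalized neighborhood weights.
attention_weights <- function(layer, x) {
  x4 <- if (length(dim(x)) == 3L) array(x, c(dim(x), 1L)) else x
  layer_forward(layer, x4, train = TRUE)
  wt <- layer$cache$wt
  d <- layer$cache$dims
  layer$cache <- NULL
  array(wt, c(9L, layer$heads, d[2] * d[3] * d[4]))
}
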