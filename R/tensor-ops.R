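# Low-level array operations on (C, H, W, N) tensors.
#
# All feature tensors in the package are column-major R arrays with dimensions
# (channels, height, width, frames). Frames of one clip occupy consecutive
# positions along the fourth dimension, so a batch of B clips of T frames has
# N = B * T with frame t of clip b at index (b - 1) * T + t.

tensor_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stopf("expected a (C, H, W, N) tensor, got dims %s", paste(dim(x), collapse = "x"))
  d
}

# 3x3 stride-2 max pooling with padding 1 (the conv1 subsampling layer).
# Returns the pooled tensor and the winners' input indices for backprop.
maxpool3_forward <- function(x) {
  d <- tensor_dims(x)
  res <- maxpool3_cpp(as.double(x), d[1], d[2], d[3], d[4])
  Ho <- (d[2] - 1L) %/% 2L + 1L
  Wo <- (d[3] - 1L) %/% 2L + 1L
  list(out = array(res$out, c(d[1], Ho, Wo, d[4])), amax = res$amax,
       in_dims = d)
}

maxpool3_backward <- function(dout, cache) {
  array(maxpool3_bwd_cpp(as.double(dout), cache$amax, prod(cache$in_dims)),
        cache$in_dims)
}

# 2x2 stride-2 average pooling (used to realize stride-2 attention stages).
avgpool2_forward <- function(x) {
  d <- tensor_dims(x)
  H <- d[2]; W <- d[3]
  if (H %% 2L || W %% 2L) stopf("avgpool2 needs even spatial dims, got %dx%d", H, W)
  od <- seq.int(1L, H, 2L); ev <- seq.int(2L, H, 2L)
  odw <- seq.int(1L, W, 2L); evw <- seq.int(2L, W, 2L)
  (x[, od, odw, , drop = FALSE] + x[, ev, odw, , drop = FALSE] +
   x[, od, evw, , drop = FALSE] + x[, ev, evw, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dout, in_dims) {
  d <- in_dims
  dx <- array(0, d)
  g <- dout / 4
  od <- seq.int(1L, d[2], 2L); ev <- seq.int(2L, d[2], 2L)
  odw <- seq.int(1L, d[3], 2L); evw <- seq.int(2L, d[3], 2L)
  dx[, od, odw, ] <- g; dx[, ev, odw, ] <- g
  dx[, od, evw, ] <- g; dx[, ev, evw, ] <- g
  dx
}

# Global (adaptive 1x1) average pooling: (C, H, W, N) -> (C, N) matrix.
gap_forward <- function(x) {
  d <- tensor_dims(x)
  HW <- d[2] * d[3]
  xm <- matrix(x, d[1], HW * d[4])
  # columns are ordered (h, w, n); sum HW consecutive columns per frame
  grp <- rep(seq_len(d[4]), each = HW)
  t(rowsum(t(xm), group = grp, reorder = FALSE)) / HW
}

gap_backward <- function(dout, in_dims) {
  d <- in_dims
  HW <- d[2] * d[3]
  array(dout[, rep(seq_len(d[4]), each = HW), drop = FALSE] / HW, d)
}

# Broadcast a (C, N) per-channel-per-frame matrix over spatial positions.
broadcast_cn <- function(s, dims) {
  HW <- dims[2] * dims[3]
  array(s[, rep(seq_len(dims[4]), each = HW), drop = FALSE], dims)
}

# Sum a (C, H, W, N) tensor over spatial positions -> (C, N).
reduce_cn <- function(x) {
  d <- tensor_dims(x)
  HW <- d[2] * d[3]
  xm <- matrix(x, d[1], HW * d[4])
  t(rowsum(t(xm), group = rep(seq_len(d[4]), each = HW), reorder = FALSE))
}
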