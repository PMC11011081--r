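#' Temporal channel shift
#'
#' The temporal relation layer of the network: for each clip of `T` frames,
#' the first `floor(C * fraction)` channels are shifted forward in time (frame
#' t receives frame t-1's content), the next `floor(C * fraction)` channels
#' are shifted backward (frame t receives frame t+1), and all remaining
#' channels pass through unchanged. Vacated boundary slots are zero-filled.
#' The operation has no parameters and exchanges information between adjacent
#' frames at zero cost; setting `reverse = TRUE` applies the adjoint
#' (backward-in-time) shift, which is also the backpropagation rule.
#'
#' @param x a (C, H, W, N) tensor whose frame axis N is grouped into clips of
#'   `frames_per_clip` consecutive frames.
#' @param fraction fraction of channels moved in each direction (default 1/8).
#' @param frames_per_clip number of frames per clip (default 8).
#' @param reverse apply the inverse shift (swap the two directions).
#' @return tensor of the same shape.
#' @export
temporal_shift <- function(x, fraction = 1 / 8, frames_per_clip = 8L,
                           reverse = FALSE) {
  d <- tensor_dims(x)
  C <- d[1]; N <- d[4]; T <- as.integer(frames_per_clip)
  if (T < 1L || N %% T != 0L)
    stopf("frame count %d is not a multiple of frames_per_clip %d", N, T)
  fold <- floor(C * fraction)
  if (fraction > 0 && fold < 1L)
    stopf("shift fraction %.3f moves no channels at C = %d", fraction, C)
  if (fold == 0L) return(x)
  fwd_ch <- seq_len(fold)
  bwd_ch <- fold + seq_len(fold)
  if (max(bwd_ch) > C) stopf("shift fraction %.3f too large for %d channels", fraction, C)
  if (reverse) { tmp <- fwd_ch; fwd_ch <- bwd_ch; bwd_ch <- tmp }
  pos <- (seq_len(N) - 1L) %% T          # position of each frame in its clip
  out <- x
  # forward shift: frame t takes frame t-1; first frame of each clip zeroed
  has_prev <- which(pos > 0L)
  out[fwd_ch, , , has_prev] <- x[fwd_ch, , , has_prev - 1L, drop = FALSE]
  out[fwd_ch, , , which(pos == 0L)] <- 0
  # backward shift: frame t takes frame t+1; last frame of each clip zeroed
  has_next <- which(pos < T - 1L)
  out[bwd_ch, , , has_next] <- x[bwd_ch, , , has_next + 1L, drop = FALSE]
  out[bwd_ch, , , which(pos == T - 1L)] <- 0
  out
}

new_temporal_shift <- function(fraction = 1 / 8, frames_per_clip = 8L) {
  new_layer("tshift", fraction = fraction, T = as.integer(frames_per_clip))
}

#' @export
layer_forward.tshift <- function(layer, x, train = FALSE) {
  temporal_shift(x, layer$fraction, layer$T)
}

#' @export
layer_backward.tshift <- function(layer, dout) {
  # adjoint of a shift is the opposite shift
  temporal_shift(dout, layer$fraction, layer$T, reverse = TRUE)
}
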