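#' Class-activation heat maps for a clip
#'
#' Weights the final-stage feature maps by the predicted class's fully
#' connected weights, rectifies, min-max normalizes over the clip, and
#' upsamples (bilinear) to the network input size — a simple visual check
#' that the attention-equipped backbone concentrates on the animals rather
#' than the enclosure background.
#'
#' Only the consensus head exposes per-class weights on the features, so the
#' GRU head is not supported.
#'
#' @param model a trained [pbatn_model()] with a consensus head.
#' @param clip a [clip()].
#' @param class_id 0-based class to visualize; default the predicted class.
#' @return list with `maps` (list of H x W matrices in `[0, 1]`, one per
#'   sampled frame, H = W = the model input size), `class_id` and
#'   `probabilities`.
#' @export
cam_heatmap <- function(model, clip, class_id = NULL) {
  if (model$head_type != "consensus")
    stopf("heat maps require the consensus head")
  cfg <- sampler_config(model$config$input_frames, "eval",
                        target_size = model$config$input_size)
  x <- clip_to_batch(clip, cfg)
  res <- backbone_forward(model$backbone, x, keep_maps = TRUE)
  logits <- head_forward(model$head, res$features)
  fused <- consensus(t(logits))
  if (is.null(class_id)) class_id <- which.max(fused$fused) - 1L
  wvec <- model$head$fc$params$W[class_id + 1L, ]        # (feature_dim)
  d <- dim(res$maps)                                     # (C, h, w, T)
  cam <- array(as.numeric(wvec %*% matrix(res$maps, d[1])), d[2:4])
  cam <- pmax(cam, 0)
  rng <- range(cam)
  if (diff(rng) > 0) cam <- (cam - rng[1]) / diff(rng)
  tgt <- model$config$input_size
  maps <- lapply(seq_len(d[4]), function(t) {
    m <- matrix(cam[, , t], d[2], d[3])
    if (!all(dim(m) == tgt)) {
      img <- EBImage::resize(EBImage::Image(t(m)), w = tgt, h = tgt)
      m <- t(EBImage::imageData(img))
    }
    pmin(pmax(m, 0), 1)
  })
  list(maps = maps, class_id = class_id, probabilities = fused$probabilities)
}
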