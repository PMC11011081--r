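#' Behavior class names
#'
#' The fixed six-class order used throughout: activity, chasing, mounting,
#' feeding, resting, disturbance. Chasing and mounting are the two breeding
#' behaviors; "disturbance" (a keeper entering the enclosure) is sometimes
#' called "other".
#'
#' @return character vector of length 6.
#' @export
behavior_classes <- function() {
  c("activity", "chasing", "mounting", "feeding", "resting", "disturbance")
}

#' Build the full recognition model
#'
#' Combines a backbone ([build_backbone()]) with a classification head:
#' either the consensus head (dropout + fully connected feature_dim -> K per
#' frame, fused by averaging logits over the clip's frames) or the GRU head
#' variant (recurrent pass over the per-frame features; typically combined
#' with `shift_fraction = 0` in the backbone config).
#'
#' @param config a [backbone_config()].
#' @param head `"consensus"` or `"gru"`.
#' @param class_names character vector of class names (defines K).
#' @param dropout dropout probability before the fully connected layer.
#' @param gru_hidden GRU hidden size (GRU head only).
#' @param seed seed for weight initialization.
#' @return an object of class `pbatn_model`.
#' @export
pbatn_model <- function(config = backbone_config("full"),
                        head = c("consensus", "gru"),
                        class_names = behavior_classes(),
                        dropout = 0.5, gru_hidden = 512L, seed = 1L) {
  head <- match.arg(head)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$class_names <- class_names
  m$head_type <- head
  m$backbone <- build_backbone(config, seed = seed)
  m$head <- with_seed(derive_seed(seed, "head"), {
    if (head == "consensus")
      new_consensus_head(m$backbone$feature_dim, length(class_names), dropout)
    else
      new_gru_head(m$backbone$feature_dim, length(class_names), gru_hidden, dropout)
  })
  m$head$frames_per_clip <- config$input_frames
  class(m) <- "pbatn_model"
  m
}

#' @export
print.pbatn_model <- function(x, ...) {
  cat(sprintf("<pbatn model: %s backbone + %s head, %d classes, %s parameters>\n",
              x$config$preset, x$head_type, length(x$class_names),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

model_layers <- function(model) {
  c(backbone_layers(model$backbone), head_layers(model$head))
}

#' Forward pass of the full model on a frame batch
#'
#' @param model a [pbatn_model()].
#' @param x (3, H, W, N) tensor, N = clips x frames_per_clip.
#' @param train keep caches for backpropagation.
#' @return list with `per_frame` (K x N logits), `fused` (K x B mean logits)
#'   and `probabilities` (K x B softmax columns).
#' @export
model_forward <- function(model, x, train = FALSE) {
  T <- model$config$input_frames
  feats <- backbone_forward(model$backbone, x, train = train)
  logits <- head_forward(model$head, feats, train = train)   # (K, N)
  B <- ncol(logits) %/% T
  fused <- t(rowsum(t(logits), group = rep(seq_len(B), each = T),
                    reorder = FALSE)) / T
  list(per_frame = logits, fused = fused, probabilities = softmax(fused))
}

# One training step's loss + full backward pass; gradients accumulate in the
# layer environments. labels are 0-based class ids, one per clip.
model_loss_backward <- function(model, x, labels) {
  out <- model_forward(model, x, train = TRUE)
  K <- nrow(out$fused); B <- ncol(out$fused)
  T <- model$config$input_frames
  onehot <- matrix(0, K, B)
  onehot[cbind(as.integer(labels) + 1L, seq_len(B))] <- 1
  loss <- cross_entropy(out$probabilities, labels)
  dfused <- (out$probabilities - onehot) / B
  dlogits <- dfused[, rep(seq_len(B), each = T), drop = FALSE] / T
  dfeats <- head_backward(model$head, dlogits)
  backbone_backward(model$backbone, dfeats)
  list(loss = loss, probabilities = out$probabilities)
}

#' Classify one clip
#'
#' Samples frames, preprocesses, runs the network in eval mode and fuses the
#' per-frame scores.
#'
#' @param model a [pbatn_model()].
#' @param clip a [clip()] object, or a preprocessed (3, H, W, T) tensor.
#' @param seed sampling seed (eval-mode sampling is deterministic anyway).
#' @return list with `class_id`, `class_name`, `probabilities`, `fused` and
#'   `per_frame` logits.
#' @export
predict_clip <- function(model, clip, seed = 1L) {
  x <- if (is.array(clip)) clip else {
    cfg <- sampler_config(num_segments = model$config$input_frames,
                          mode = "eval", seed = seed,
                          target_size = model$config$input_size)
    clip_to_batch(clip, cfg)
  }
  out <- model_forward(model, x, train = FALSE)
  res <- predict_scores(out$fused[, 1], model$class_names)
  res$fused <- out$fused[, 1]
  res$per_frame <- t(out$per_frame)
  res
}

#' Save / load model checkpoints
#'
#' Checkpoints store a flat name -> array mapping of every weight, the
#' architecture configuration, head type and the class-name list, so
#' predictions are label-stable across sessions.
#'
#' @param model a [pbatn_model()].
#' @param path file path (.rds).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a reconstructed `pbatn_model`.
#' @export
save_checkpoint <- function(model, path) {
  layers <- model_layers(model)
  flat <- list()
  for (i in seq_along(layers))
    for (nm in names(layers[[i]]$params))
      flat[[sprintf("layer%03d.%s", i, nm)]] <- layers[[i]]$params[[nm]]
  saveRDS(list(format = "pbatn-checkpoint-v1",
               config = unclass(model$config),
               head_type = model$head_type,
               class_names = model$class_names,
               dropout = model$head$dropout$p,
               gru_hidden = if (model$head_type == "gru") model$head$hidden else NULL,
               params = flat),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pbatn-checkpoint-v1"))
    stopf("not a recognized checkpoint: %s", path)
  cfg <- do.call(backbone_config,
                 c(list(preset = ck$config$preset),
                   ck$config[setdiff(names(ck$config), "preset")]))
  model <- pbatn_model(cfg, head = ck$head_type, class_names = ck$class_names,
                       dropout = ck$dropout, gru_hidden = ck$gru_hidden %||% 512L)
  layers <- model_layers(model)
  for (i in seq_along(layers))
    for (nm in names(layers[[i]]$params)) {
      key <- sprintf("layer%03d.%s", i, nm)
      if (is.null(ck$params[[key]])) stopf("checkpoint missing %s", key)
      layers[[i]]$params[[nm]] <- ck$params[[key]]
    }
  model
}
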