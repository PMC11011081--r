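# SGD training with momentum, cosine learning-rate decay and optional
# gradient-norm clipping.

#' Optimizer settings
#'
#' @param lr base learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty coefficient (0 disables).
#' @param clip_norm global gradient-norm clip (`Inf` disables).
#' @param cosine decay the learning rate to 0 over the epochs by a cosine
#'   schedule.
#' @return list of class `pbatn_optim_config`.
#' @export
optim_config <- function(lr = 1e-3, momentum = 0.9, weight_decay = 0,
                         clip_norm = 5, cosine = TRUE) {
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 clip_norm = clip_norm, cosine = cosine),
            class = "pbatn_optim_config")
}

sgd_step <- function(layers, opt, lr) {
  if (is.finite(opt$clip_norm)) {
    total <- 0
    for (l in layers) for (g in l$grads) total <- total + sum(g * g)
    total <- sqrt(total)
    scale <- if (total > opt$clip_norm) opt$clip_norm / total else 1
  } else scale <- 1
  for (l in layers) {
    if (is.null(l$vel)) l$vel <- lapply(l$params, function(p) p * 0)
    for (nm in names(l$params)) {
      g <- l$grads[[nm]] * scale
      if (opt$weight_decay > 0) g <- g + opt$weight_decay * l$params[[nm]]
      l$vel[[nm]] <- opt$momentum * l$vel[[nm]] - lr * g
      l$params[[nm]] <- l$params[[nm]] + l$vel[[nm]]
    }
    zero_grads(l)
  }
}

# Preprocess every clip of a dataset split into input tensors. Train-mode
# sampling redraws frames each epoch from the cached clips instead.
prepare_inputs <- function(ds, rows, cfg) {
  lapply(rows, function(i) clip_to_batch(dataset_clip(ds, i), cfg))
}

#' Train a model on a clip dataset
#'
#' Minimizes the segment-consensus cross-entropy with SGD (momentum 0.9,
#' cosine-decayed learning rate). Each epoch reshuffles the training clips
#' and redraws the random per-segment frames; validation accuracy is
#' computed in eval mode (deterministic midpoint sampling) after each epoch,
#' and the best-by-validation weights are restored (and optionally saved) at
#' the end.
#'
#' @param model a [pbatn_model()].
#' @param dataset a dataset index from [generate_dataset()] or
#'   [load_dataset()] with `train` and `val` splits.
#' @param epochs number of epochs.
#' @param batch_size clips per gradient step.
#' @param opt an [optim_config()].
#' @param seed master seed for shuffling, sampling and dropout.
#' @param checkpoint optional path to save the best checkpoint.
#' @param verbose log one line per epoch.
#' @return the trained model, with a `history` data frame (epoch, lr,
#'   train_loss, train_acc, val_acc) attached as `model$history`.
#' @export
train_model <- function(model, dataset, epochs = 20L, batch_size = 8L,
                        opt = optim_config(), seed = 1L,
                        checkpoint = NULL, verbose = TRUE) {
  T <- model$config$input_frames
  tgt <- model$config$input_size
  layers <- model_layers(model)
  tr_rows <- which(dataset$split == "train")
  va_rows <- which(dataset$split == "val")
  if (!length(tr_rows)) stopf("dataset has no training split")
  tr_labels <- dataset$label[tr_rows]
  # cache raw clips once; frame sampling happens per epoch
  tr_clips <- lapply(tr_rows, function(i) dataset_clip(dataset, i))
  va_inputs <- if (length(va_rows)) {
    ecfg <- sampler_config(T, "eval", target_size = tgt)
    lapply(va_rows, function(i) clip_to_batch(dataset_clip(dataset, i), ecfg))
  } else list()
  va_labels <- dataset$label[va_rows]
  history <- data.frame()
  best <- list(acc = -Inf, params = NULL)
  for (ep in seq_len(epochs)) {
    lr <- if (opt$cosine) opt$lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs)) else opt$lr
    ep_seed <- derive_seed(seed, paste0("epoch", ep))
    ord <- with_seed(ep_seed, sample(seq_along(tr_rows)))
    losses <- c(); hits <- 0L
    nb <- ceiling(length(ord) / batch_size)
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      xs <- lapply(rows, function(i) {
        scfg <- sampler_config(T, "train", target_size = tgt,
                               seed = derive_seed(ep_seed, paste0(b, "_", i)))
        clip_to_batch(tr_clips[[i]], scfg)
      })
      x <- array(unlist(xs), c(dim(xs[[1]])[1:3], T * length(rows)))
      labels <- tr_labels[rows]
      res <- with_seed(derive_seed(ep_seed, paste0("drop", b)),
                       model_loss_backward(model, x, labels))
      sgd_step(layers, opt, lr)
      losses <- c(losses, res$loss)
      hits <- hits + sum(max.col(t(res$probabilities)) - 1L == labels)
    }
    train_acc <- 100 * hits / length(ord)
    val_acc <- if (length(va_inputs))
      100 * mean(vapply(seq_along(va_inputs), function(i) {
        out <- model_forward(model, va_inputs[[i]])
        (which.max(out$fused[, 1]) - 1L) == va_labels[i]
      }, TRUE)) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = mean(losses),
                                         train_acc = train_acc,
                                         val_acc = val_acc))
    if (verbose)
      log_msg("epoch %2d/%d  lr %.2e  loss %.4f  train acc %.1f%%  val acc %s",
              ep, epochs, lr, mean(losses), train_acc,
              if (is.na(val_acc)) "-" else sprintf("%.1f%%", val_acc))
    if (!is.na(val_acc) && val_acc > best$acc) {
      best$acc <- val_acc
      best$params <- lapply(layers, function(l) l$params)
    }
  }
  if (!is.null(best$params)) {
    for (i in seq_along(layers)) layers[[i]]$params <- best$params[[i]]
  }
  model$history <- history
  model$best_val_acc <- if (is.finite(best$acc)) best$acc else NA_real_
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  model
}

#' Evaluate a model on a dataset split
#'
#' Runs deterministic eval-mode inference on every clip of the requested
#' split and assembles the full metric report plus the score matrix used for
#' PR/ROC curves.
#'
#' @param model a trained [pbatn_model()].
#' @param dataset a dataset index.
#' @param split which split to evaluate (`"test"`, `"val"`, `"train"` or
#'   `"all"`).
#' @return list with `report` ([metric_report()]), `scores` (K x n
#'   probability matrix), `predicted` and `true` label vectors.
#' @export
evaluate_model <- function(model, dataset, split = "val") {
  rows <- if (split == "all") seq_len(nrow(dataset)) else which(dataset$split == split)
  if (!length(rows)) stopf("no clips in split '%s'", split)
  ecfg <- sampler_config(model$config$input_frames, "eval",
                         target_size = model$config$input_size)
  K <- length(model$class_names)
  scores <- matrix(0, K, length(rows))
  for (j in seq_along(rows)) {
    x <- clip_to_batch(dataset_clip(dataset, rows[j]), ecfg)
    scores[, j] <- model_forward(model, x)$probabilities[, 1]
  }
  predicted <- max.col(t(scores), ties.method = "first") - 1L
  true <- dataset$label[rows]
  list(report = metric_report(true, predicted, model$class_names),
       scores = scores, predicted = predicted, true = true)
}
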