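#' Fuse per-frame class weights by segment consensus
#'
#' The consensus function of the classification head: the pre-softmax class
#' logits of the sampled frames are averaged arithmetically, and softmax is
#' applied only after fusion. Averaging logits (rather than probabilities)
#' keeps the fusion linear, so it is invariant to frame order.
#'
#' @param per_frame a T x K matrix of per-frame class logits.
#' @return list with `fused` (length-K mean logits) and `probabilities`
#'   (length-K softmax simplex vector).
#' @export
consensus <- function(per_frame) {
  if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, nrow = 1L)
  fused <- colMeans(per_frame)
  list(fused = fused, probabilities = softmax(fused))
}

#' Cross-entropy loss
#'
#' For one-hot true labels the multiclass cross-entropy reduces to the
#' negative log-probability of the true class; over a batch the mean is
#' taken. Zero predicted probability at the true class is clamped at 1e-12
#' with a warning.
#'
#' @param probabilities a length-K simplex vector, or K x B matrix of
#'   per-clip probability columns.
#' @param true_class integer class ids in `0:(K-1)` (one per clip).
#' @return non-negative scalar loss.
#' @export
cross_entropy <- function(probabilities, true_class) {
  p <- if (is.matrix(probabilities)) probabilities else matrix(probabilities)
  K <- nrow(p)
  true_class <- as.integer(true_class)
  if (any(true_class < 0L | true_class >= K))
    stopf("true class out of range 0..%d", K - 1L)
  idx <- cbind(true_class + 1L, seq_len(ncol(p)))
  pt <- p[idx]
  if (any(pt <= 0)) {
    warnf("clamping %d zero probabilities at the true class", sum(pt <= 0))
    pt <- pmax(pt, 1e-12)
  }
  mean(-log(pt))
}

#' Predict the class of a fused score vector
#'
#' Argmax with ties broken toward the lowest class index.
#'
#' @param fused length-K fused logits or probabilities.
#' @param class_names optional character vector of class names.
#' @return list with `class_id` (0-based), `class_name` (or NULL) and
#'   `probabilities`.
#' @export
predict_scores <- function(fused, class_names = NULL) {
  probs <- if (abs(sum(fused) - 1) < 1e-9 && all(fused >= 0)) fused else softmax(fused)
  id <- which.max(fused) - 1L   # which.max breaks ties at the first maximum
  list(class_id = id,
       class_name = if (!is.null(class_names)) class_names[id + 1L] else NULL,
       probabilities = probs)
}

## ---- consensus head --------------------------------------------------------

# Dropout + fully connected feature_dim -> K classifier applied per frame,
# fused by consensus at the model level.
new_consensus_head <- function(feature_dim, n_classes, dropout = 0.5) {
  h <- new.env(parent = emptyenv())
  h$type <- "consensus"
  h$feature_dim <- feature_dim
  h$n_classes <- n_classes
  h$dropout <- new_dropout(dropout)
  h$fc <- new_linear(feature_dim, n_classes)
  class(h) <- "pbatn_head"
  h
}

# features: (feature_dim, N) -> per-frame logits (K, N)
head_forward <- function(head, feats, train = FALSE) {
  if (head$type == "consensus") {
    layer_forward(head$fc, layer_forward(head$dropout, feats, train), train)
  } else {
    gru_forward(head, feats, train)
  }
}

head_backward <- function(head, dout) {
  if (head$type == "consensus") {
    layer_backward(head$dropout, layer_backward(head$fc, dout))
  } else {
    gru_backward(head, dout)
  }
}

head_layers <- function(head) {
  if (head$type == "consensus") list(head$fc)
  else list(head$gru, head$fc)
}

## ---- GRU head (PBAn variant) -----------------------------------------------

# The ablation head: instead of segment consensus, a single-layer GRU reads
# the 8 per-frame feature vectors in order and the final hidden state is
# mapped to class logits. Used with a backbone whose shift_fraction is 0,
# this is the "temporal information through recurrence" variant.
new_gru_head <- function(feature_dim, n_classes, hidden = 512L, dropout = 0.5) {
  h <- new.env(parent = emptyenv())
  h$type <- "gru"
  h$feature_dim <- feature_dim
  h$n_classes <- n_classes
  h$hidden <- as.integer(hidden)
  h$dropout <- new_dropout(dropout)
  g <- new_layer("gru_cell", din = feature_dim, dh = h$hidden, params = list(
    Wz = he_init(hidden, feature_dim, feature_dim),
    Wr = he_init(hidden, feature_dim, feature_dim),
    Wn = he_init(hidden, feature_dim, feature_dim),
    Uz = he_init(hidden, hidden, hidden),
    Ur = he_init(hidden, hidden, hidden),
    Un = he_init(hidden, hidden, hidden),
    bz = numeric(hidden), br = numeric(hidden),
    bn = numeric(hidden), bhn = numeric(hidden)))
  h$gru <- g
  h$fc <- new_linear(h$hidden, n_classes)
  class(h) <- "pbatn_head"
  h
}

# feats (feature_dim, N) with N = B*T frames -> logits (K, N) where every
# frame of a clip carries that clip's final-state logits (so the model-level
# consensus mean is a no-op for the GRU head).
gru_forward <- function(head, feats, train = FALSE) {
  g <- head$gru; P <- g$params
  T <- head$frames_per_clip %||% 8L
  N <- ncol(feats); B <- N %/% T
  x <- layer_forward(head$dropout, feats, train)
  hprev <- matrix(0, g$dh, B)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- x[, (seq_len(B) - 1L) * T + t, drop = FALSE]
    z <- sigmoid(P$Wz %*% xt + P$Uz %*% hprev + P$bz)
    r <- sigmoid(P$Wr %*% xt + P$Ur %*% hprev + P$br)
    hn_in <- P$Un %*% hprev + P$bhn
    n <- tanh(P$Wn %*% xt + P$bn + r * hn_in)
    hnew <- (1 - z) * n + z * hprev
    steps[[t]] <- list(xt = xt, z = z, r = r, n = n, hn_in = hn_in, hprev = hprev)
    hprev <- hnew
  }
  logits <- layer_forward(head$fc, hprev, train)      # (K, B)
  if (train) g$cache <- list(steps = steps, T = T, B = B, N = N)
  logits[, rep(seq_len(B), each = T), drop = FALSE]
}

gru_backward <- function(head, dout) {
  g <- head$gru; P <- g$params
  cc <- g$cache
  T <- cc$T; B <- cc$B
  # dout is (K, N) with duplicated columns per clip; collapse to (K, B)
  dl <- t(rowsum(t(dout), group = rep(seq_len(B), each = T), reorder = FALSE))
  dh <- layer_backward(head$fc, dl)
  dx <- matrix(0, g$din, cc$N)
  for (t in rev(seq_len(T))) {
    st <- cc$steps[[t]]
    dz <- dh * (st$hprev - st$n) * st$z * (1 - st$z)
    dn <- dh * (1 - st$z) * (1 - st$n^2)
    dr <- dn * st$hn_in * st$r * (1 - st$r)
    g$grads$Wz <- g$grads$Wz + dz %*% t(st$xt)
    g$grads$Wr <- g$grads$Wr + dr %*% t(st$xt)
    g$grads$Wn <- g$grads$Wn + dn %*% t(st$xt)
    g$grads$Uz <- g$grads$Uz + dz %*% t(st$hprev)
    g$grads$Ur <- g$grads$Ur + dr %*% t(st$hprev)
    g$grads$Un <- g$grads$Un + (dn * st$r) %*% t(st$hprev)
    g$grads$bz <- g$grads$bz + rowSums(dz)
    g$grads$br <- g$grads$br + rowSums(dr)
    g$grads$bn <- g$grads$bn + rowSums(dn)
    g$grads$bhn <- g$grads$bhn + rowSums(dn * st$r)
    dxt <- crossprod(P$Wz, dz) + crossprod(P$Wr, dr) + crossprod(P$Wn, dn)
    dx[, (seq_len(B) - 1L) * T + t] <- dxt
    dh <- dh * st$z + crossprod(P$Uz, dz) + crossprod(P$Ur, dr) +
      crossprod(P$Un, dn * st$r)
  }
  g$cache <- NULL
  layer_backward(head$dropout, dx)
}

#' Run a GRU consensus head over per-frame features
#'
#' @param features a T x feature_dim matrix of per-frame features (rows in
#'   temporal order).
#' @param head an existing GRU head, or NULL to build a fresh seeded one.
#' @param n_classes,hidden,seed used when building a fresh head.
#' @return length-`n_classes` fused logits from the final hidden state.
#' @export
gru_head <- function(features, head = NULL, n_classes = 6L, hidden = 512L,
                     seed = 1L) {
  T <- nrow(features); D <- ncol(features)
  if (is.null(head))
    head <- with_seed(seed, new_gru_head(D, n_classes, hidden, dropout = 0))
  head$frames_per_clip <- T
  logits <- gru_forward(head, t(features), train = FALSE)
  logits[, 1]
}
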