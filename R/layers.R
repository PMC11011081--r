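# Parameterized layers with hand-derived backpropagation.
#
# A layer is an environment carrying `params` (named list of arrays),
# `grads` (same shapes, accumulated by layer_backward) and a forward cache.
# Environments let the optimizer update weights in place without copying the
# whole model on every step.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- e$params %||% list()
  e$grads <- lapply(e$params, function(p) p * 0)
  class(e) <- c(type, "pbatn_layer")
  e
}

#' @export
print.pbatn_layer <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<%s layer, %d parameters>\n", class(x)[1], np))
  invisible(x)
}

layer_forward <- function(layer, x, train = FALSE) UseMethod("layer_forward")
layer_backward <- function(layer, dout) UseMethod("layer_backward")

zero_grads <- function(layer) {
  layer$grads <- lapply(layer$params, function(p) p * 0)
  invisible(layer)
}

# He-normal initialization for a fan_in-dominated weight.
he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- convolution -----------------------------------------------------------

# 2D convolution over (C, H, W, N). Weights are stored as a
# (out_channels x in_channels*k*k) matrix whose column order matches the
# im2col row order (channel fastest, then kernel row, then kernel column).
new_conv2d <- function(cin, cout, k = 1L, stride = 1L, pad = 0L, bias = TRUE) {
  params <- list(W = he_init(cout, cin * k * k, cin * k * k))
  if (bias) params$b <- numeric(cout)
  new_layer("conv2d", cin = cin, cout = cout, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            use_bias = bias, params = params)
}

#' @export
layer_forward.conv2d <- function(layer, x, train = FALSE) {
  d <- tensor_dims(x)
  if (d[1] != layer$cin)
    stopf("conv2d expected %d input channels, got %d", layer$cin, d[1])
  full_dims <- d
  if (layer$k == 1L) {
    if (layer$stride > 1L) {
      x <- x[, seq.int(1L, d[2], layer$stride), seq.int(1L, d[3], layer$stride), ,
             drop = FALSE]
      d <- dim(x)
    }
    cols <- matrix(x, d[1], d[2] * d[3] * d[4])
    od <- c(layer$cout, d[2], d[3], d[4])
  } else {
    Ho <- (d[2] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
    Wo <- (d[3] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
    cols <- im2col_cpp(as.double(x), d[1], d[2], d[3], d[4],
                       layer$k, layer$stride, layer$pad)
    od <- c(layer$cout, Ho, Wo, d[4])
  }
  y <- layer$params$W %*% cols
  if (layer$use_bias) y <- y + layer$params$b
  if (train) layer$cache <- list(cols = cols, in_dims = d, full_dims = full_dims,
                                 out_dims = od)
  array(y, od)
}

#' @export
layer_backward.conv2d <- function(layer, dout) {
  cc <- layer$cache
  dm <- matrix(dout, layer$cout)
  layer$grads$W <- layer$grads$W + tcrossprod(dm, cc$cols)
  if (layer$use_bias) layer$grads$b <- layer$grads$b + rowSums(dm)
  dcols <- crossprod(layer$params$W, dm)
  d <- cc$in_dims
  if (layer$k == 1L) {
    dx <- array(dcols, c(layer$cin, d[2], d[3], d[4]))
    if (layer$stride > 1L) {
      # in_dims was recorded after subsampling; rebuild the full-size gradient
      full <- cc$full_dims
      big <- array(0, full)
      big[, seq.int(1L, full[2], layer$stride), seq.int(1L, full[3], layer$stride), ] <- dx
      dx <- big
    }
  } else {
    dx <- array(col2im_cpp(dcols, d[1], d[2], d[3], d[4],
                           layer$k, layer$stride, layer$pad), d)
  }
  layer$cache <- NULL
  dx
}

## ---- group normalization ---------------------------------------------------

# Group normalization: channels are split into `groups` contiguous groups and
# each group is standardized by its own mean and variance per frame, followed
# by a learned per-channel affine map. `zero_gamma` initializes the scale to
# zero (used on the last normalization of each residual block so blocks start
# as identities).
new_group_norm <- function(C, groups = 32L, eps = 1e-5, zero_gamma = FALSE) {
  if (C %% groups != 0L)
    stopf("group norm: %d channels not divisible by %d groups", C, groups)
  new_layer("group_norm", C = C, groups = as.integer(groups), eps = eps,
            params = list(gamma = if (zero_gamma) numeric(C) else rep(1, C),
                          beta = numeric(C)))
}

#' @export
layer_forward.group_norm <- function(layer, x, train = FALSE) {
  d <- tensor_dims(x)
  if (d[1] != layer$C) stopf("group norm built for %d channels, got %d", layer$C, d[1])
  res <- gn_forward_cpp(as.double(x), d[1], d[2], d[3], d[4], layer$groups,
                        layer$eps, layer$params$gamma, layer$params$beta)
  if (train) layer$cache <- list(xhat = res$xhat, sd = res$sd, dims = d)
  array(res$y, d)
}

#' @export
layer_backward.group_norm <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$dims
  res <- gn_backward_cpp(as.double(dout), cc$xhat, cc$sd, layer$params$gamma,
                         d[1], d[2], d[3], d[4], layer$groups)
  layer$grads$gamma <- layer$grads$gamma + res$dgamma
  layer$grads$beta <- layer$grads$beta + res$dbeta
  layer$cache <- NULL
  array(res$dx, d)
}

## ---- ReLU ------------------------------------------------------------------

new_relu <- function() new_layer("relu")

#' @export
layer_forward.relu <- function(layer, x, train = FALSE) {
  y <- x * (x > 0)
  if (train) layer$cache <- (x > 0)
  y
}

#' @export
layer_backward.relu <- function(layer, dout) {
  dx <- dout * layer$cache
  layer$cache <- NULL
  dx
}

## ---- dropout ---------------------------------------------------------------

# Inverted dropout: active only in training mode, identity in eval mode.
new_dropout <- function(p = 0.5) new_layer("dropout", p = p)

#' @export
layer_forward.dropout <- function(layer, x, train = FALSE) {
  if (!train || layer$p <= 0) return(x)
  keep <- 1 - layer$p
  mask <- (array(runif(length(x)), dim(x) %||% length(x)) < keep) / keep
  layer$cache <- mask
  x * mask
}

#' @export
layer_backward.dropout <- function(layer, dout) {
  if (is.null(layer$cache)) return(dout)
  dx <- dout * layer$cache
  layer$cache <- NULL
  dx
}

## ---- linear ----------------------------------------------------------------

# Fully connected layer on (features x batch) matrices.
new_linear <- function(din, dout) {
  new_layer("linear", din = din, dout = dout,
            params = list(W = he_init(dout, din, din), b = numeric(dout)))
}

#' @export
layer_forward.linear <- function(layer, x, train = FALSE) {
  if (nrow(x) != layer$din)
    stopf("linear layer expected %d input features, got %d", layer$din, nrow(x))
  if (train) layer$cache <- x
  layer$params$W %*% x + layer$params$b
}

#' @export
layer_backward.linear <- function(layer, dout) {
  layer$grads$W <- layer$grads$W + dout %*% t(layer$cache)
  layer$grads$b <- layer$grads$b + rowSums(dout)
  dx <- crossprod(layer$params$W, dout)
  layer$cache <- NULL
  dx
}
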