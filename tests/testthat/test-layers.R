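# Layer-level behavior: temporal shift, local self-attention, channel
# attention, group normalization, and analytic-vs-numeric gradients.

test_that("temporal shift moves one channel each way with zero-filled borders", {
  # x[t, c] = 10 * (t+1) + c on a T=2, C=8, 1x1 spatial tensor
  x <- array(0, c(8, 1, 1, 2))
  for (t in 0:1) for (c in 0:7) x[c + 1, 1, 1, t + 1] <- 10 * (t + 1) + c
  out <- temporal_shift(x, fraction = 1 / 8, frames_per_clip = 2)
  expect_equal(out[1, 1, 1, 1], 0)    # forward channel, first frame vacated
  expect_equal(out[1, 1, 1, 2], 10)   # frame 2 inherits frame 1
  expect_equal(out[2, 1, 1, 1], 21)   # backward channel, frame 1 takes frame 2
  expect_equal(out[2, 1, 1, 2], 0)    # last frame vacated
  expect_equal(out[3:8, , , ], x[3:8, , , ])  # other channels untouched

  # C = 8 at fraction 1/8 shifts exactly one channel per direction
  expect_equal(floor(8 * 1 / 8), 1)
  # a single-frame clip has no neighbors: shifted channels all zero
  x1 <- array(rnorm(8 * 2 * 2), c(8, 2, 2, 1))
  o1 <- temporal_shift(x1, 1 / 8, frames_per_clip = 1)
  expect_true(all(o1[1:2, , , ] == 0))
  expect_equal(o1[3:8, , , ], x1[3:8, , , ])
})

test_that("temporal shift conserves values and inverts on interior frames", {
  x <- with_seed(3, array(rnorm(16 * 3 * 3 * 8), c(16, 3, 3, 8)))
  out <- temporal_shift(x, 1 / 8, 8)
  fold <- 2
  # conservation: shifted-channel interior values are a pure relabeling
  expect_setequal(as.numeric(out[1:fold, , , 2:8]),
                  as.numeric(x[1:fold, , , 1:7]))
  # inverse shift recovers the input on interior frames
  back <- temporal_shift(out, 1 / 8, 8, reverse = TRUE)
  expect_equal(back[, , , 2:7], x[, , , 2:7])
  expect_error(temporal_shift(x[, , , 1:6, drop = FALSE], 1 / 8, 8),
               "multiple")
  expect_error(temporal_shift(array(0, c(4, 1, 1, 2)), 1 / 16, 2), "no channels")
})

test_that("attention weights are a softmax over the 3x3 neighborhood", {
  layer <- with_seed(5, pbatn:::new_local_attention(8L, heads = 2L))
  x <- with_seed(6, array(rnorm(8 * 5 * 5), c(8, 5, 5)))
  wt <- pbatn:::attention_weights(layer, x)
  expect_equal(dim(wt), c(9, 2, 25))
  sums <- apply(wt, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(wt >= 0))
  expect_error(pbatn:::new_local_attention(8L, heads = 2L, window = 4L), "odd")
})

test_that("uniform attention over a constant input stays constant away from borders", {
  # zero position terms + constant input => every neighborhood weight equals
  # its neighbors', so the output equals the (value-projected) input in the
  # interior; verified against a brute-force 5x5 oracle
  C <- 4L
  layer <- with_seed(9, pbatn:::new_local_attention(C, heads = 1L))
  layer$params$rel[] <- 0
  x <- array(1, c(C, 5, 5))
  out <- local_attention_map(x, layer)
  vproj <- as.numeric(layer$params$Wv %*% rep(1, C))
  for (c in seq_len(C))
    expect_equal(as.numeric(out[c, 2:4, 2:4]), rep(vproj[c], 9), tolerance = 1e-10)

  # brute-force oracle on a random input: explicit per-position softmax sums
  xr <- with_seed(10, array(rnorm(C * 5 * 5), c(C, 5, 5)))
  got <- local_attention_map(xr, layer)
  q <- array(layer$params$Wq %*% matrix(xr, C), dim(xr))
  k <- array(layer$params$Wk %*% matrix(xr, C), dim(xr))
  v <- array(layer$params$Wv %*% matrix(xr, C), dim(xr))
  oracle <- array(0, dim(xr))
  for (h in 1:5) for (w in 1:5) {
    logit <- c(); vals <- list()
    for (dx in -1:1) for (dy in -1:1) {
      h2 <- h + dy; w2 <- w + dx
      kv <- if (h2 >= 1 && h2 <= 5 && w2 >= 1 && w2 <= 5)
        list(k = k[, h2, w2], v = v[, h2, w2]) else list(k = rep(0, C), v = rep(0, C))
      logit <- c(logit, sum(q[, h, w] * kv$k) / sqrt(C))
      vals[[length(vals) + 1]] <- kv$v
    }
    wts <- exp(logit - max(logit)); wts <- wts / sum(wts)
    oracle[, h, w] <- Reduce(`+`, Map(`*`, vals, wts))
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("stride-2 attention halves the spatial dimensions by pooling", {
  layer <- with_seed(4, pbatn:::new_local_attention(4L, heads = 2L))
  x <- with_seed(2, array(rnorm(4 * 8 * 8), c(4, 8, 8)))
  expect_equal(dim(local_attention_map(x, layer, stride = 2L)), c(4, 4, 4))
})

test_that("channel attention gates attenuate and vanish on zero input", {
  x0 <- array(0, c(8, 4, 4))
  res <- channel_attention_map(x0, reduction = 4L)
  expect_true(all(res$out == 0))
  expect_true(all(res$gates > 0 & res$gates < 1))

  x <- with_seed(8, array(rnorm(8 * 4 * 4), c(8, 4, 4)))
  res2 <- channel_attention_map(x, reduction = 4L)
  nz <- x != 0
  expect_true(all(abs(res2$out[nz]) < abs(x[nz])))
  expect_error(channel_attention_map(x, reduction = 3L), "divisible")
})

test_that("channel attention matches the closed form on hand-set weights", {
  layer <- pbatn:::new_channel_attention(4L, reduction = 2L)
  layer$params$W1 <- matrix(c(1, 0, 0, 0,
                              0, -1, 1, 0), 2, 4, byrow = TRUE)
  layer$params$b1 <- c(0.5, -0.25)
  layer$params$W2 <- matrix(c(1, 0, 0, 1, 2, 0, 0, -1), 4, 2)
  layer$params$b2 <- c(0, 0.1, -0.2, 0.3)
  z <- c(1, 2, -1, 0.5)                       # 1x1 input: gap is identity
  x <- array(z, c(4, 1, 1))
  h <- pmax(layer$params$W1 %*% z + layer$params$b1, 0)
  s <- 1 / (1 + exp(-(layer$params$W2 %*% h + layer$params$b2)))
  res <- channel_attention_map(x, layer)
  expect_equal(res$gates, as.numeric(s), tolerance = 1e-12)
  expect_equal(as.numeric(res$out), z * as.numeric(s), tolerance = 1e-12)
})

test_that("channel gating is positively homogeneous once the gates are frozen", {
  layer <- with_seed(12, pbatn:::new_channel_attention(8L, reduction = 4L))
  x <- with_seed(13, array(rnorm(8 * 3 * 3 * 2), c(8, 3, 3, 2)))
  g <- pbatn:::ca_gates(layer, x)
  scaled <- x * pbatn:::broadcast_cn(g$s, dim(x))
  for (a in c(0.5, 2, 7))
    expect_equal((a * x) * pbatn:::broadcast_cn(g$s, dim(x)), a * scaled)
})

test_that("group norm standardizes each group to mean 0 variance 1", {
  gn <- pbatn:::new_group_norm(8L, groups = 4L)
  x <- with_seed(21, array(rnorm(8 * 6 * 6 * 3, mean = 3, sd = 2.5),
                           c(8, 6, 6, 3)))
  y <- pbatn:::layer_forward(gn, x)   # unit affine at init
  for (n in 1:3) for (g in 1:4) {
    vals <- as.numeric(y[(g - 1) * 2 + 1:2, , , n])
    expect_lt(abs(mean(vals)), 1e-5)
    expect_lt(abs(var(vals) * (length(vals) - 1) / length(vals) - 1), 1e-4)
  }
  # per-group constant input with zero affine bias maps to zero
  gn2 <- pbatn:::new_group_norm(4L, groups = 2L)
  xc <- array(rep(c(2, 2, -3, -3), 16), c(4, 4, 4, 1))
  y2 <- pbatn:::layer_forward(gn2, xc)
  expect_true(all(abs(y2) < 1e-2))    # 0/sd(=sqrt(eps)) stays 0
  expect_error(pbatn:::new_group_norm(48L, groups = 32L), "divisible")
})

test_that("analytic gradients match finite differences through the whole net", {
  model <- micro_model(frames = 2L, size = 32L, seed = 7L)
  x <- with_seed(42, array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2)))
  label <- 3L
  layers <- pbatn:::model_layers(model)
  res <- pbatn:::model_loss_backward(model, x, label)
  expect_gt(res$loss, 0)
  eps <- 1e-5
  check <- function(l, nm, ii) {
    g_an <- l$grads[[nm]][ii]
    orig <- l$params[[nm]][ii]
    l$params[[nm]][ii] <- orig + eps
    lp <- pbatn:::model_loss_backward(model, x, label)$loss
    l$params[[nm]][ii] <- orig - eps
    lm <- pbatn:::model_loss_backward(model, x, label)$loss
    l$params[[nm]][ii] <- orig
    g_fd <- (lp - lm) / (2 * eps)
    # relative error, except where the true gradient is numerically zero
    if (abs(g_an) + abs(g_fd) < 1e-6) return(invisible(TRUE))
    expect_lt(abs(g_an - g_fd) / (abs(g_an) + abs(g_fd)), 1e-3,
              label = sprintf("grad of %s[%d] in %s", nm, ii, class(l)[1]))
  }
  set.seed(77)
  for (l in layers) {
    for (nm in names(l$params)) {
      # fresh analytic gradient for every probe: the perturbation passes in
      # check() also accumulate into the buffers
      for (m in layers) pbatn:::zero_grads(m)
      pbatn:::model_loss_backward(model, x, label)
      check(l, nm, sample(length(l$params[[nm]]), 1))
    }
  }
})
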