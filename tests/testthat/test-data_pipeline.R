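# Frame sampling, geometric preprocessing, sliding-window collection and
# dataset indexing.

test_that("segment sampling hits midpoints in eval mode and stays in range", {
  expect_equal(sample_segments(32, sampler_config(8, "eval")),
               c(2L, 6L, 10L, 14L, 18L, 22L, 26L, 30L))
  expect_equal(sample_segments(8, sampler_config(8, "eval")), 0:7)
  # short clips nearest-fill to the full segment count
  idx <- sample_segments(3, sampler_config(8, "eval"))
  expect_length(idx, 8)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= 0 & idx <= 2))
  expect_error(sample_segments(0, sampler_config(8, "eval")), "total_frames")
})

test_that("train-mode sampling is uniform within segment bounds and seeded", {
  for (seed in c(1, 17, 400, 9999)) {
    cfg <- sampler_config(8, "train", seed = seed)
    idx <- sample_segments(32, cfg)
    expect_length(idx, 8)
    expect_true(all(idx >= 4 * (0:7) & idx < 4 * (1:8)), info = paste("seed", seed))
    expect_identical(idx, sample_segments(32, cfg))  # deterministic per seed
  }
})

test_that("segment sampling output is sorted and in range for all sizes up to 64", {
  for (total in 1:64) for (S in c(1L, 3L, 8L, 16L, 64L)) {
    idx <- sample_segments(total, sampler_config(S, "eval"))
    expect_length(idx, S)
    expect_true(all(diff(idx) >= 0))
    expect_true(all(idx >= 0 & idx < total))
    idxt <- sample_segments(total, sampler_config(S, "train", seed = total + S))
    expect_true(all(idxt >= 0 & idxt < total))
    expect_true(all(diff(idxt) >= 0))
  }
})

test_that("resize_pad scales the long side and pads symmetrically", {
  fr <- array(runif(240 * 414 * 3), c(240, 414, 3))   # 414x240 (WxH) source
  out <- resize_pad(fr, 224)
  expect_equal(dim(out), c(224, 224, 3))
  rows_nonzero <- apply(out, 1, function(r) any(r != 0))
  expect_equal(sum(rows_nonzero), 130)                # 240 * 224/414 -> 130
  expect_equal(sum(cumprod(!rows_nonzero)), 47)       # 47 zero rows on top
  expect_equal(sum(cumprod(rev(!rows_nonzero))), 47)  # and 47 at the bottom

  sq <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_identical(resize_pad(sq, 224), sq)           # identity on squares

  wide <- array(runif(224 * 448 * 3), c(224, 448, 3)) # 448x224 halves to 112
  out2 <- resize_pad(wide, 224)
  rows2 <- apply(out2, 1, function(r) any(r != 0))
  expect_equal(sum(rows2), 112)
  expect_equal(sum(cumprod(!rows2)), 56)
  expect_error(resize_pad(sq, 0), "target")
})

test_that("resize_pad preserves the aspect ratio within rounding", {
  for (dims in list(c(100, 37), c(63, 200), c(31, 31), c(240, 414))) {
    fr <- array(runif(prod(dims) * 3) + 0.1, c(dims, 3))
    out <- resize_pad(fr, 96)
    rows <- sum(apply(out, 1, function(r) any(r != 0)))
    cols <- sum(apply(out, 2, function(r) any(r != 0)))
    expect_lte(abs(cols / rows - dims[2] / dims[1]) * rows, 1.5)
  }
})

test_that("clip_to_batch produces the standardized network input tensor", {
  cl <- noise_clip(32, 240, 414)
  cfg <- sampler_config(8, "eval", target_size = 224)
  x <- clip_to_batch(cl, cfg)
  expect_equal(dim(x), c(3, 224, 224, 8))
  expect_identical(x, clip_to_batch(cl, cfg))   # deterministic

  # train mode with a fixed seed is reproducible too
  tcfg <- sampler_config(8, "train", seed = 3, target_size = 64)
  small <- noise_clip(32, 64, 64)
  expect_identical(clip_to_batch(small, tcfg), clip_to_batch(small, tcfg))

  # an all-black clip maps to the standardization of zeros everywhere
  black <- clip(replicate(8, array(0, c(64, 64, 3)), simplify = FALSE))
  xb <- clip_to_batch(black, sampler_config(8, "eval", target_size = 64))
  for (ch in 1:3)
    expect_equal(unique(as.numeric(xb[ch, , , ])),
                 (0 - tcfg$mean[ch]) / tcfg$sd[ch], tolerance = 1e-12)
})

test_that("sliding window emits one clip per hop once the window fills", {
  frames <- replicate(240, array(0.5, c(8, 8, 3)), simplify = FALSE)
  clips <- sliding_window(frames, fps = 30, window = 8)
  expect_length(clips, 1)                       # 240/30 = 8 buckets, 1 window
  expect_length(clips[[1]]$frames, 8)

  clips2 <- sliding_window(frames[1:8], fps = 1, window = 8)
  expect_length(clips2, 1)

  frames10 <- replicate(80, array(0.2, c(8, 8, 3)), simplify = FALSE)
  clips3 <- sliding_window(frames10, fps = 8, window = 8, hop = 1)
  expect_length(clips3, 3)                      # windows ending at t = 8, 9, 10 s

  expect_warning(out <- sliding_window(frames[1:29], fps = 30, window = 8),
                 "never filled")
  expect_length(out, 0)
})

test_that("dataset indexing enumerates deterministically and splits 4:1", {
  root <- withr::local_tempdir()
  for (cn in behavior_classes())
    for (i in 1:10) {
      d <- file.path(root, cn, sprintf("%s_%02d", cn, i))
      dir.create(d, recursive = TRUE)
      png::writePNG(array(0.5, c(8, 8, 3)), file.path(d, "frame_00001.png"))
    }
  ds <- load_dataset(root, test_fraction = 0, seed = 5)
  expect_s3_class(ds, "pbatn_dataset")
  expect_equal(nrow(ds), 60)
  expect_setequal(unique(ds$label), 0:5)
  expect_equal(sum(ds$split == "train"), 48)    # 4:1 on the 90%=all remainder
  expect_equal(sum(ds$split == "val"), 12)
  ds2 <- load_dataset(root, test_fraction = 0, seed = 5)
  expect_identical(ds$split, ds2$split)         # same seed, same split
  ds3 <- load_dataset(root, test_fraction = 0.1, seed = 5)
  expect_equal(sum(ds3$split == "test"), 6)

  dir.create(file.path(root, "swimming"))
  expect_error(load_dataset(root), "swimming")
})

test_that("clips round-trip through the on-disk frame layout", {
  root <- withr::local_tempdir()
  cl <- noise_clip(4, 16, 16, seed = 2)
  d <- file.path(root, "c")
  dir.create(d)
  for (t in 1:4)
    png::writePNG(cl$frames[[t]], file.path(d, sprintf("frame_%05d.png", t)))
  back <- read_clip(d, label = 3L)
  expect_equal(length(back$frames), 4)
  expect_equal(back$label, 3L)
  expect_equal(back$frames[[2]], cl$frames[[2]], tolerance = 1 / 255)
  expect_error(read_clip(file.path(root, "nope")), "no PNG")
})
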