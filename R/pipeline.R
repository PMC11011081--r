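#' Clip objects
#'
#' A clip is an ordered list of equally sized RGB frames with an optional
#' behavior label and free-form metadata (the synthetic generator stores the
#' agent trajectories there).
#'
#' @param frames list of H x W x 3 numeric arrays with values in `[0, 1]`.
#' @param label integer behavior id in `0..K-1`, or `NULL` for unlabeled.
#' @param clip_id identifier string.
#' @param meta optional named list of metadata.
#' @return an object of class `pbatn_clip`.
#' @export
clip <- function(frames, label = NULL, clip_id = "clip", meta = list()) {
  if (length(frames) < 1L) stopf("a clip needs at least one frame")
  d1 <- dim(frames[[1]])
  if (length(d1) != 3L || d1[3] != 3L)
    stopf("frames must be H x W x 3 arrays")
  ok <- vapply(frames, function(f) identical(dim(f), d1), TRUE)
  if (!all(ok)) stopf("all frames of a clip must share dimensions")
  structure(list(frames = frames, label = label, clip_id = clip_id, meta = meta),
            class = "pbatn_clip")
}

#' @export
print.pbatn_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<clip '%s': %d frames of %dx%d, label %s>\n", x$clip_id,
              length(x$frames), d[1], d[2],
              if (is.null(x$label)) "none" else x$label))
  invisible(x)
}

#' Frame sampler configuration
#'
#' @param num_segments number of segments a clip is divided into (one frame
#'   is drawn per segment; default 8).
#' @param mode `"train"` (uniform random frame within each segment) or
#'   `"eval"` (deterministic segment midpoint).
#' @param seed RNG seed for train-mode sampling.
#' @param target_size side length of the square network input (default 224).
#' @param mean,sd per-channel normalization constants applied after scaling
#'   pixel values to `[0, 1]` (defaults: the ImageNet statistics).
#' @return list of class `pbatn_sampler_config`.
#' @export
sampler_config <- function(num_segments = 8L, mode = c("eval", "train"),
                           seed = 1L, target_size = 224L,
                           mean = c(0.485, 0.456, 0.406),
                           sd = c(0.229, 0.224, 0.225)) {
  mode <- match.arg(mode)
  if (num_segments < 1L) stopf("num_segments must be >= 1")
  structure(list(num_segments = as.integer(num_segments), mode = mode,
                 seed = as.integer(seed), target_size = as.integer(target_size),
                 mean = mean, sd = sd),
            class = "pbatn_sampler_config")
}

#' Sparse segment sampling of frame indices
#'
#' Divides `total_frames` frames into `num_segments` equal segments
#' (`[floor(i*total/S), floor((i+1)*total/S))` for segment i) and picks one
#' frame per segment: a uniformly random one in train mode, the segment
#' midpoint in eval mode. Clips shorter than the segment count yield repeated
#' nearest indices so the output length is always `num_segments`.
#'
#' @param total_frames number of frames available (>= 1).
#' @param cfg a [sampler_config()].
#' @return non-decreasing integer vector of 0-based frame indices, length
#'   `cfg$num_segments`, each within its segment.
#' @export
sample_segments <- function(total_frames, cfg = sampler_config()) {
  total_frames <- as.integer(total_frames)
  if (is.na(total_frames) || total_frames < 1L)
    stopf("total_frames must be >= 1, got %s", total_frames)
  S <- cfg$num_segments
  lo <- floor((seq_len(S) - 1L) * total_frames / S)
  hi <- floor(seq_len(S) * total_frames / S)
  if (cfg$mode == "eval") {
    idx <- floor(((seq_len(S) - 1L) + 0.5) * total_frames / S)
  } else {
    idx <- with_seed(cfg$seed, {
      vapply(seq_len(S), function(i) {
        if (hi[i] > lo[i]) lo[i] + sample.int(hi[i] - lo[i], 1L) - 1L
        else min(lo[i], total_frames - 1L)
      }, 0)
    })
  }
  as.integer(pmin(pmax(idx, 0L), total_frames - 1L))
}

#' Aspect-preserving resize and zero padding
#'
#' Scales a frame so its longer side equals `target` (bilinear, preserving
#' the aspect ratio; the shorter side is rounded to the nearest integer),
#' then pads the shorter dimension symmetrically with black `[0,0,0]` pixels
#' to a `target x target` square. An odd pad remainder goes to the
#' bottom/right.
#'
#' @param frame H x W x 3 numeric array in `[0, 1]`.
#' @param target side length of the output square (default 224).
#' @return target x target x 3 array.
#' @export
resize_pad <- function(frame, target = 224L) {
  if (target < 1L) stopf("target must be >= 1")
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) stopf("frame must be H x W x 3")
  H <- d[1]; W <- d[2]
  if (H == target && W == target) return(frame)
  if (H >= W) { nh <- target; nw <- as.integer(round(W * target / H)) }
  else        { nw <- target; nh <- as.integer(round(H * target / W)) }
  if (nh != H || nw != W) {
    img <- EBImage::Image(aperm(frame, c(2L, 1L, 3L)), colormode = "Color")
    img <- EBImage::resize(img, w = nw, h = nh)
    frame <- aperm(EBImage::imageData(img), c(2L, 1L, 3L))
  }
  out <- array(0, c(target, target, 3L))
  pt <- (target - nh) %/% 2L
  pl <- (target - nw) %/% 2L
  out[pt + seq_len(nh), pl + seq_len(nw), ] <- frame
  out
}

#' Convert a clip into a network input tensor
#'
#' Applies [sample_segments()], [resize_pad()] on each sampled frame,
#' channel-first conversion, and per-channel standardization, producing the
#' (3, target, target, num_segments) input the backbone consumes (the
#' conventional 8 x 3 x 224 x 224 input at default settings).
#'
#' @param clip a [clip()].
#' @param cfg a [sampler_config()].
#' @return a (3, target, target, num_segments) numeric array.
#' @export
clip_to_batch <- function(clip, cfg = sampler_config()) {
  if (!inherits(clip, "pbatn_clip")) stopf("expected a pbatn_clip")
  idx <- sample_segments(length(clip$frames), cfg) + 1L
  tgt <- cfg$target_size
  x <- array(0, c(3L, tgt, tgt, cfg$num_segments))
  for (t in seq_along(idx)) {
    f <- resize_pad(clip$frames[[idx[t]]], tgt)
    x[, , , t] <- aperm(f, c(3L, 1L, 2L))
  }
  (x - cfg$mean) / cfg$sd
}

#' Sliding-window clip collection from an online frame stream
#'
#' Mirrors the online capture protocol: one frame is chosen at random inside
#' every one-second bucket of the stream; once `window` buckets have been
#' collected a clip is emitted, and subsequent clips slide forward by `hop`
#' seconds. A stream shorter than one window emits nothing (with a warning).
#'
#' @param frames list of H x W x 3 frames, in stream order.
#' @param fps frames per second of the stream (>= 1).
#' @param window clip length in buckets/frames (default 8).
#' @param hop hop between successive windows, in seconds (default 1).
#' @param seed RNG seed for the within-second random pick.
#' @return list of [clip()] objects (possibly empty).
#' @export
sliding_window <- function(frames, fps, window = 8L, hop = 1L, seed = 1L) {
  if (fps < 1L) stopf("fps must be >= 1")
  nb <- length(frames) %/% fps
  picks <- with_seed(seed, {
    vapply(seq_len(nb), function(b)
      (b - 1L) * fps + sample.int(fps, 1L), 0)
  })
  if (nb < window) {
    warnf("stream ended after %d bucket(s); window of %d never filled", nb, window)
    return(list())
  }
  ends <- seq.int(window, nb, by = hop)
  lapply(seq_along(ends), function(i) {
    sel <- picks[(ends[i] - window + 1L):ends[i]]
    clip(frames[sel], clip_id = sprintf("window_t%02ds", ends[i]))
  })
}

#' Index a clip dataset directory
#'
#' Scans `root/<class_name>/<clip_id>/frame_*.png` layouts, assigns labels by
#' the fixed class order, and splits entries into train/validation/test sets:
#' a fixed `test_fraction` is drawn per class first, and the remainder is
#' divided train:validation at `train_val_ratio` (default 4:1), all under one
#' seed.
#'
#' @param root dataset root directory (one subdirectory per class).
#' @param class_names expected class folders, in label order.
#' @param test_fraction fraction held out as the test split (default 0.1).
#' @param train_val_ratio train:validation ratio for the remainder (default 4).
#' @param seed split RNG seed.
#' @return a `data.frame` of class `pbatn_dataset` with columns `clip_id`,
#'   `path`, `label`, `class_name`, `split`.
#' @export
load_dataset <- function(root, class_names = behavior_classes(),
                         test_fraction = 0.1, train_val_ratio = 4,
                         seed = 1L) {
  if (!dir.exists(root)) stopf("dataset root does not exist: %s", root)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  unknown <- setdiff(dirs, class_names)
  if (length(unknown))
    stopf("unknown class folder(s): %s", paste(unknown, collapse = ", "))
  rows <- list()
  for (cn in class_names) {
    cdir <- file.path(root, cn)
    if (!dir.exists(cdir)) next
    clips <- sort(list.dirs(cdir, recursive = FALSE, full.names = FALSE))
    if (!length(clips)) { warnf("class folder '%s' is empty", cn); next }
    rows[[cn]] <- data.frame(
      clip_id = paste(cn, clips, sep = "/"),
      path = file.path(cdir, clips),
      label = match(cn, class_names) - 1L,
      class_name = cn, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$split <- assign_splits(df$label, test_fraction, train_val_ratio, seed)
  attr(df, "class_names") <- class_names
  attr(df, "root") <- root
  class(df) <- c("pbatn_dataset", "data.frame")
  df
}

# Stratified split: per class, test first, then remainder 4:1 train:val.
assign_splits <- function(labels, test_fraction, train_val_ratio, seed) {
  split <- character(length(labels))
  with_seed(seed, {
    for (lb in sort(unique(labels))) {
      idx <- which(labels == lb)
      n <- length(idx)
      n_test <- round(n * test_fraction)
      test_idx <- if (n_test > 0) sample(idx, n_test) else integer(0)
      rest <- setdiff(idx, test_idx)
      n_val <- round(length(rest) / (train_val_ratio + 1))
      val_idx <- if (n_val > 0) sample(rest, n_val) else integer(0)
      split[test_idx] <- "test"
      split[val_idx] <- "val"
      split[setdiff(rest, val_idx)] <- "train"
    }
  })
  split
}

#' Read a clip's frames from disk
#'
#' @param path clip directory containing `frame_*.png` files.
#' @param label optional label to attach.
#' @param clip_id identifier (defaults to the directory name).
#' @return a [clip()].
#' @export
read_clip <- function(path, label = NULL, clip_id = basename(path)) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stopf("no PNG frames found in %s", path)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a[, , 1:3, drop = FALSE]
  })
  clip(frames, label = label, clip_id = clip_id)
}

# Fetch clip i of a dataset index, whether on disk or in memory.
dataset_clip <- function(ds, i) {
  clips <- attr(ds, "clips")
  if (!is.null(clips)) return(clips[[ds$path[i]]])
  read_clip(ds$path[i], label = ds$label[i], clip_id = ds$clip_id[i])
}
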