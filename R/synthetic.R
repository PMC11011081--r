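# Synthetic six-class behavior clips: two disk agents in a square arena.
#
# The generator is the package's stand-in for real enclosure video. Each
# behavior class gets a distinct motion signature:
#   activity    - the leader walks; the partner keeps a comparable separation
#                 but its displacement is statistically independent of the
#                 leader's path
#   chasing     - the partner follows the leader's trail `follow_delay`
#                 frames behind, so it keeps landing where the leader just
#                 was (pursuit: the temporal-order signature)
#   mounting    - sustained >= 60% disk overlap, both near-static
#   feeding     - one agent parked at the fixed trough coordinate, the other
#                 walks
#   resting     - both static, well separated
#   disturbance - a third, larger, bright agent walks through the scene
# Chasing and activity are deliberately matched in single-frame appearance:
# in both, the partner sits one delayed-walk displacement away from the
# leader (the activity offset is drawn from an independent walk with the
# same statistics), so a frame-order-invariant classifier sees the same
# marginal picture and only temporal order separates the pair. All other
# classes carry spatial or appearance cues.

#' Scene parameters for the synthetic generator
#'
#' @param width,height frame size in pixels (default 64 x 64; use 240 x 414
#'   to emulate full-resolution source frames).
#' @param radius agent disk radius in pixels.
#' @param speed step length of a walking agent per frame (also the tether
#'   distance between the agent pair in activity/chasing).
#' @param heading_sd standard deviation (radians) of the per-frame heading
#'   increment of the correlated random walk.
#' @param follow_delay trail lag of the chasing partner, in frames (it
#'   follows the leader's position this many frames back).
#' @param overlap_fraction minimum disk-overlap fraction held during mounting.
#' @param trough normalized (x, y) position of the feeding trough.
#' @param noise_sd Gaussian pixel noise standard deviation (on the `[0, 1]`
#'   intensity scale; default 4/255).
#' @param frames_per_clip frames rendered per clip (default 32).
#' @return list of class `pbatn_scene_params`.
#' @export
scene_params <- function(width = 64L, height = 64L, radius = 5,
                         speed = 6, heading_sd = 0.35, follow_delay = 3L,
                         overlap_fraction = 0.6,
                         trough = c(0.78, 0.22), noise_sd = 4 / 255,
                         frames_per_clip = 32L) {
  stopifnot(width >= 16, height >= 16, radius > 0, speed > 0, noise_sd >= 0,
            follow_delay >= 1, frames_per_clip >= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 radius = radius, speed = speed, heading_sd = heading_sd,
                 follow_delay = as.integer(follow_delay),
                 overlap_fraction = overlap_fraction, trough = trough,
                 noise_sd = noise_sd,
                 frames_per_clip = as.integer(frames_per_clip)),
            class = "pbatn_scene_params")
}

# Correlated random walk confined to the arena (positions are (x, y)).
random_walk <- function(T, params, margin, start = NULL, speed = NULL) {
  W <- params$width; H <- params$height
  sp <- speed %||% params$speed
  lo <- margin; hix <- W - margin; hiy <- H - margin
  pos <- matrix(0, T, 2)
  p <- start %||% c(runif(1, lo, hix), runif(1, lo, hiy))
  th <- runif(1, 0, 2 * pi)
  for (t in seq_len(T)) {
    pos[t, ] <- p
    th <- th + rnorm(1, 0, params$heading_sd)
    cand <- p + sp * c(cos(th), sin(th))
    # reflect off the walls
    if (cand[1] < lo || cand[1] > hix) { th <- pi - th; cand[1] <- pmin(pmax(cand[1], lo), hix) }
    if (cand[2] < lo || cand[2] > hiy) { th <- -th; cand[2] <- pmin(pmax(cand[2], lo), hiy) }
    p <- cand
  }
  pos
}

render_frame <- function(agents, params) {
  W <- params$width; H <- params$height
  img <- array(0.12, c(H, W, 3L))
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), W), H, W)
  for (a in agents) {
    dist <- sqrt((xg - a$pos[1])^2 + (yg - a$pos[2])^2)
    alpha <- pmin(pmax(a$r + 0.5 - dist, 0), 1)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) + a$col[ch] * alpha
  }
  if (params$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
  pmin(pmax(img, 0), 1)
}

AGENT_COL_A <- c(0.85, 0.45, 0.35)
AGENT_COL_B <- c(0.35, 0.55, 0.85)
AGENT_COL_X <- c(0.95, 0.95, 0.95)

#' Generate one synthetic behavior clip
#'
#' Renders `params$frames_per_clip` frames of two (or, for disturbance,
#' three) disk agents following the motion model of the requested behavior,
#' adds Gaussian pixel noise, and attaches the exact agent trajectories as
#' metadata. Fully determined by `(behavior, params, seed)`.
#'
#' @param behavior one of [behavior_classes()].
#' @param params a [scene_params()].
#' @param seed integer RNG seed.
#' @return a [clip()] with `meta$trajectories` (`A`, `B`, optionally `X`,
#'   each a T x 2 matrix of (x, y) positions) and the class id as label.
#' @export
generate_clip <- function(behavior, params = scene_params(), seed = 1L) {
  classes <- behavior_classes()
  if (!behavior %in% classes)
    stopf("unknown behavior '%s' (expected one of %s)", behavior,
          paste(classes, collapse = ", "))
  T <- params$frames_per_clip
  r <- params$radius
  margin <- r + params$speed + 2
  with_seed(seed, {
    X <- NULL
    # both partners live in the walk's margin box so the chasing and
    # activity classes share the same positional support frame by frame
    clamp_box <- function(P) {
      P[, 1] <- pmin(pmax(P[, 1], margin), params$width - margin)
      P[, 2] <- pmin(pmax(P[, 2], margin), params$height - margin)
      P
    }
    d <- params$follow_delay
    if (behavior == "activity") {
      # the partner sits one independent d-step-walk displacement from the
      # leader: same separation statistics as chasing, no motion coupling.
      # Offsets that would leave the walk's box are rotated (not clamped),
      # so the partner occupies the same support as a trailing chaser and
      # no boundary-contact cue separates the classes frame by frame.
      A <- random_walk(T, params, margin)
      G <- random_walk(T + d, params, margin)
      off <- G[(d + 1):(T + d), , drop = FALSE] - G[seq_len(T), , drop = FALSE]
      lo <- margin; hx <- params$width - margin; hy <- params$height - margin
      feasible <- function(cand)
        cand[1] >= lo && cand[1] <= hx && cand[2] >= lo && cand[2] <= hy
      rot <- function(o, ang)
        c(cos(ang) * o[1] - sin(ang) * o[2], sin(ang) * o[1] + cos(ang) * o[2])
      for (t in seq_len(T)) {
        o <- off[t, ]
        if (!feasible(A[t, ] - o)) {
          # smallest rotation that keeps the partner inside the box,
          # preserving the separation distance exactly
          for (ang in as.vector(rbind(1, -1)) * rep(seq(0.15, pi, 0.15), each = 2)) {
            if (feasible(A[t, ] - rot(o, ang))) { o <- rot(o, ang); break }
          }
        }
        off[t, ] <- o
      }
      B <- clamp_box(A - off + matrix(rnorm(2 * T, 0, 0.4), T, 2))
    } else if (behavior == "chasing") {
      # trail pursuit: B follows A's position d frames back
      Afull <- random_walk(T + d, params, margin)
      A <- Afull[(d + 1):(T + d), , drop = FALSE]
      B <- clamp_box(Afull[seq_len(T), , drop = FALSE] +
                       matrix(rnorm(2 * T, 0, 0.4), T, 2))
    } else if (behavior == "mounting") {
      c0 <- c(runif(1, margin, params$width - margin),
              runif(1, margin, params$height - margin))
      # center separation giving at least the requested overlap fraction
      dmax <- 2 * r * (1 - params$overlap_fraction)
      off <- runif(1, 0, dmax) * c(cos(a0 <- runif(1, 0, 2 * pi)), sin(a0))
      A <- matrix(rep(c0, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.25), T, 2)
      B <- sweep(A, 2, -off) + matrix(rnorm(2 * T, 0, 0.25), T, 2)
    } else if (behavior == "feeding") {
      tr <- c(params$trough[1] * params$width, params$trough[2] * params$height)
      A <- matrix(rep(tr, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.25), T, 2)
      B <- random_walk(T, params, margin)
    } else if (behavior == "resting") {
      repeat {
        pA <- c(runif(1, margin, params$width - margin),
                runif(1, margin, params$height - margin))
        pB <- c(runif(1, margin, params$width - margin),
                runif(1, margin, params$height - margin))
        if (sum((pA - pB)^2) > (3 * r)^2) break
      }
      A <- matrix(rep(pA, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.2), T, 2)
      B <- matrix(rep(pB, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.2), T, 2)
    } else {  # disturbance
      repeat {
        pA <- c(runif(1, margin, params$width - margin),
                runif(1, margin, params$height - margin))
        pB <- c(runif(1, margin, params$width - margin),
                runif(1, margin, params$height - margin))
        if (sum((pA - pB)^2) > (3 * r)^2) break
      }
      A <- matrix(rep(pA, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.2), T, 2)
      B <- matrix(rep(pB, each = T), T, 2) + matrix(rnorm(2 * T, 0, 0.2), T, 2)
      X <- random_walk(T, params, 2 * r + 2)
    }
    frames <- lapply(seq_len(T), function(t) {
      agents <- list(list(pos = A[t, ], r = r, col = AGENT_COL_A),
                     list(pos = B[t, ], r = r, col = AGENT_COL_B))
      if (!is.null(X))
        agents <- c(agents, list(list(pos = X[t, ], r = 2 * r, col = AGENT_COL_X)))
      render_frame(agents, params)
    })
    clip(frames, label = match(behavior, classes) - 1L,
         clip_id = sprintf("%s_seed%d", behavior, seed),
         meta = list(trajectories = list(A = A, B = B, X = X),
                     behavior = behavior, seed = seed))
  })
}

#' Pursuit statistic of a two-agent trajectory
#'
#' Mean cosine of the angle between the partner's step vector and the
#' partner-to-leader bearing. Positive values mean the partner tends to move
#' toward where the leader is (pursuit); reversing the frame order of a
#' pursuit flips the sign (the partner then appears to lead).
#'
#' @param A,B T x 2 position matrices of leader and partner.
#' @return scalar in `[-1, 1]`.
#' @export
follow_statistic <- function(A, B) {
  T <- nrow(B)
  step <- B[-1, , drop = FALSE] - B[-T, , drop = FALSE]
  bear <- A[-1, , drop = FALSE] - B[-1, , drop = FALSE]
  num <- rowSums(step * bear)
  den <- sqrt(rowSums(step^2) * rowSums(bear^2))
  ok <- den > 1e-9
  mean(num[ok] / den[ok])
}

#' Generate a labeled synthetic dataset
#'
#' Builds `counts` clips per class (balanced unless a named per-class vector
#' is given). With `root = NULL` the clips stay in memory; otherwise the
#' standard `root/<class>/<clip_id>/frame_%05d.png` layout plus a
#' `manifest.json` (class names, counts, per-clip seeds, scene parameters)
#' is written to disk.
#'
#' @param counts clips per class: a single integer or a named vector over
#'   [behavior_classes()].
#' @param params a [scene_params()].
#' @param seed master seed; every clip derives its own sub-seed from it.
#' @param root output directory or `NULL` for in-memory.
#' @param overwrite allow writing into an existing non-empty `root`.
#' @param test_fraction,train_val_ratio,split_seed split controls passed to
#'   the same stratified splitter as [load_dataset()].
#' @return a dataset index (`pbatn_dataset` data frame).
#' @export
generate_dataset <- function(counts = 10L, params = scene_params(), seed = 1L,
                             root = NULL, overwrite = FALSE,
                             test_fraction = 0, train_val_ratio = 4,
                             split_seed = seed) {
  classes <- behavior_classes()
  if (is.null(names(counts))) counts <- setNames(rep(counts, length(classes)), classes)
  if (any(!names(counts) %in% classes)) stopf("unknown class in counts")
  if (any(counts < 1L)) stopf("counts must be >= 1 per class")
  classes <- classes[classes %in% names(counts)]   # named subsets allowed
  if (!is.null(root) && dir.exists(root) && length(list.files(root)) && !overwrite)
    stopf("refusing to write into non-empty directory %s (use overwrite = TRUE)", root)
  rows <- list(); clips <- list(); seeds <- list()
  for (cn in classes) {
    for (i in seq_len(counts[[cn]])) {
      s <- derive_seed(seed, paste0(cn, i))
      cl <- generate_clip(cn, params, seed = s)
      cl$clip_id <- sprintf("%s/%s_%03d", cn, cn, i)
      key <- sprintf("%s_%03d", cn, i)
      clips[[key]] <- cl
      seeds[[key]] <- s
      rows[[key]] <- data.frame(clip_id = cl$clip_id, path = key,
                                label = cl$label, class_name = cn,
                                stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$split <- assign_splits(df$label, test_fraction, train_val_ratio, split_seed)
  attr(df, "class_names") <- behavior_classes()
  class(df) <- c("pbatn_dataset", "data.frame")
  if (is.null(root)) {
    attr(df, "clips") <- clips
    return(df)
  }
  for (key in names(clips)) {
    cl <- clips[[key]]
    cdir <- file.path(root, cl$clip_id)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(cl$frames))
      png::writePNG(cl$frames[[t]], file.path(cdir, sprintf("frame_%05d.png", t)))
  }
  manifest <- list(class_names = classes, counts = as.list(counts),
                   seed = seed, clip_seeds = seeds,
                   params = unclass(params))
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df$path <- file.path(root, df$clip_id)
  attr(df, "root") <- root
  df
}

#' Resolve overlapping behavior events by breeding precedence
#'
#' Annotation rule for overlapping event intervals: a breeding behavior
#' (mounting or chasing) takes priority over any non-breeding behavior
#' wherever they overlap; mounting outranks chasing; remaining conflicts go
#' to the earliest-starting event (then the lowest class id).
#'
#' @param events data frame with columns `start`, `end` (half-open
#'   `[start, end)` frame intervals, `start < end`) and `behavior` (name or
#'   0-based id).
#' @return data frame of non-overlapping `(start, end, behavior)` runs
#'   covering the union of the input intervals.
#' @export
resolve_labels <- function(events) {
  if (!nrow(events)) stopf("no events to resolve")
  classes <- behavior_classes()
  beh <- events$behavior
  if (is.numeric(beh)) beh <- classes[beh + 1L]
  if (any(!beh %in% classes)) stopf("unknown behavior in events")
  if (any(events$start >= events$end)) stopf("event intervals need start < end")
  prio <- function(b, s) {
    # smaller is stronger: mounting, then chasing, then start order
    base <- ifelse(b == "mounting", 0, ifelse(b == "chasing", 1, 2))
    base * 1e9 + ifelse(base == 2, s * 1e3 + match(b, classes), 0)
  }
  bounds <- sort(unique(c(events$start, events$end)))
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    act <- which(events$start <= s & events$end >= e)
    if (!length(act)) next
    win <- act[which.min(prio(beh[act], events$start[act]))]
    out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                          behavior = beh[win],
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  # merge adjacent runs with the same label
  keep <- c(TRUE, res$behavior[-1] != res$behavior[-nrow(res)] |
                  res$start[-1] != res$end[-nrow(res)])
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(res, grp), function(g)
    data.frame(start = g$start[1], end = g$end[nrow(g)], behavior = g$behavior[1],
               stringsAsFactors = FALSE)))
  rownames(merged) <- NULL
  merged
}
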