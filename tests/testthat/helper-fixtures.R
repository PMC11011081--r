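# Shared fixtures: miniature architecture configs and toy clips, built in
# code so the repository ships no binary data.

# A very small but structurally complete backbone (all five stages, one
# block each) for fast layer/shape tests.
micro_config <- function(frames = 2L, size = 32L, shift = 1 / 8) {
  backbone_config("tiny", conv1_channels = 8L,
                  bottleneck_widths = c(4L, 4L, 8L, 8L),
                  stage_depths = c(1L, 1L, 1L, 1L), gn_groups = 2L,
                  heads = 2L, ca_reduction = 4L,
                  input_frames = frames, input_size = size,
                  shift_fraction = shift)
}

micro_model <- function(frames = 2L, size = 32L, seed = 7L, head = "consensus",
                        dropout = 0, shift = 1 / 8) {
  pbatn_model(micro_config(frames, size, shift), head = head,
              dropout = dropout, gru_hidden = 8L, seed = seed)
}

# A deterministic gradient-free toy clip: n solid-color frames.
toy_clip <- function(n = 8L, h = 32L, w = 32L, value = 0.5, label = 0L) {
  clip(replicate(n, array(value, c(h, w, 3L)), simplify = FALSE),
       label = label, clip_id = "toy")
}

# Random frames clip.
noise_clip <- function(n = 8L, h = 32L, w = 32L, seed = 1L, label = NULL) {
  with_seed(seed,
    clip(replicate(n, array(runif(h * w * 3), c(h, w, 3L)), simplify = FALSE),
         label = label, clip_id = "noise"))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
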