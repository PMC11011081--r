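# pbatn

Video behavior recognition for captive-animal monitoring, built around
**PBATn** — a temporal-shift + attention network originally designed to
recognize the breeding and daily behaviors of pangolins from enclosure
video — implemented entirely in R with hand-derived backpropagation (no
external deep-learning framework), plus the full surrounding pipeline:
frame sampling, preprocessing, a synthetic clip generator, training,
multiclass evaluation, online sliding-window inference, class-activation
heat maps and a CLI.

## Who this is for

Researchers who want a transparent, testable reference implementation of
the architecture and its evaluation protocol — every layer's forward and
backward pass is ordinary R/C++ code that can be read, probed and verified
(the test suite checks all gradients against finite differences).

## The model

Six behaviors are recognized: `activity`, `chasing`, `mounting`, `feeding`,
`resting`, `disturbance` (chasing and mounting are breeding behaviors). A
clip is reduced to 8 sparsely sampled frames (one per segment), resized
aspect-preserving to 224 and zero-padded square: an `8 × 3 × 224 × 224`
input.

The backbone is ResNet-50-shaped (stages of 3-4-6-3 bottlenecks) with a
modified main path in every residual block:

```
temporal shift → 1×1 conv → local 3×3 self-attention → 1×1 conv → channel attention
```

* **temporal shift** — 1/8 of the channels move one frame forward in time
  and 1/8 one frame backward (zero-filled boundaries): zero-parameter
  temporal mixing;
* **local self-attention** — per position, softmax-scaled dot-product
  weights over the 3×3 neighborhood from shared 1×1 query/key/value
  projections with learned relative-position terms (replaces the 3×3
  convolution);
* **channel attention** — squeeze-excite gating (pool → C/16 → C → sigmoid);
* every 7×7/1×1 convolution is followed by GroupNorm(32) + ReLU.

Stage outputs follow `64×112×112 → 64×56×56 → 256×56×56 → 512×28×28 →
1024×14×14 → 2048×7×7 → 2048×1×1`. The head applies dropout and a fully
connected 2048 → 6 map per frame, averages the 8 logit vectors (segment
consensus), and trains with cross-entropy `L(y, y') = −Σ_i y_i log y'_i`.
A GRU-head ablation variant (`head = "gru"`, `shift_fraction = 0`) is
included. Evaluation implements the one-vs-rest protocol: per-class
accuracy, precision, recall/TPR, FPR, specificity, F1, macro averages (the
macro precision is reported as mAP), PR curves with the balance point, and
macro/micro-averaged ROC with AUC.

## Worked example

Everything below runs on synthetic data rendered by the package (two disk
agents in an arena; each behavior class has its own motion signature, and
chasing vs activity is separable only through temporal order):

```r
library(pbatn)

# 60 clips per class, 64x64, split 4:1 train:val
ds <- generate_dataset(60L, scene_params(), seed = 11)

model <- pbatn_model(backbone_config("tiny"), dropout = 0.3, seed = 11)
model <- train_model(model, ds, epochs = 30, batch_size = 8,
                     opt = optim_config(lr = 0.02), seed = 11)

res <- evaluate_model(model, ds, split = "val")
print(res$report)
```

which prints (seed 11; ~20 s per epoch on one CPU; best validation accuracy
98.61%):

```
<evaluation of 72 clips>
  class_name accuracy precision recall specificity     f1
    activity   100.00    100.00 100.00      100.00 100.00
     chasing   100.00    100.00 100.00      100.00 100.00
    mounting    98.61     92.31 100.00       98.33  96.00
     feeding   100.00    100.00 100.00      100.00 100.00
     resting    98.61    100.00  91.67      100.00  95.65
 disturbance   100.00    100.00 100.00      100.00 100.00
macro: accuracy 99.54  precision (mAP) 98.72  recall 98.61  specificity 99.72  F1 98.61
micro accuracy: 98.61
```

Chasing and activity — the pair that is indistinguishable frame-by-frame
and is separable only through the temporal-shift pathway — are both
resolved perfectly; ablating the shift (`shift_fraction = 0`) drops that
pair to near chance while leaving the spatially cued classes intact.
Classify a single clip or an online stream:

```r
cl <- generate_clip("chasing", scene_params(), seed = 99)
predict_clip(model, cl)$class_name
#> [1] "chasing"
```

A thin CLI wraps the same functions
(`Rscript inst/cli/pbatn.R synth|train|eval|infer|cam --config run.yaml`).

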