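# stresswear

Three-class stress detection from wearable biosignals — a complete,
reproducible pipeline covering synthetic cohort generation, signal
preprocessing, self-supervised pretraining and deep-model evaluation, in
pure R.

## The problem

Wearable sensors make it cheap to record photoplethysmography (PPG, three
optical channels at 55 Hz), single-lead ECG (512 Hz) and single-channel
EEG (512 Hz) while a person works on a demanding task. Each 15-minute
session carries one self-reported stress score *s* ∈ {0,…,8}, mapped to a
class *y*:

* *y* = 0 (relaxed): *s* ≤ 4
* *y* = 1 (medium stress): 5 ≤ *s* ≤ 7
* *y* = 2 (high stress): *s* = 8

The pipeline turns raw sessions into labeled 10-second windows and trains
three 1-D deep architectures to predict *y* per window:

1. **StressNeXt** — 1×1 projection, then four multi-kernel blocks
   (parallel convolutions with kernels 1/3/5/7 combined by elementwise
   **addition**), global average pooling, dense head;
2. **LRCN** — convolutions + residual blocks followed by two LSTM layers
   (convolutional-recurrent);
3. **Self-supervised CNN** — a 3-block encoder (32/64/128 filters,
   kernels 32/16/8, max-pool 8 stride 2) pretrained to recognize which of
   five signal transformations (noise σ = 0.01, scaling ×1.1, negation,
   time reversal, 20×64-sample piece permutation) produced its input,
   then reused through global max pooling (128-feature embedding) for
   classification.

Preprocessing follows a fixed protocol: every channel is resampled onto a
230,400-sample grid (15 min × 256 Hz), band-passed with a zero-phase
order-4 Butterworth (PPG 0.5–5 Hz, ECG 5–15 Hz, EEG 0.1–15 Hz), cut into
90 windows of 2,560 samples, and z-scored per window. Evaluation uses
stratified 3-fold cross-validation, Adam (lr 0.001), accuracy and
macro-averaged F1, fold-averaged confusion matrices, and breakdowns by
signal combination, scenario and puzzle difficulty.

Since cohorts of this kind are rarely redistributable, the package ships a
statistically structured synthetic generator (stress raises heart rate,
lowers heart-rate variability and suppresses the EEG alpha/beta ratio) so
every stage is testable end to end; real recordings in the same
plain-text session format run through the identical code path.

## Worked example

Generate a small balanced cohort with well-separated class heart rates,
preprocess the ECG, and train the convolutional-recurrent model:

```r
library(stresswear)

spec <- cohort_spec(n_participants = 6, n_medium = 3, n_hard = 3,
                    score_mode = "balanced", hr_by_class = c(60, 90, 120),
                    early_finish_frac = 0)
cohort <- generate_cohort(spec, seed = 7, modalities = "ecg")
segs <- build_segment_set(cohort, modalities = "ecg")
segs
#> <segment_set> 1620 segments x 1 channels x 2560 samples @ 256 Hz
#>   channels: ECG
#>   classes: 0:630  1:450  2:540

set.seed(7)
keep <- unlist(lapply(0:2, function(cl) sample(which(segs$labels == cl), 40)))
labels <- segs$labels[keep]
folds <- stratified_folds(labels, k = 3, seed = 7)

model <- build_lrcn(model_spec("lrcn", in_channels = 1), seed = 7)
fit <- train_model(model, segs$segments[keep, , , drop = FALSE], labels,
                   train_idx = setdiff(seq_along(labels), folds[[1]]),
                   val_idx = folds[[1]],
                   config = train_config(epochs_main = 25, batch_size = 16,
                                         seed = 7, early_stop_acc = 0.95,
                                         fold_metric_mode = "final_epoch"))
glance(fit)
#> # A tibble: 1 x 8
#>   model epochs accuracy    f1 final_val_accuracy n_params n_train n_val
#>   <chr>  <int>    <dbl> <dbl>              <dbl>    <int>   <int> <int>
#> 1 lrcn       6    0.952 0.952              0.952   309443      78    42
```

The model separates the three simulated stress classes from raw ECG
windows within six epochs (95 % validation accuracy) — expected, because
the generator gives the classes strongly separated heart rates (60/90/120
bpm). `accuracy`/`f1` are the fold metrics under the configured mode
(final epoch); `tidy(fit)` returns the per-epoch curves and
`autoplot(fit)` plots them. `evaluate_suite()` runs the full model ×
signal-combination × breakdown grid and returns per-fold tibbles plus
fold-averaged confusion matrices (`plot_confusion()`).

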