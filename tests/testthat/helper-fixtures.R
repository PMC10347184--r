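# Shared fixtures, built once per test session and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Tiny in-memory cohort with all modalities (short sessions keep it fast).
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    spec <- cohort_spec(n_participants = 2, n_medium = 1, n_hard = 1,
                        session_minutes = 0.5, early_finish_frac = 0)
    generate_cohort(spec, seed = 101)
  })
}

tiny_segset <- function() {
  fixture("tiny_segset", function() build_segment_set(tiny_cohort()))
}

# Balanced cohort with strongly separated class heart rates (60/90/120 bpm)
# for the model-recovery checks: ECG-only, 6 participants x 3 scenarios,
# subsampled to 40 segments per class with a stratified train/val split.
recovery_data <- function() {
  fixture("recovery_data", function() {
    spec <- cohort_spec(n_participants = 6, n_medium = 3, n_hard = 3,
                        hr_by_class = c(60, 90, 120),
                        score_mode = "balanced", early_finish_frac = 0)
    coh <- generate_cohort(spec, seed = 11, modalities = "ecg")
    ss <- build_segment_set(coh, modalities = "ecg")
    set.seed(5)
    keep <- unlist(lapply(0:2, function(cl) sample(which(ss$labels == cl), 40)))
    labels <- ss$labels[keep]
    folds <- stratified_folds(labels, k = 3, seed = 2)
    list(segments = ss$segments[keep, , , drop = FALSE],
         labels = labels,
         val_idx = folds[[1]],
         train_idx = setdiff(seq_along(labels), folds[[1]]))
  })
}

# Full-size self-supervised run on the recovery cohort: pretext stage on a
# training subset, encoder snapshot taken right after pretraining (before
# any label is seen), then the classifier stage on the full labeled split.
# Shared between the recovery checks and the low-label-benefit property.
recovery_sscnn <- function() {
  fixture("recovery_sscnn", function() {
    data <- recovery_data()
    spec <- model_spec("sscnn", in_channels = 1)
    cfg <- train_config(epochs_main = 30, epochs_pretrain = 30,
                        batch_size = 16, seed = 408,
                        early_stop_acc = 0.9, early_stop_acc_pretrain = 0.65,
                        fold_metric_mode = "final_epoch")
    bundle <- build_sscnn(spec, seed = cfg$seed)
    pb <- make_pretext_batch(
      data$segments[data$train_idx[1:24], , , drop = FALSE],
      seed = derive_seed_t(cfg$seed, "pretext_train"))
    pvb <- make_pretext_batch(
      data$segments[data$val_idx[1:6], , , drop = FALSE],
      seed = derive_seed_t(cfg$seed, "pretext_val"))
    n1 <- length(pb$labels)
    allin <- array(NA_real_, dim = c(n1 + length(pvb$labels), 1, 2560))
    allin[seq_len(n1), , ] <- pb$inputs
    allin[n1 + seq_along(pvb$labels), , ] <- pvb$inputs
    pre_cfg <- cfg
    pre_cfg$early_stop_acc <- cfg$early_stop_acc_pretrain
    pretext_fit <- train_model(bundle$pretext, allin,
                               c(pb$labels, pvb$labels),
                               seq_len(n1), n1 + seq_along(pvb$labels),
                               pre_cfg, epochs = cfg$epochs_pretrain)
    encoder_snapshot <- model_weights(bundle$encoder)
    classifier_fit <- train_model(bundle$classifier, data$segments,
                                  data$labels, data$train_idx, data$val_idx,
                                  cfg)
    list(spec = spec, config = cfg, pretext_fit = pretext_fit,
         classifier_fit = classifier_fit,
         encoder_snapshot = encoder_snapshot)
  })
}

derive_seed_t <- function(...) asNamespace("stresswear")$derive_seed(...)

# Random normalized segments for model/transform tests (no physiology).
random_segments <- function(n, C = 1, len = 2560, seed = 1) {
  set.seed(seed)
  normalize_segments(array(rnorm(n * C * len), dim = c(n, C, len)))
}

# Brute-force metric oracle: explicit counting loops, independent of the
# package's vectorized implementations.
oracle_confusion <- function(pred, true, levels) {
  cm <- matrix(0L, length(levels), length(levels),
               dimnames = list(true = levels, pred = levels))
  for (i in seq_along(pred)) {
    r <- which(levels == true[i])
    c <- which(levels == pred[i])
    cm[r, c] <- cm[r, c] + 1L
  }
  cm
}

oracle_metrics <- function(pred, true, levels) {
  cm <- oracle_confusion(pred, true, levels)
  n_correct <- 0L
  for (i in seq_along(pred)) if (pred[i] == true[i]) n_correct <- n_correct + 1L
  prec <- rec <- f1 <- numeric(length(levels))
  for (k in seq_along(levels)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = n_correct / length(pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       confusion = cm)
}

# Measured zero-phase filter gain: amplitude ratio of a long probe sinusoid,
# read off the central section to exclude any residual edge effects.
probe_gain <- function(spec, f, rate = 256, dur = 240) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * f * t)
  y <- bandpass(x, spec, rate)
  mid <- y[round(length(y) * 0.3):round(length(y) * 0.7)]
  sqrt(2) * sqrt(mean(mid^2))
}

# Simple R-peak counter on a clean quasi-periodic trace: local maxima above
# half the global maximum, separated by a refractory gap.
count_peaks <- function(x, rate, refractory_s = 0.25) {
  thr <- max(x) / 2
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  gap <- round(refractory_s * rate)
  while (i < n) {
    if (x[i] > thr && x[i] >= x[i - 1] && x[i] >= x[i + 1]) {
      peaks <- c(peaks, i)
      i <- i + gap
    } else {
      i <- i + 1L
    }
  }
  length(peaks)
}
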