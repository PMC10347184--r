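# Training protocol: Adam, minibatch cross-entropy, per-epoch validation
# metrics; fold performance is the mean of the per-epoch validation metrics
# (the protocol's stated rule) or the final epoch's, by configuration.

#' Training configuration
#'
#' Defaults follow the evaluation protocol: 3-fold stratified
#' cross-validation, Adam with learning rate 0.001, 300 epochs for the
#' classifiers and 150 for self-supervised pretraining, cross-entropy loss.
#'
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param learning_rate Adam learning rate.
#' @param epochs_main Classifier training epochs.
#' @param epochs_pretrain Pretext pretraining epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling and weight initialization.
#' @param fold_metric_mode `"epoch_mean"`: a fold's performance is the mean
#'   of its per-epoch validation metrics (the protocol's rule);
#'   `"final_epoch"`: the last epoch's metrics.
#' @param early_stop_acc Optional validation-accuracy threshold at which
#'   training stops early (useful for desk-scale runs); `NULL` disables.
#' @param early_stop_acc_pretrain Separate early-stop threshold for the
#'   pretext pretraining stage; defaults to `early_stop_acc`.
#' @return An object of class `train_config`.
#' @export
#' @examples
#' train_config(epochs_main = 10, batch_size = 16)
train_config <- function(k_folds = 3L, learning_rate = 0.001,
                         epochs_main = 300L, epochs_pretrain = 150L,
                         batch_size = 64L, seed = 1L,
                         fold_metric_mode = c("epoch_mean", "final_epoch"),
                         early_stop_acc = NULL,
                         early_stop_acc_pretrain = NULL) {
  fold_metric_mode <- match.arg(fold_metric_mode)
  assert_that(is_count(k_folds) && k_folds >= 2, "k_folds must be >= 2")
  assert_that(is_number(learning_rate) && learning_rate > 0,
              "learning_rate must be > 0")
  assert_that(is_count(epochs_main) && is_count(epochs_pretrain),
              "epochs must be >= 1")
  assert_that(is_count(batch_size), "batch_size must be >= 1")
  structure(list(k_folds = as.integer(k_folds),
                 learning_rate = learning_rate,
                 epochs_main = as.integer(epochs_main),
                 epochs_pretrain = as.integer(epochs_pretrain),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 fold_metric_mode = fold_metric_mode,
                 early_stop_acc = early_stop_acc,
                 early_stop_acc_pretrain = early_stop_acc_pretrain),
            class = "train_config")
}

# Labels arrive 0-based (stress classes 0-2, pretext 0-5); the engine wants
# 1-based column indices.
as_y1 <- function(labels) as.integer(labels) + 1L

#' Train a model on a train/validation split
#'
#' Minimizes cross-entropy with Adam. After every epoch the validation
#' accuracy and macro-F1 are recorded; the fold performance is their mean
#' over epochs or the final epoch's value, per the configuration.
#'
#' @param model A `stress_model` (modified in place: layer weights live in
#'   environments).
#' @param segments `[n x C x len]` array or `segment_set`.
#' @param labels Integer labels, 0-based, one per segment.
#' @param train_idx,val_idx Disjoint index vectors into `segments`.
#' @param config A [train_config()].
#' @param epochs Number of epochs; defaults to `config$epochs_main`.
#' @return An object of class `stress_fit`: the model plus a per-epoch
#'   `history` tibble and the fold-level `metrics`.
#' @export
train_model <- function(model, segments, labels, train_idx, val_idx,
                        config = train_config(), epochs = config$epochs_main) {
  assert_that(inherits(model, "stress_model"), "model must be a stress_model")
  if (inherits(segments, "segment_set")) segments <- segments$segments
  assert_that(length(intersect(train_idx, val_idx)) == 0,
              "train and validation indices must be disjoint")
  y <- as_y1(labels)
  assert_that(max(y) <= model$n_out, "label outside the model's output range")
  n_train <- length(train_idx)
  bs <- min(config$batch_size, n_train)
  history <- vector("list", epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(config$seed, "epoch", model$name, ep),
                     sample(train_idx))
    losses <- c()
    for (start in seq(1, n_train, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n_train)]
      t <- segments_to_tensor(segments[idx, , , drop = FALSE])
      logits <- net_forward(model$layers, t, train = TRUE)
      sc <- softmax_ce(logits$x, y[idx])
      if (!is.finite(sc$loss)) {
        rlang::abort(sprintf(
          "training diverged (non-finite loss) at epoch %d, step %d", ep, step))
      }
      losses <- c(losses, sc$loss)
      net_backward(model$layers, nn_tensor(sc$dlogits, 1L, length(idx)))
      step <- step + 1L
      adam_step(model$layers, config$learning_rate, step)
    }
    val_pred <- predict(model, segments[val_idx, , , drop = FALSE],
                        type = "class", batch_size = bs)
    val_true <- labels[val_idx]
    acc <- accuracy(val_pred, val_true)
    f1 <- precision_recall_f1(val_pred, val_true,
                              levels = 0:(model$n_out - 1))$f1
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                            val_accuracy = acc, val_macro_f1 = f1)
    if (!is.null(config$early_stop_acc) && acc >= config$early_stop_acc) break
  }
  net_clear_state(model$layers)
  history <- dplyr::bind_rows(history)
  metrics <- if (config$fold_metric_mode == "epoch_mean") {
    list(accuracy = mean(history$val_accuracy),
         f1 = mean(history$val_macro_f1))
  } else {
    list(accuracy = history$val_accuracy[nrow(history)],
         f1 = history$val_macro_f1[nrow(history)])
  }
  structure(list(model = model, history = history, metrics = metrics,
                 config = config,
                 n_train = n_train, n_val = length(val_idx)),
            class = "stress_fit")
}

#' @export
print.stress_fit <- function(x, ...) {
  cat("<stress_fit> ", x$model$name, ": ", nrow(x$history), " epochs, ",
      x$n_train, " train / ", x$n_val, " val segments\n", sep = "")
  cat(sprintf("  fold metrics (%s): accuracy %.3f, macro-F1 %.3f\n",
              x$config$fold_metric_mode, x$metrics$accuracy, x$metrics$f1))
  invisible(x)
}

#' Self-supervised pretraining followed by classifier training
#'
#' Stage 1 trains the pretext model (shared encoder + 6-way transformation
#' head) on a [make_pretext_batch()] built from the *training* segments
#' only, for `epochs_pretrain` epochs. Stage 2 trains the classifier head
#' (and, unless `freeze_encoder`, fine-tunes the shared encoder) on the
#' stress labels for `epochs` epochs. Because the encoder is shared by
#' reference, stage 2 starts exactly from the pretrained weights.
#'
#' @param segments `[n x C x len]` array or `segment_set`.
#' @param labels Stress classes (0-2), one per segment.
#' @param train_idx,val_idx Disjoint index vectors.
#' @param spec A [model_spec()] for `"sscnn"`.
#' @param config A [train_config()].
#' @param transform A [transform_spec()].
#' @param freeze_encoder If `TRUE`, stage 2 updates only the classifier
#'   head.
#' @param skip_pretrain If `TRUE`, stage 1 is skipped entirely, giving the
#'   plain randomly initialized CNN baseline.
#' @param epochs,epochs_pretrain Stage lengths; default from `config`.
#' @param pretext_train_idx,pretext_val_idx Segments used to build the
#'   pretext batches; default to the full training/validation splits.
#'   Because every source segment yields six pretext examples, a subset
#'   keeps the pretraining stage proportionate.
#' @return List of class `sscnn_fit` with elements `classifier_fit`,
#'   `pretext_fit` (`NULL` when skipped) and `model` (the `sscnn` bundle).
#' @export
pretrain_then_classify <- function(segments, labels, train_idx, val_idx,
                                   spec = model_spec("sscnn"),
                                   config = train_config(),
                                   transform = transform_spec(),
                                   freeze_encoder = FALSE,
                                   skip_pretrain = FALSE,
                                   epochs = config$epochs_main,
                                   epochs_pretrain = config$epochs_pretrain,
                                   pretext_train_idx = train_idx,
                                   pretext_val_idx = val_idx) {
  if (inherits(segments, "segment_set")) segments <- segments$segments
  assert_that(all(pretext_train_idx %in% train_idx) &&
                all(pretext_val_idx %in% val_idx),
              "pretext indices must come from the corresponding splits")
  bundle <- build_sscnn(spec, seed = config$seed)
  pretext_fit <- NULL
  if (!skip_pretrain) {
    batch <- make_pretext_batch(segments[pretext_train_idx, , , drop = FALSE],
                                spec = transform,
                                seed = derive_seed(config$seed, "pretext_train"))
    vbatch <- make_pretext_batch(segments[pretext_val_idx, , , drop = FALSE],
                                 spec = transform,
                                 seed = derive_seed(config$seed, "pretext_val"))
    all_in <- abind3(batch$inputs, vbatch$inputs)
    all_lab <- c(batch$labels, vbatch$labels)
    ntr <- length(batch$labels)
    pre_cfg <- config
    pre_cfg$early_stop_acc <- config$early_stop_acc_pretrain %||%
      config$early_stop_acc
    pretext_fit <- train_model(bundle$pretext, all_in, all_lab,
                               train_idx = seq_len(ntr),
                               val_idx = ntr + seq_along(vbatch$labels),
                               config = pre_cfg, epochs = epochs_pretrain)
  }
  if (freeze_encoder) {
    # Encoder gradients are discarded before each optimizer step, so only
    # the classifier head moves.
    classifier_fit <- train_model_frozen(bundle, segments, labels, train_idx,
                                         val_idx, config, epochs)
  } else {
    classifier_fit <- train_model(bundle$classifier, segments, labels,
                                  train_idx, val_idx, config, epochs)
  }
  structure(list(model = bundle, pretext_fit = pretext_fit,
                 classifier_fit = classifier_fit,
                 freeze_encoder = freeze_encoder,
                 skip_pretrain = skip_pretrain),
            class = "sscnn_fit")
}

# Classifier training with encoder weights held fixed: gradients of encoder
# layers are deleted before each optimizer step.
train_model_frozen <- function(bundle, segments, labels, train_idx, val_idx,
                               config, epochs) {
  enc_layers <- flatten_layers(unclass(bundle$encoder))
  # wrap adam by clearing encoder grads: temporarily replace grads after bwd
  model <- bundle$classifier
  y <- as_y1(labels)
  n_train <- length(train_idx)
  bs <- min(config$batch_size, n_train)
  history <- vector("list", epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(config$seed, "epochF", ep), sample(train_idx))
    losses <- c()
    for (start in seq(1, n_train, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n_train)]
      t <- segments_to_tensor(segments[idx, , , drop = FALSE])
      logits <- net_forward(model$layers, t, train = TRUE)
      sc <- softmax_ce(logits$x, y[idx])
      losses <- c(losses, sc$loss)
      net_backward(model$layers, nn_tensor(sc$dlogits, 1L, length(idx)))
      for (ly in enc_layers) ly$grads <- list()
      step <- step + 1L
      adam_step(model$layers, config$learning_rate, step)
    }
    val_pred <- predict(model, segments[val_idx, , , drop = FALSE],
                        type = "class", batch_size = bs)
    acc <- accuracy(val_pred, labels[val_idx])
    f1 <- precision_recall_f1(val_pred, labels[val_idx],
                              levels = 0:(model$n_out - 1))$f1
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                            val_accuracy = acc, val_macro_f1 = f1)
    if (!is.null(config$early_stop_acc) && acc >= config$early_stop_acc) break
  }
  net_clear_state(model$layers)
  history <- dplyr::bind_rows(history)
  metrics <- if (config$fold_metric_mode == "epoch_mean") {
    list(accuracy = mean(history$val_accuracy), f1 = mean(history$val_macro_f1))
  } else {
    list(accuracy = history$val_accuracy[nrow(history)],
         f1 = history$val_macro_f1[nrow(history)])
  }
  structure(list(model = model, history = history, metrics = metrics,
                 config = config, n_train = n_train, n_val = length(val_idx)),
            class = "stress_fit")
}

# Bind two [n x C x L] arrays along the first dimension.
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(NA_real_, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}
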