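# Evaluation pipeline: folds, metrics, training loop contracts and the
# self-report change table.

test_that("stratified folds partition indices and balance classes", {
  labels <- rep(0:2, c(60, 30, 9))
  folds <- stratified_folds(labels, k = 3, seed = 1)
  expect_length(folds, 3)
  # exhaustive count check: each fold holds exactly (20, 10, 3)
  for (f in folds) {
    expect_equal(unname(tabulate(factor(labels[f], 0:2), 3)), c(20, 10, 3))
  }
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(labels))
  expect_equal(sum(lengths(folds)), length(labels))
  expect_error(stratified_folds(c(0, 0, 0, 1, 1), k = 3, seed = 1),
               "fewer than k")
})

test_that("folds contain every class on heavily skewed labels", {
  scores <- sample_scores(cohort_spec(), seed = 17)
  labels <- rep(scores$class, each = 90)   # segment-level labels
  folds <- stratified_folds(labels, k = 3, seed = 2)
  for (f in folds) expect_setequal(unique(labels[f]), 0:2)
})

test_that("metrics agree with the brute-force confusion-matrix oracle", {
  set.seed(42)
  worst <- 0
  cm_ok <- TRUE
  for (r in 1:200) {
    n <- sample(2:50, 1)
    lv <- 0:2
    true <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    o <- oracle_metrics(pred, true, lv)
    m <- precision_recall_f1(pred, true, levels = lv)
    worst <- max(worst,
                 abs(accuracy(pred, true) - o$accuracy),
                 abs(m$precision - o$precision),
                 abs(m$recall - o$recall),
                 abs(m$f1 - o$f1))
    cm_ok <- cm_ok && all(confusion_matrix(pred, true, levels = lv) ==
                            o$confusion)
  }
  expect_lt(worst, 1e-12)
  expect_true(cm_ok)
})

test_that("metric edge cases behave", {
  expect_equal(accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(accuracy(c(1, 2, 0), c(0, 1, 2)), 0)
  p <- precision_recall_f1(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("the constant-majority predictor reproduces the imbalance arithmetic", {
  # class counts as observed over the full 8100-segment corpus
  true <- rep(0:2, c(6030, 1710, 360))
  pred <- rep(0L, length(true))
  expect_equal(accuracy(pred, true), 6030 / 8100)
  expect_equal(round(accuracy(pred, true), 4), 0.7444)
  m <- precision_recall_f1(pred, true, levels = 0:2)
  a <- 6030 / 8100
  expect_equal(m$f1, (2 * a / (1 + a)) / 3, tolerance = 1e-12)
  expect_equal(round(m$f1, 4), 0.2845)
})

test_that("training records per-epoch metrics and honours the metric modes", {
  segs <- random_segments(24, 1, seed = 20)
  labs <- rep(0:2, 8)
  cfg <- train_config(epochs_main = 3, batch_size = 8, seed = 1,
                      fold_metric_mode = "epoch_mean")
  m <- build_model(model_spec("stressnext", in_channels = 1, width = 4), seed = 1)
  fit <- train_model(m, segs, labs, train_idx = 1:18, val_idx = 19:24, cfg)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$metrics$accuracy, mean(fit$history$val_accuracy))
  cfg2 <- cfg; cfg2$fold_metric_mode <- "final_epoch"
  m2 <- build_model(model_spec("stressnext", in_channels = 1, width = 4), seed = 1)
  fit2 <- train_model(m2, segs, labs, 1:18, 19:24, cfg2, epochs = 1)
  expect_equal(nrow(fit2$history), 1)
  # with one epoch both modes coincide
  expect_equal(fit2$metrics$accuracy, fit2$history$val_accuracy[1])
  expect_error(train_model(m2, segs, labs, 1:18, 15:24, cfg2), "disjoint")
  # tidiers
  expect_equal(tidy(fit)$epoch, 1:3)
  expect_equal(glance(fit)$epochs, 3)
})

test_that("training drives accuracy to 1 on a separable toy problem", {
  # two classes distinguished by a strong low- vs high-frequency component
  set.seed(30)
  n <- 16
  len <- 512
  t <- seq_len(len) / 256
  segs <- array(0, dim = c(n, 1, len))
  labs <- rep(0:1, each = n / 2)
  for (i in seq_len(n)) {
    f <- if (labs[i] == 0) 3 else 20
    segs[i, 1, ] <- sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(len, 0, 0.1)
  }
  segs <- normalize_segments(segs)
  m <- build_model(model_spec("stressnext", in_channels = 1, width = 8), seed = 2)
  cfg <- train_config(epochs_main = 50, batch_size = 8, seed = 2,
                      early_stop_acc = 1.0, fold_metric_mode = "final_epoch")
  fit <- train_model(m, segs, labs, train_idx = which(seq_len(n) %% 2 == 1),
                     val_idx = which(seq_len(n) %% 2 == 0), cfg)
  expect_equal(fit$metrics$accuracy, 1.0)
  expect_lte(nrow(fit$history), 50)
})

test_that("training is deterministic under a fixed seed", {
  segs <- random_segments(12, 1, seed = 33)
  labs <- rep(0:2, 4)
  cfg <- train_config(epochs_main = 2, batch_size = 6, seed = 9)
  run <- function() {
    m <- build_model(model_spec("lrcn", in_channels = 1, width = 4,
                                lstm_hidden = 4), seed = 9)
    train_model(m, segs, labs, 1:9, 10:12, cfg)$history
  }
  expect_identical(run(), run())
})

test_that("pretraining then classifying shares and reuses the encoder", {
  segs <- random_segments(18, 1, seed = 40)
  labs <- rep(0:2, 6)
  spec <- model_spec("sscnn", in_channels = 1,
                     encoder_filters = c(4L, 8L, 16L),
                     encoder_kernels = c(8L, 8L, 8L))
  cfg <- train_config(epochs_main = 2, epochs_pretrain = 2, batch_size = 12,
                      seed = 13)
  fit <- pretrain_then_classify(segs, labs, 1:12, 13:18, spec, cfg)
  # stage 2 starts exactly from the stage-1 encoder: same environments
  enc_in_classifier <- fit$model$classifier$layers[seq_along(unclass(fit$model$encoder))]
  expect_true(all(mapply(identical, enc_in_classifier,
                         unclass(fit$model$encoder))))
  expect_equal(nrow(fit$pretext_fit$history), 2)
  expect_equal(nrow(fit$classifier_fit$history), 2)
  # skipping stage 1 gives the plain CNN baseline (no pretext fit)
  base <- pretrain_then_classify(segs, labs, 1:12, 13:18, spec, cfg,
                                 skip_pretrain = TRUE)
  expect_null(base$pretext_fit)
  # frozen-encoder mode leaves the pretrained encoder weights untouched
  froz <- pretrain_then_classify(segs, labs, 1:12, 13:18, spec, cfg,
                                 freeze_encoder = TRUE)
  expect_s3_class(froz$classifier_fit, "stress_fit")
})

test_that("weight snapshots restore a model exactly", {
  m1 <- build_model(model_spec("stressnext", in_channels = 1, width = 4),
                    seed = 1)
  m2 <- build_model(model_spec("stressnext", in_channels = 1, width = 4),
                    seed = 2)
  segs <- random_segments(2, 1, seed = 41)
  expect_false(isTRUE(all.equal(predict(m1, segs, type = "logits"),
                                predict(m2, segs, type = "logits"))))
  set_model_weights(m2, model_weights(m1))
  expect_equal(predict(m2, segs, type = "logits"),
               predict(m1, segs, type = "logits"), tolerance = 1e-12)
  expect_error(set_model_weights(
    build_model(model_spec("stressnext", in_channels = 1, width = 8), seed = 1),
    model_weights(m1)), "shapes differ|layer structure")
})

test_that("pretext pretraining helps when labels are scarce", {
  # the low-label regime: 9 labeled training segments (3 per class); the
  # pretrained encoder comes from the shared recovery fixture, snapshotted
  # before any stress label was seen
  data <- recovery_data()
  fx <- recovery_sscnn()
  set.seed(9)
  low_idx <- unlist(lapply(0:2, function(cl)
    sample(intersect(data$train_idx, which(data$labels == cl)), 3)))
  val_idx <- data$val_idx[1:21]
  cfg <- train_config(epochs_main = 10, batch_size = 16, seed = 3,
                      fold_metric_mode = "final_epoch")
  pre <- build_sscnn(fx$spec, seed = cfg$seed)
  set_model_weights(pre$encoder, fx$encoder_snapshot)
  fit_pre <- train_model(pre$classifier, data$segments, data$labels,
                         low_idx, val_idx, cfg)
  base <- build_sscnn(fx$spec, seed = cfg$seed)
  fit_base <- train_model(base$classifier, data$segments, data$labels,
                          low_idx, val_idx, cfg)
  expect_gte(max(fit_pre$history$val_accuracy),
             max(fit_base$history$val_accuracy))
})

test_that("self-report change counts are consistent", {
  scores <- sample_scores(cohort_spec(), seed = 23)
  tab <- selfreport_summary(scores)
  all_rows <- tab[tab$difficulty == "all", ]
  expect_true(all(all_rows$increased + all_rows$decreased +
                    all_rows$unchanged == 30))
  # skewed-mode generator: comforting scenario 3 lowers stress vs noisy 1
  s31 <- all_rows[all_rows$comparison == "scenario 3 vs 1", ]
  expect_gte(s31$decreased, s31$increased)
  # all-equal scores give zero changes
  const <- tibble::tibble(participant_id = rep(1:5, each = 3),
                          scenario = rep(1:3, 5),
                          difficulty = "medium", score = 4L)
  tab0 <- selfreport_summary(const)
  expect_true(all(tab0$increased == 0 & tab0$decreased == 0))
  expect_true(all(tab0[tab0$difficulty == "all", ]$unchanged == 5))
  dup <- const[c(1, 1, 2), ]
  expect_error(selfreport_summary(dup), "exactly one score")
})
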