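# Cross-validated evaluation across models, signal combinations and
# scenario / difficulty breakdowns.

signal_combinations <- c("ppg", "ecg", "eeg", "ppg+ecg", "ppg+eeg",
                         "ecg+eeg", "ppg+ecg+eeg")

# Train/evaluate one model spec on one segment set under k-fold stratified
# CV; returns per-fold metrics and the fold-averaged confusion matrix.
cross_validate_model <- function(model_name, segset, config,
                                 width = 64L, lstm_hidden = 128L,
                                 encoder_filters = c(32L, 64L, 128L),
                                 encoder_kernels = c(32L, 16L, 8L),
                                 transform = transform_spec()) {
  labels <- segset$labels
  folds <- stratified_folds(labels, k = config$k_folds, seed = config$seed)
  spec <- model_spec(model_name, in_channels = length(segset$channel_map),
                     width = width, lstm_hidden = lstm_hidden,
                     encoder_filters = encoder_filters,
                     encoder_kernels = encoder_kernels)
  fold_rows <- vector("list", length(folds))
  cms <- vector("list", length(folds))
  npar <- NA_integer_
  for (f in seq_along(folds)) {
    val_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), val_idx)
    fold_seed <- derive_seed(config$seed, "fold", model_name, f)
    fold_cfg <- config
    fold_cfg$seed <- fold_seed
    if (model_name == "sscnn") {
      fit <- pretrain_then_classify(segset$segments, labels, train_idx,
                                    val_idx, spec, fold_cfg, transform)
      cfit <- fit$classifier_fit
      npar <- n_params(fit$model)
    } else {
      model <- build_model(spec, seed = fold_seed)
      cfit <- train_model(model, segset$segments, labels, train_idx, val_idx,
                          fold_cfg)
      npar <- n_params(model)
    }
    pred <- predict(cfit$model, segset$segments[val_idx, , , drop = FALSE],
                    type = "class")
    cms[[f]] <- confusion_matrix(pred, labels[val_idx], levels = 0:2)
    fold_rows[[f]] <- tibble(fold = f,
                             accuracy = cfit$metrics$accuracy,
                             f1 = cfit$metrics$f1,
                             epochs_run = nrow(cfit$history))
  }
  cm_avg <- Reduce(`+`, cms) / length(cms)
  list(folds = dplyr::bind_rows(fold_rows), confusion = cm_avg,
       n_params = npar)
}

#' Evaluate models across signal combinations and breakdowns
#'
#' For every requested model and signal combination, runs stratified
#' k-fold cross-validation on the segment set and records fold metrics and
#' the fold-averaged confusion matrix. Scenario and difficulty breakdowns
#' retrain on the corresponding subset by default (each breakdown cell is
#' its own experiment); `subset_mode = "slice"` instead slices the global
#' validation predictions.
#'
#' @param segset A `segment_set` containing every modality needed by
#'   `combinations`.
#' @param models Model names among `"stressnext"`, `"lrcn"`, `"sscnn"`.
#' @param combinations Signal combinations, e.g. `c("ecg", "ppg+ecg")`.
#' @param config A [train_config()].
#' @param breakdowns Any of `"scenario"`, `"difficulty"` (or none).
#' @param subset_mode `"retrain"` or `"slice"` for the breakdowns.
#' @param ... Width knobs passed to the model specs (`width`,
#'   `lstm_hidden`, `encoder_filters`, `encoder_kernels`).
#' @return An object of class `stress_eval`: tibbles `results` (per fold)
#'   and `summary` (aggregated), a named list `confusion` of fold-averaged
#'   confusion matrices, an optional `breakdown` tibble, and the config.
#' @export
evaluate_suite <- function(segset,
                           models = c("stressnext", "lrcn", "sscnn"),
                           combinations = signal_combinations,
                           config = train_config(),
                           breakdowns = character(0),
                           subset_mode = c("retrain", "slice"),
                           ...) {
  subset_mode <- match.arg(subset_mode)
  models <- match.arg(models, c("stressnext", "lrcn", "sscnn"),
                      several.ok = TRUE)
  bad <- setdiff(combinations, signal_combinations)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown signal combination: %s",
                         paste(bad, collapse = ", ")))
  }
  results <- list()
  confusion <- list()
  breakdown_rows <- list()
  for (m in models) {
    for (comb in combinations) {
      sub <- select_channels(segset, comb)
      cv <- cross_validate_model(m, sub, config, ...)
      key <- paste(m, comb, sep = " | ")
      confusion[[key]] <- cv$confusion
      results[[key]] <- dplyr::mutate(cv$folds, model = m, combination = comb,
                                      n_params = cv$n_params, .before = 1)
      for (brk in breakdowns) {
        vals <- sort(unique(sub$provenance[[if (brk == "scenario") "scenario"
                                            else "difficulty"]]))
        for (v in vals) {
          keep <- which(sub$provenance[[if (brk == "scenario") "scenario"
                                        else "difficulty"]] == v)
          bs <- sub
          bs$segments <- sub$segments[keep, , , drop = FALSE]
          bs$labels <- sub$labels[keep]
          bs$provenance <- sub$provenance[keep, ]
          bm <- if (subset_mode == "retrain") {
            bcv <- cross_validate_model(m, bs, config, ...)
            list(accuracy = mean(bcv$folds$accuracy), f1 = mean(bcv$folds$f1))
          } else {
            slice_metrics(m, sub, keep, config, ...)
          }
          breakdown_rows[[length(breakdown_rows) + 1]] <-
            tibble(model = m, combination = comb, breakdown = brk,
                   level = as.character(v), accuracy = bm$accuracy,
                   f1 = bm$f1)
        }
      }
    }
  }
  results <- dplyr::bind_rows(results)
  summary <- results |>
    dplyr::group_by(.data$model, .data$combination) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), f1 = mean(.data$f1),
                     n_params = .data$n_params[1], .groups = "drop")
  structure(list(results = results, summary = summary, confusion = confusion,
                 breakdown = if (length(breakdown_rows) > 0)
                   dplyr::bind_rows(breakdown_rows) else NULL,
                 config = config),
            class = "stress_eval")
}

# Slice mode: one global CV, metrics computed on the subset's validation
# predictions only.
slice_metrics <- function(model_name, segset, keep, config,
                          transform = transform_spec(), ...) {
  labels <- segset$labels
  folds <- stratified_folds(labels, k = config$k_folds, seed = config$seed)
  accs <- c(); f1s <- c()
  for (f in seq_along(folds)) {
    val_idx <- intersect(folds[[f]], keep)
    if (length(val_idx) == 0) next
    train_idx <- setdiff(seq_along(labels), folds[[f]])
    fold_seed <- derive_seed(config$seed, "fold", model_name, f)
    fold_cfg <- config; fold_cfg$seed <- fold_seed
    spec <- model_spec(model_name, in_channels = length(segset$channel_map), ...)
    model <- if (model_name == "sscnn") {
      pretrain_then_classify(segset$segments, labels, train_idx,
                             folds[[f]], spec, fold_cfg)$classifier_fit$model
    } else {
      mm <- build_model(spec, seed = fold_seed)
      train_model(mm, segset$segments, labels, train_idx, folds[[f]],
                  fold_cfg)$model
    }
    pred <- predict(model, segset$segments[val_idx, , , drop = FALSE],
                    type = "class")
    accs <- c(accs, accuracy(pred, labels[val_idx]))
    f1s <- c(f1s, precision_recall_f1(pred, labels[val_idx], levels = 0:2)$f1)
  }
  list(accuracy = mean(accs), f1 = mean(f1s))
}

#' @export
print.stress_eval <- function(x, ...) {
  cat("<stress_eval> ", nrow(x$summary), " model x combination cells, k = ",
      x$config$k_folds, " folds\n", sep = "")
  print(x$summary, n = 25)
  invisible(x)
}

#' Scenario-to-scenario self-report stress changes
#'
#' For each ordered scenario pair, counts the participants whose
#' self-report score increased, decreased or held, split by puzzle
#' difficulty group (plus an `"all"` row). Requires one score per
#' participant per scenario.
#'
#' @param manifest A cohort manifest (see [generate_cohort()]) or scores
#'   tibble with `participant_id`, `scenario`, `difficulty`, `score`.
#' @return A tibble with columns `comparison`, `difficulty`, `increased`,
#'   `decreased`, `unchanged`, `n`.
#' @export
#' @examples
#' selfreport_summary(sample_scores(cohort_spec(), seed = 1))
selfreport_summary <- function(manifest) {
  need <- c("participant_id", "scenario", "difficulty", "score")
  assert_that(all(need %in% names(manifest)),
              sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  dup <- manifest |>
    dplyr::count(.data$participant_id, .data$scenario) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(dup) == 0, "need exactly one score per participant per scenario")
  wide <- manifest |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "score",
                       names_prefix = "s")
  scen <- sort(unique(manifest$scenario))
  pairs <- utils::combn(scen, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- wide[[paste0("s", pr[1])]]
    b <- wide[[paste0("s", pr[2])]]
    d <- b - a
    for (g in c("all", unique(wide$difficulty))) {
      sel <- if (g == "all") rep(TRUE, nrow(wide)) else wide$difficulty == g
      rows[[length(rows) + 1]] <- tibble(
        comparison = sprintf("scenario %d vs %d", pr[2], pr[1]),
        difficulty = g,
        increased = sum(d[sel] > 0),
        decreased = sum(d[sel] < 0),
        unchanged = sum(d[sel] == 0),
        n = sum(sel))
    }
  }
  dplyr::bind_rows(rows)
}
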