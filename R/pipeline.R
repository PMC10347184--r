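# One-call orchestration: synthesize -> preprocess -> (pretrain) -> train ->
# evaluate, with a single seed fanning out to stage seeds.

#' Pipeline configuration
#'
#' Bundles the stage configurations with their protocol defaults: the
#' 230,400-sample / 256 Hz grid, the per-modality band-passes (PPG 0.5-5,
#' ECG 5-15, EEG 0.1-15 Hz), 10 s windows, the pretext transformation
#' parameters, and the training protocol (k = 3, Adam 0.001, 300/150
#' epochs).
#'
#' @param cohort A [cohort_spec()].
#' @param modalities Modalities to synthesize and preprocess.
#' @param combinations Signal combinations to evaluate.
#' @param models Model names to evaluate.
#' @param train A [train_config()].
#' @param transform A [transform_spec()].
#' @param target_len,rate,window_s Preprocessing grid parameters.
#' @param filters Named list of [filter_spec()]s.
#' @param seed Global seed; stage seeds are derived from it.
#' @param ... Width knobs forwarded to [evaluate_suite()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       modalities = c("ppg", "ecg", "eeg"),
                       combinations = signal_combinations,
                       models = c("stressnext", "lrcn", "sscnn"),
                       train = train_config(),
                       transform = transform_spec(),
                       target_len = 230400L,
                       rate = 256,
                       window_s = 10,
                       filters = list(ppg = filter_spec("ppg"),
                                      ecg = filter_spec("ecg"),
                                      eeg = filter_spec("eeg")),
                       seed = 1L,
                       ...) {
  for (f in filters) {
    if (f$high >= rate / 2) {
      rlang::abort(sprintf(
        "filter %s high cut %.3g Hz is not below the working Nyquist %.3g Hz",
        f$modality, f$high, rate / 2))
    }
  }
  structure(list(cohort = cohort, modalities = modalities,
                 combinations = combinations, models = models,
                 train = train, transform = transform,
                 target_len = as.integer(target_len), rate = rate,
                 window_s = window_s, filters = filters,
                 seed = as.integer(seed), model_knobs = list(...)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes synthesis, preprocessing and evaluation in order and returns
#' every artifact. Stage timings and data shapes are reported via messages.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `segments` (a `segment_set`), `eval`
#'   (a `stress_eval`), `selfreport` (scenario change table) and the
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    rlang::inform(sprintf("[%s] done in %.1f s", name,
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  cohort <- stage("synth", generate_cohort(config$cohort,
                                           seed = derive_seed(config$seed, "synth"),
                                           modalities = config$modalities))
  segset <- stage("preprocess", build_segment_set(
    cohort, modalities = config$modalities, target_len = config$target_len,
    rate = config$rate, window_s = config$window_s, filters = config$filters))
  train_cfg <- config$train
  train_cfg$seed <- derive_seed(config$seed, "train")
  ev <- stage("evaluate", do.call(evaluate_suite, c(
    list(segset = segset, models = config$models,
         combinations = config$combinations, config = train_cfg,
         transform = config$transform),
    config$model_knobs)))
  list(cohort = cohort,
       segments = segset,
       eval = ev,
       selfreport = selfreport_summary(cohort$manifest),
       config = config)
}
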