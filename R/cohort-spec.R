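#' Cohort specification for synthetic study generation
#'
#' Describes a simulated study cohort: participants split into a
#' medium-difficulty and a hard-difficulty puzzle group, each completing one
#' recording session per scenario while wearing three devices (a 3-channel
#' PPG sensor at 55 Hz, a single-lead ECG at 512 Hz and a single-channel EEG
#' headset at 512 Hz). Defaults mirror the study design the package
#' emulates: 30 participants (15 medium / 15 hard), 3 scenarios, 15-minute
#' nominal sessions.
#'
#' Class-dependent physiology is controlled by three per-class vectors
#' (index 1 = relaxed, 2 = medium stress, 3 = high stress): mean heart rate
#' must be strictly increasing with stress, the RR-interval jitter
#' (heart-rate variability) and the EEG alpha/beta power ratio strictly
#' decreasing — the classical stress signatures the classifiers are expected
#' to find.
#'
#' @param n_participants Total number of participants.
#' @param n_medium,n_hard Participants assigned medium / hard puzzles;
#'   must sum to `n_participants`.
#' @param scenarios Ordered scenario identifiers.
#' @param session_minutes Nominal session duration in minutes.
#' @param rates Named sampling rates in Hz for the three modalities.
#' @param hr_by_class Mean heart rate (bpm) per stress class, strictly
#'   increasing.
#' @param rr_jitter_by_class RR-interval standard deviation (s) per class,
#'   strictly decreasing (stress lowers heart-rate variability).
#' @param alpha_beta_by_class EEG alpha/beta band-power ratio per class,
#'   strictly decreasing (stress suppresses alpha relative to beta).
#' @param score_mode `"skewed"` (heavily skewed towards the relaxed
#'   class, as observed in the study) or `"balanced"` (approximately equal
#'   classes, useful for model-recovery experiments).
#' @param early_finish_frac Fraction of sessions truncated below the nominal
#'   duration, emulating participants finishing the puzzles early.
#' @param seed Default RNG seed used by generation functions.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [sample_scores()]
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 4, n_medium = 2, n_hard = 2,
#'                     session_minutes = 1)
#' spec
cohort_spec <- function(n_participants = 30L,
                        n_medium = 15L,
                        n_hard = 15L,
                        scenarios = 1:3,
                        session_minutes = 15,
                        rates = c(ppg = 55, ecg = 512, eeg = 512),
                        hr_by_class = c(62, 74, 86),
                        rr_jitter_by_class = c(0.05, 0.035, 0.02),
                        alpha_beta_by_class = c(1.6, 1.1, 0.7),
                        score_mode = c("skewed", "balanced"),
                        early_finish_frac = 0.1,
                        seed = 1L) {
  score_mode <- match.arg(score_mode)
  assert_that(is_count(n_participants), "n_participants must be a positive integer")
  assert_that(n_participants == n_medium + n_hard,
              "n_participants must equal n_medium + n_hard")
  assert_that(is_number(session_minutes) && session_minutes > 0,
              "session_minutes must be > 0")
  assert_that(all(c("ppg", "ecg", "eeg") %in% names(rates)),
              "rates must name ppg, ecg and eeg")
  assert_that(all(rates > 0), "all sampling rates must be > 0")
  assert_that(length(hr_by_class) == 3 && all(diff(hr_by_class) > 0),
              "hr_by_class must be strictly increasing over the 3 classes")
  assert_that(length(rr_jitter_by_class) == 3 && all(diff(rr_jitter_by_class) < 0),
              "rr_jitter_by_class must be strictly decreasing")
  assert_that(length(alpha_beta_by_class) == 3 && all(diff(alpha_beta_by_class) < 0),
              "alpha_beta_by_class must be strictly decreasing")
  assert_that(is_number(early_finish_frac) && early_finish_frac >= 0 &&
                early_finish_frac <= 1, "early_finish_frac must be in [0,1]")
  structure(
    list(n_participants = as.integer(n_participants),
         n_medium = as.integer(n_medium),
         n_hard = as.integer(n_hard),
         scenarios = as.integer(scenarios),
         session_minutes = session_minutes,
         rates = rates,
         hr_by_class = hr_by_class,
         rr_jitter_by_class = rr_jitter_by_class,
         alpha_beta_by_class = alpha_beta_by_class,
         score_mode = score_mode,
         early_finish_frac = early_finish_frac,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_participants, " participants (",
      x$n_medium, " medium / ", x$n_hard, " hard), scenarios ",
      paste(x$scenarios, collapse = ","), ", ", x$session_minutes,
      " min sessions\n", sep = "")
  cat("  rates: PPG ", x$rates[["ppg"]], " Hz (3 ch), ECG ",
      x$rates[["ecg"]], " Hz, EEG ", x$rates[["eeg"]], " Hz; score mode: ",
      x$score_mode, "\n", sep = "")
  invisible(x)
}

# Per-scenario, per-difficulty stress-class probabilities (classes 0/1/2).
# The skewed tables are calibrated so that (i) averaged over scenarios
# and difficulty groups the class mix approaches the 74.4/21.1/4.4 percent
# split observed over 8100 segments, (ii) expected scores fall from the
# noisy scenario 1 to the comforting scenario 3, and (iii) the hard-puzzle
# group is more stressed than the medium group in scenario 1.
class_prob_table <- function(mode) {
  if (mode == "balanced") {
    p <- rep(1 / 3, 3)
    return(list(medium = list(`1` = p, `2` = p, `3` = p),
                hard   = list(`1` = p, `2` = p, `3` = p)))
  }
  list(
    medium = list(`1` = c(0.65, 0.29, 0.06),
                  `2` = c(0.75, 0.21, 0.04),
                  `3` = c(0.88, 0.105, 0.015)),
    hard   = list(`1` = c(0.55, 0.35, 0.10),
                  `2` = c(0.75, 0.21, 0.04),
                  `3` = c(0.88, 0.105, 0.015)))
}

# Within-class self-report score distributions on the 0-8 scale.
score_within_class <- list(
  list(values = 0:4, prob = c(0.30, 0.25, 0.20, 0.15, 0.10)),
  list(values = 5:7, prob = c(0.45, 0.35, 0.20)),
  list(values = 8L, prob = 1))

#' Sample per-session self-report stress scores
#'
#' Draws one questionnaire score (0-8) per participant and scenario. In
#' `"skewed"` mode the resulting stress-class mix is heavily skewed
#' towards the relaxed class and ordered across scenarios (noisy scenario 1
#' most stressful, comforting scenario 3 least); in `"balanced"` mode the
#' three classes are equiprobable.
#'
#' @param spec A [cohort_spec()].
#' @param mode Score mode; defaults to the spec's `score_mode`.
#' @param seed RNG seed; defaults to the spec's seed.
#' @return A tibble with one row per (participant, scenario):
#'   `participant_id`, `difficulty`, `scenario`, `score`, `class`.
#' @export
#' @examples
#' scores <- sample_scores(cohort_spec(), seed = 7)
#' table(scores$class)
sample_scores <- function(spec, mode = spec$score_mode, seed = spec$seed) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  if (!mode %in% c("skewed", "balanced")) {
    rlang::abort(sprintf("unknown score mode '%s' (use 'skewed' or 'balanced')", mode))
  }
  tab <- class_prob_table(mode)
  difficulty <- rep(c("medium", "hard"), c(spec$n_medium, spec$n_hard))
  with_seed(derive_seed(seed, "scores"), {
    rows <- purrr::map(seq_len(spec$n_participants), function(p) {
      purrr::map(spec$scenarios, function(sc) {
        pr <- tab[[difficulty[p]]][[as.character(sc)]]
        cls <- sample(0:2, 1, prob = pr)
        swc <- score_within_class[[cls + 1]]
        tibble(participant_id = p, difficulty = difficulty[p], scenario = sc,
               score = as.integer(sample(rep(swc$values, 2), 1,
                                         prob = rep(swc$prob, 2) / 2)),
               class = as.integer(cls))
      })
    })
    dplyr::bind_rows(rows)
  })
}
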