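#' Generate a synthetic study cohort
#'
#' Produces one raw multi-device recording per participant and scenario:
#' self-report scores are drawn first ([sample_scores()]), each session's
#' stress class then sets the cardiac and cortical parameters (heart rate
#' up, RR jitter and alpha/beta ratio down with stress, plus a stable
#' per-participant offset so physiology is strictly monotone in class
#' within a participant), and the three device streams are synthesized at
#' their native rates. A configurable fraction of sessions is truncated
#' below the nominal duration, emulating participants who finish early.
#'
#' All randomness derives from a single seed through per-session child
#' seeds, so any single session can be regenerated in isolation and the
#' whole cohort is byte-reproducible.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to the spec's seed.
#' @param modalities Modalities to synthesize (subset of
#'   `c("ppg", "ecg", "eeg")`). ECG is always generated when PPG is
#'   requested, because the PPG pulse train is phase-locked to the ECG beat
#'   process.
#' @param dir Optional directory: when given, each session is written to
#'   disk as plain-text CSV files (see [write_session()]) and dropped from
#'   memory; otherwise sessions are returned in the `sessions` element.
#' @return An object of class `stress_cohort`: a list with `manifest`
#'   (tibble of session metadata), `sessions` (list of `raw_session`
#'   objects, or `NULL` when `dir` is used), `spec` and `seed`.
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 2, n_medium = 1, n_hard = 1,
#'                     session_minutes = 0.5)
#' coh <- generate_cohort(spec, seed = 1, modalities = "ecg")
#' coh$manifest
generate_cohort <- function(spec, seed = spec$seed,
                            modalities = c("ppg", "ecg", "eeg"),
                            dir = NULL) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  modalities <- match.arg(modalities, c("ppg", "ecg", "eeg"), several.ok = TRUE)
  scores <- sample_scores(spec, seed = seed)
  n_sess <- nrow(scores)
  nominal_s <- spec$session_minutes * 60

  # Participant-level stable physiology offsets and session durations.
  offs <- with_seed(derive_seed(seed, "participants"), {
    list(hr = rnorm(spec$n_participants, 0, 2),
         ratio = exp(rnorm(spec$n_participants, 0, 0.05)))
  })
  durations <- with_seed(derive_seed(seed, "durations"), {
    d <- rep(nominal_s, n_sess)
    n_early <- round(spec$early_finish_frac * n_sess)
    if (n_early > 0) {
      early <- sample(n_sess, n_early)
      d[early] <- round(runif(n_early, 0.6, 0.95) * nominal_s)
    }
    d
  })

  sessions <- vector("list", n_sess)
  paths <- rep(NA_character_, n_sess)
  for (i in seq_len(n_sess)) {
    row <- scores[i, ]
    cls <- row$class
    profile <- list(
      score = row$score, class = cls,
      hr_bpm = spec$hr_by_class[cls + 1] + offs$hr[row$participant_id],
      rr_jitter = spec$rr_jitter_by_class[cls + 1],
      alpha_beta = spec$alpha_beta_by_class[cls + 1] * offs$ratio[row$participant_id])
    s <- synth_session(profile, row, durations[i], spec$rates, modalities,
                       seed = derive_seed(seed, "session", row$participant_id,
                                          row$scenario))
    if (!is.null(dir)) {
      paths[i] <- write_session(s, dir)
    } else {
      sessions[[i]] <- s
    }
  }

  manifest <- dplyr::mutate(scores,
                            duration_s = durations,
                            nominal_s = nominal_s,
                            ppg_rate = spec$rates[["ppg"]],
                            ecg_rate = spec$rates[["ecg"]],
                            eeg_rate = spec$rates[["eeg"]],
                            path = paths)
  structure(list(manifest = manifest,
                 sessions = if (is.null(dir)) sessions else NULL,
                 modalities = modalities, spec = spec, seed = seed),
            class = "stress_cohort")
}

# Build one raw_session from a stress profile and a scores row.
synth_session <- function(profile, row, duration_s, rates, modalities, seed) {
  need_ecg <- any(c("ecg", "ppg") %in% modalities)
  ecg <- NULL
  beats <- numeric(0)
  if (need_ecg) {
    ecg <- synth_ecg(profile$hr_bpm, duration_s, rates[["ecg"]],
                     rr_jitter = profile$rr_jitter, seed = seed)
    beats <- attr(ecg, "beat_times")
    attr(ecg, "beat_times") <- NULL
  }
  out <- list(participant_id = row$participant_id,
              scenario = row$scenario,
              difficulty = row$difficulty,
              score = row$score,
              class = row$class,
              duration_s = duration_s,
              rates = rates)
  if ("ecg" %in% modalities) out$ecg <- ecg
  if ("ppg" %in% modalities) {
    out$ppg <- synth_ppg(beats, duration_s, rates[["ppg"]], seed = seed)
  }
  if ("eeg" %in% modalities) {
    out$eeg <- synth_eeg(duration_s, rates[["eeg"]],
                         alpha_beta_ratio = profile$alpha_beta, seed = seed)
  }
  structure(out, class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  mods <- intersect(c("ppg", "ecg", "eeg"), names(x))
  cat("<raw_session> participant ", x$participant_id, ", scenario ",
      x$scenario, " (", x$difficulty, "), score ", x$score, " -> class ",
      x$class, ", ", round(x$duration_s), " s [",
      paste(mods, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
print.stress_cohort <- function(x, ...) {
  cat("<stress_cohort> ", nrow(x$manifest), " sessions, modalities: ",
      paste(x$modalities, collapse = ", "),
      if (is.null(x$sessions)) " (on disk)" else " (in memory)", "\n", sep = "")
  print(utils::head(x$manifest, 4))
  invisible(x)
}
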