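# Synthetic cohort generator: score sampling, waveform structure,
# determinism and the class-monotone physiology contract.

test_that("cohort_spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_participants = 10, n_medium = 4, n_hard = 5),
               "n_medium")
  expect_error(cohort_spec(session_minutes = 0), "session_minutes")
  expect_error(cohort_spec(hr_by_class = c(80, 70, 90)), "increasing")
})

test_that("sampled scores are in range with one row per participant-scenario", {
  scores <- sample_scores(cohort_spec(), seed = 7)
  expect_equal(nrow(scores), 90)
  expect_true(all(scores$score >= 0 & scores$score <= 8))
  expect_equal(scores$class, score_to_class(scores$score))
  expect_error(sample_scores(cohort_spec(), mode = "bogus"), "unknown score mode")
})

test_that("skewed mode reproduces the observed class skew at large n", {
  spec <- cohort_spec(n_participants = 300, n_medium = 150, n_hard = 150)
  scores <- sample_scores(spec, mode = "skewed", seed = 11)
  props <- tabulate(factor(scores$class, 0:2), 3) / nrow(scores)
  # reference proportions 6030/8100, 1710/8100, 360/8100
  target <- c(6030, 1710, 360) / 8100
  expect_true(all(abs(props - target) < 0.05))
  # scenario ordering of mean scores: noisy (1) >= observed (2) >= comforting (3)
  ms <- tapply(scores$score, scores$scenario, mean)
  expect_true(ms[1] >= ms[2] && ms[2] >= ms[3])
  # hard group more stressed than medium in scenario 1
  s1 <- scores[scores$scenario == 1, ]
  expect_gte(mean(s1$score[s1$difficulty == "hard"]),
             mean(s1$score[s1$difficulty == "medium"]))
})

test_that("balanced mode yields near-equal class frequencies", {
  spec <- cohort_spec(n_participants = 300, n_medium = 150, n_hard = 150)
  scores <- sample_scores(spec, mode = "balanced", seed = 13)
  props <- tabulate(factor(scores$class, 0:2), 3) / nrow(scores)
  expect_true(all(props > 0.28 & props < 0.39))
})

test_that("synthetic ECG has the right length and beat structure", {
  ecg <- synth_ecg(60, duration_s = 10, rate = 512, rr_jitter = 0.02,
                   noise_sd = 0, wander_amp = 0, seed = 5)
  expect_length(ecg, 5120)
  # peak-counting oracle on the clean template
  expect_true(abs(count_peaks(as.numeric(ecg), 512) - 10) <= 1)
  expect_true(abs(length(attr(ecg, "beat_times")) - 10) <= 1)
  # doubling heart rate halves the mean RR interval
  rr60 <- mean(diff(attr(synth_ecg(60, 60, 512, seed = 8), "beat_times")))
  rr120 <- mean(diff(attr(synth_ecg(120, 60, 512, seed = 8), "beat_times")))
  expect_true(abs(rr120 / rr60 - 0.5) < 0.05)
  expect_error(synth_ecg(60, duration_s = 0, rate = 512), "duration")
  # dominant spectral energy at the beat frequency
  clean <- synth_ecg(72, 60, 256, rr_jitter = 0.005, noise_sd = 0,
                     wander_amp = 0, seed = 2)
  p <- Mod(fft(as.numeric(clean) - mean(clean)))^2
  f <- (seq_along(p) - 1) * 256 / length(p)
  # fundamental spectral line sits at the beat frequency (72 bpm = 1.2 Hz);
  # the spiky PQRST shape also puts energy at its harmonics
  sel <- f > 0.3 & f < 2
  fpeak <- f[sel][which.max(p[sel])]
  expect_true(abs(fpeak - 1.2) < 0.1)
  harmonics <- outer(f[sel][which.max(p[sel])], 1:4)
  line_power <- sum(vapply(harmonics, function(h) max(p[abs(f - h) < 0.05]), 0))
  expect_gt(line_power / sum(p[f > 0.3 & f < 10]), 0.3)
})

test_that("synthetic PPG is phase-locked to the beat process", {
  ecg <- synth_ecg(70, 20, 512, rr_jitter = 0.01, noise_sd = 0, seed = 3)
  beats <- attr(ecg, "beat_times")
  ppg <- synth_ppg(beats, 20, 55, noise_sd = 0, seed = 3)
  expect_equal(dim(ppg), c(20 * 55, 3))
  expect_equal(colnames(ppg), c("PPG1", "PPG2", "PPG3"))
  # noise-free channels are essentially perfectly correlated
  cors <- cor(ppg)
  expect_true(all(cors[upper.tri(cors)] >= 0.99))
  # one pulse per beat (count on the clean dominant channel)
  expect_true(abs(count_peaks(ppg[, 1], 55, refractory_s = 0.4) -
                    length(beats)) <= 1)
  expect_warning(flat <- synth_ppg(numeric(0), 5, 55, seed = 1), "flat-line")
  expect_true(all(flat == 0))
})

test_that("synthetic EEG carries the alpha/beta class signature over 1/f background", {
  hi <- synth_eeg(30, 512, alpha_beta_ratio = 1.6, seed = 21)
  lo <- synth_eeg(30, 512, alpha_beta_ratio = 0.7, seed = 21)
  expect_length(hi, 30 * 512)
  ratio_of <- function(x) band_power(x, 512, c(8, 12)) / band_power(x, 512, c(13, 30))
  # beta/alpha strictly greater for the stressed (low-ratio) profile
  expect_gt(1 / ratio_of(lo), 1 / ratio_of(hi))
  # with oscillations off the spectrum is 1/f: log-log power slope near -1
  bg <- synth_eeg(60, 256, osc_amp = 0, seed = 22)
  p <- Mod(fft(bg - mean(bg)))^2 / length(bg)
  f <- (seq_along(p) - 1) * 256 / length(p)
  sel <- f >= 1 & f <= 50
  fit <- stats::lm(log(p[sel]) ~ log(f[sel]))
  expect_true(abs(unname(stats::coef(fit)[2]) + 1) < 0.3)
})

test_that("generate_cohort honours the study structure and is deterministic", {
  spec <- cohort_spec(session_minutes = 0.25)
  coh <- generate_cohort(spec, seed = 31, modalities = "ecg")
  expect_equal(nrow(coh$manifest), 90)
  expect_equal(unname(table(coh$manifest$difficulty)[c("medium", "hard")] / 3),
               c(15, 15), ignore_attr = TRUE)
  # one difficulty per participant across scenarios
  per_part <- tapply(coh$manifest$difficulty, coh$manifest$participant_id,
                     function(d) length(unique(d)))
  expect_true(all(per_part == 1))
  # early finishes truncate but never extend
  expect_true(all(coh$manifest$duration_s <= coh$manifest$nominal_s))
  expect_equal(sum(coh$manifest$duration_s < coh$manifest$nominal_s), 9)
  # byte-identical regeneration from the same seed
  coh2 <- generate_cohort(spec, seed = 31, modalities = "ecg")
  expect_identical(coh$sessions, coh2$sessions)
  expect_identical(coh$manifest, coh2$manifest)
  # sample counts match round(duration x rate)
  lens <- vapply(coh$sessions, function(s) length(s$ecg), 0)
  expect_equal(lens, round(coh$manifest$duration_s * 512))
})

test_that("physiology is strictly monotone in stress class within a participant", {
  spec <- cohort_spec(n_participants = 2, n_medium = 1, n_hard = 1,
                      session_minutes = 0.5, early_finish_frac = 0)
  # force one participant through all three classes via a custom score table
  scores <- sample_scores(spec, seed = 1)
  profs <- lapply(0:2, function(cl) {
    ecg <- synth_ecg(spec$hr_by_class[cl + 1], 60, 512,
                     rr_jitter = spec$rr_jitter_by_class[cl + 1],
                     noise_sd = 0, wander_amp = 0, seed = 50 + cl)
    eeg <- synth_eeg(60, 512, alpha_beta_ratio = spec$alpha_beta_by_class[cl + 1],
                     seed = 50 + cl)
    beats <- attr(ecg, "beat_times")
    list(hr = 60 / mean(diff(beats)),
         ab = band_power(eeg, 512, c(8, 12)) / band_power(eeg, 512, c(13, 30)))
  })
  hrs <- vapply(profs, `[[`, 0, "hr")
  abs_ <- vapply(profs, `[[`, 0, "ab")
  expect_true(all(diff(hrs) > 0))
  expect_true(all(diff(abs_) < 0))
})
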