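# Synthetic biosignal generators. Waveform families are deliberately simple
# parametric models whose only job is to carry the class-dependent structure
# (heart rate, heart-rate variability, EEG alpha/beta balance) that the
# downstream classifiers must recover.

# Gaussian bump helper: adds amp * exp(-(t-mu)^2 / (2 w^2)) to x on grid tt,
# touching only samples within +-4w of mu.
add_bump <- function(x, tt, rate, mu, w, amp) {
  i0 <- max(1L, floor((mu - 4 * w) * rate) + 1L)
  i1 <- min(length(x), ceiling((mu + 4 * w) * rate) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  x[idx] <- x[idx] + amp * exp(-((tt[idx] - mu)^2) / (2 * w^2))
  x
}

# PQRST template: (offset s, width s, amplitude) per deflection.
ecg_template <- rbind(
  P = c(-0.200, 0.035, 0.12),
  Q = c(-0.028, 0.012, -0.12),
  R = c(0.000, 0.014, 1.00),
  S = c(0.030, 0.013, -0.18),
  T = c(0.220, 0.055, 0.28))

#' Synthesize a single-lead ECG trace
#'
#' Beats follow a stochastic RR-interval process (mean `60/hr_bpm` seconds,
#' Gaussian jitter `rr_jitter`); each beat stamps a PQRST template of
#' Gaussian deflections onto the time grid. Baseline wander (a slow
#' respiratory-band oscillation) and white measurement noise are added on
#' top, so the dominant spectral energy sits at the beat frequency.
#'
#' @param hr_bpm Mean heart rate in beats per minute.
#' @param duration_s Duration in seconds (> 0).
#' @param rate Sampling rate in Hz (>= 100).
#' @param rr_jitter Standard deviation of the RR intervals in seconds.
#' @param noise_sd White-noise standard deviation (template R peak = 1).
#' @param wander_amp Baseline-wander amplitude.
#' @param seed RNG seed.
#' @return Numeric vector of `round(duration_s * rate)` samples with the
#'   beat times (s) attached as attribute `"beat_times"`.
#' @export
#' @examples
#' ecg <- synth_ecg(60, duration_s = 10, rate = 512, seed = 1)
#' length(ecg)
#' head(attr(ecg, "beat_times"))
synth_ecg <- function(hr_bpm, duration_s, rate,
                      rr_jitter = 0.04, noise_sd = 0.05,
                      wander_amp = 0.1, seed = 1L) {
  assert_that(is_number(duration_s) && duration_s > 0, "duration_s must be > 0")
  assert_that(is_number(rate) && rate >= 100, "ECG rate must be >= 100 Hz")
  assert_that(is_number(hr_bpm) && hr_bpm > 0, "hr_bpm must be > 0")
  n <- round(duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  with_seed(derive_seed(seed, "ecg"), {
    rr_mean <- 60 / hr_bpm
    n_beats <- ceiling(duration_s / rr_mean) + 3L
    rr <- pmax(0.3, rnorm(n_beats, rr_mean, rr_jitter))
    beats <- runif(1, 0.2, 0.2 + rr_mean) + cumsum(c(0, rr[-n_beats]))
    beats <- beats[beats < duration_s]
    x <- numeric(n)
    for (b in beats) {
      for (k in seq_len(nrow(ecg_template))) {
        x <- add_bump(x, tt, rate, b + ecg_template[k, 1],
                      ecg_template[k, 2], ecg_template[k, 3])
      }
    }
    if (wander_amp > 0) {
      x <- x + wander_amp * sin(2 * pi * 0.25 * tt + runif(1, 0, 2 * pi))
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    attr(x, "beat_times") <- beats
    x
  })
}

#' Synthesize a 3-channel PPG trace phase-locked to an ECG beat process
#'
#' Each cardiac beat produces one blood-volume pulse: a systolic peak and a
#' smaller diastolic (dicrotic) hump, modelled as two Gaussians, delayed
#' from the electrical beat by a fixed pulse-transit offset. The three
#' optical channels (green, red, infrared) are amplitude-scaled copies of
#' the same pulse wave with independent sensor noise, so they are strongly
#' mutually correlated in the noise-free limit.
#'
#' @param beat_times Beat times in seconds, from the same session's ECG
#'   process (see [synth_ecg()]).
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param ptt Pulse-transit offset from the R peak in seconds.
#' @param channel_amp Length-3 per-channel amplitude scaling.
#' @param noise_sd Per-channel white-noise standard deviation.
#' @param seed RNG seed.
#' @return Numeric matrix `[n x 3]`, columns `PPG1`, `PPG2`, `PPG3`
#'   (green, red, infrared).
#' @export
#' @examples
#' ecg <- synth_ecg(70, 10, 512, seed = 2)
#' ppg <- synth_ppg(attr(ecg, "beat_times"), 10, 55, seed = 2)
#' dim(ppg)
synth_ppg <- function(beat_times, duration_s, rate,
                      ptt = 0.25, channel_amp = c(1, 0.8, 0.6),
                      noise_sd = 0.03, seed = 1L) {
  assert_that(is_number(duration_s) && duration_s > 0, "duration_s must be > 0")
  assert_that(is_number(rate) && rate > 0, "rate must be > 0")
  n <- round(duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  if (length(beat_times) == 0) {
    rlang::warn("synth_ppg: empty beat_times; emitting flat-line PPG")
    out <- matrix(0, n, 3)
    colnames(out) <- paste0("PPG", 1:3)
    return(out)
  }
  with_seed(derive_seed(seed, "ppg"), {
    pulse <- numeric(n)
    for (b in beat_times) {
      pulse <- add_bump(pulse, tt, rate, b + ptt, 0.07, 1.0)
      pulse <- add_bump(pulse, tt, rate, b + ptt + 0.18, 0.09, 0.35)
    }
    out <- vapply(1:3, function(ch) {
      channel_amp[ch] * pulse +
        (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    }, numeric(n))
    colnames(out) <- paste0("PPG", 1:3)
    out
  })
}

#' Synthesize a single-channel EEG trace
#'
#' A 1/f-coloured background (power spectral density proportional to 1/f)
#' plus amplitude-modulated alpha-band (10 Hz) and beta-band (20 Hz)
#' oscillations whose band-power ratio is set by `alpha_beta_ratio`. Under
#' stress, alpha power drops relative to beta, so the ratio decreases with
#' the stress class.
#'
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz (>= 64).
#' @param alpha_beta_ratio Target alpha/beta band-power ratio (> 0).
#' @param osc_amp Overall oscillation amplitude; 0 gives a pure 1/f
#'   spectrum.
#' @param background_sd Standard deviation of the 1/f background.
#' @param seed RNG seed.
#' @return Numeric vector of `round(duration_s * rate)` samples.
#' @export
#' @examples
#' eeg <- synth_eeg(10, 512, alpha_beta_ratio = 1.5, seed = 3)
#' length(eeg)
synth_eeg <- function(duration_s, rate, alpha_beta_ratio = 1.3,
                      osc_amp = 0.8, background_sd = 1, seed = 1L) {
  assert_that(is_number(duration_s) && duration_s > 0, "duration_s must be > 0")
  assert_that(is_number(rate) && rate >= 64, "EEG rate must be >= 64 Hz")
  assert_that(is_number(alpha_beta_ratio) && alpha_beta_ratio > 0,
              "alpha_beta_ratio must be > 0")
  n <- round(duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  with_seed(derive_seed(seed, "eeg"), {
    # 1/f background: shape a white spectrum by f^(-1/2) in amplitude.
    white <- rnorm(n)
    spec <- fft(white)
    fidx <- seq_len(n) - 1
    f <- pmin(fidx, n - fidx) * rate / n    # two-sided frequency axis
    shape <- ifelse(f > 0, f^(-0.5), 0)
    bg <- Re(fft(spec * shape, inverse = TRUE)) / n
    bg <- background_sd * bg / stats::sd(bg)
    x <- bg
    if (osc_amp > 0) {
      a_amp <- osc_amp * sqrt(alpha_beta_ratio)
      b_amp <- osc_amp
      env_a <- 1 + 0.3 * sin(2 * pi * 0.10 * tt + runif(1, 0, 2 * pi))
      env_b <- 1 + 0.3 * sin(2 * pi * 0.13 * tt + runif(1, 0, 2 * pi))
      x <- x + a_amp * env_a * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
        b_amp * env_b * sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi))
    }
    x
  })
}

#' Periodogram band power
#'
#' Mean periodogram power of `x` over a frequency band, used to verify the
#' spectral structure of synthesized EEG (alpha 8-12 Hz vs beta 13-30 Hz).
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 frequency band in Hz.
#' @return Mean power in the band.
#' @export
band_power <- function(x, rate, band) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  sel <- f >= band[1] & f <= band[2] & f <= rate / 2
  mean(p[sel])
}
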