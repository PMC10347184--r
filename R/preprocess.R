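# Preprocessing chain: fixed-grid resampling -> zero-phase Butterworth
# band-pass -> 10 s non-overlapping segmentation -> per-segment z-score
# normalization -> per-session class labels broadcast to segments.

# Zero-phase IIR application with odd-reflection edge padding: the filter
# runs forward and backward over the padded signal, which removes both the
# phase distortion and the startup transients a bare forward-backward pass
# leaves at the record edges.
zero_phase <- function(bf, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1L, pad %||% 3L * max(length(bf$b), length(bf$a), 256L))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

#' Resample a signal onto the fixed analysis grid
#'
#' Every recording, regardless of native rate or actual duration, is mapped
#' onto the same fixed-length grid (230,400 samples, i.e. 15 minutes at
#' 256 Hz). Sessions that ended early are time-normalized onto the full
#' grid, which is what guarantees a constant segment count downstream.
#' When decimating, a zero-phase Butterworth low-pass at 90% of the target
#' Nyquist removes energy that would alias; interpolation onto the target
#' grid is by natural cubic spline. A constant input maps to the same
#' constant.
#'
#' @param x Numeric vector (one channel) of at least 2 samples.
#' @param target_len Output length in samples.
#' @return Numeric vector of exactly `target_len` samples.
#' @export
#' @examples
#' length(resample_to_grid(sin(seq(0, 10, length.out = 5000)), 2560))
resample_to_grid <- function(x, target_len = 230400L) {
  n <- length(x)
  if (n == 0) rlang::abort("resample_to_grid: empty input")
  assert_that(n >= 2, "resample_to_grid: need at least 2 samples")
  assert_that(is_count(target_len), "target_len must be a positive integer")
  if (target_len < n) {
    # Anti-alias: keep only frequencies representable on the target grid.
    cutoff <- 0.9 * target_len / n   # relative to input Nyquist
    bf <- signal::butter(8, cutoff, type = "low")
    x <- zero_phase(bf, x)
  }
  s <- stats::spline(x = seq(0, 1, length.out = n), y = x,
                     xout = seq(0, 1, length.out = target_len),
                     method = "natural")
  s$y
}

#' Band-pass filter specification per modality
#'
#' Pass bands follow the analysis protocol: PPG 0.5-5 Hz, ECG 5-15 Hz,
#' EEG 0.1-15 Hz, all applied at the 256 Hz working rate as order-4
#' zero-phase (forward-backward) Butterworth band-passes.
#'
#' @param modality One of `"ppg"`, `"ecg"`, `"eeg"`, or `"custom"`.
#' @param low,high Cut-off frequencies in Hz (required for `"custom"`,
#'   otherwise taken from the modality preset).
#' @param order Butterworth design order.
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("ecg")
filter_spec <- function(modality = c("ppg", "ecg", "eeg", "custom"),
                        low = NULL, high = NULL, order = 4L) {
  modality <- match.arg(modality)
  presets <- list(ppg = c(0.5, 5), ecg = c(5, 15), eeg = c(0.1, 15))
  if (modality != "custom") {
    low <- low %||% presets[[modality]][1]
    high <- high %||% presets[[modality]][2]
  }
  assert_that(is_number(low) && is_number(high) && low > 0 && low < high,
              "need 0 < low < high")
  assert_that(is_count(order), "order must be a positive integer")
  structure(list(modality = modality, low = low, high = high,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s: %.1f-%.1f Hz Butterworth order %d (zero-phase)\n",
              x$modality, x$low, x$high, x$order))
  invisible(x)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the band-pass forward and backward ([signal::filtfilt()]) so the
#' net phase response is zero and waveform morphology is preserved; the
#' effective magnitude response is the squared Butterworth magnitude.
#'
#' @param x Numeric vector or matrix (channels in columns).
#' @param spec A [filter_spec()].
#' @param rate Sampling rate of `x` in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, spec, rate = 256) {
  assert_that(inherits(spec, "filter_spec"), "spec must be a filter_spec")
  if (spec$high >= rate / 2) {
    rlang::abort(sprintf("high cut %.3g Hz must be below the Nyquist %.3g Hz",
                         spec$high, rate / 2))
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (rate / 2),
                       type = "pass")
  pad <- min(ceiling(3 * rate / spec$low), 30L * rate)
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) zero_phase(bf, col, pad = pad))
    dimnames(out) <- dimnames(x)
    out
  } else {
    zero_phase(bf, x, pad = pad)
  }
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Closed-form squared-magnitude response of the digital order-`order`
#' Butterworth band-pass (bilinear transform with prewarped band edges),
#' raised to the zero-phase (forward-backward) application, i.e. the gain
#' a sinusoid at frequency `f` experiences under [bandpass()].
#'
#' @param f Frequencies in Hz.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate in Hz.
#' @return Gain values in (0, 1].
#' @export
butter_gain <- function(f, spec, rate = 256) {
  w <- tan(pi * f / rate)
  w1 <- tan(pi * spec$low / rate)
  w2 <- tan(pi * spec$high / rate)
  h2 <- 1 / (1 + ((w^2 - w1 * w2) / (w * (w2 - w1)))^(2 * spec$order))
  h2  # |H|^2: filtfilt applies the filter twice
}

#' Split a record into fixed non-overlapping windows
#'
#' @param x Numeric vector or matrix (time in rows, channels in columns).
#' @param window_s Window duration in seconds.
#' @param overlap Overlap fraction (0 = non-overlapping; only 0 is
#'   supported, matching the analysis protocol).
#' @param rate Sampling rate in Hz.
#' @return Array `[n_segments x n_channels x window_len]`; zero segments
#'   (with a warning) when the record is shorter than one window.
#' @export
#' @examples
#' dim(segment_signal(rnorm(230400), 10, rate = 256))
segment_signal <- function(x, window_s = 10, overlap = 0, rate = 256) {
  assert_that(overlap == 0, "only non-overlapping windows are supported")
  wlen <- round(window_s * rate)
  assert_that(wlen >= 1, "window_s x rate must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  nseg <- n %/% wlen
  if (nseg == 0) {
    rlang::warn(sprintf("record of %d samples shorter than one %d-sample window",
                        n, wlen))
    return(array(0, dim = c(0, ncol(x), wlen)))
  }
  used <- x[seq_len(nseg * wlen), , drop = FALSE]
  # [wlen, nseg, C] -> [nseg, C, wlen]
  a <- array(used, dim = c(wlen, nseg, ncol(x)))
  aperm(a, c(2, 3, 1))
}

#' Per-segment, per-channel z-score normalization
#'
#' @param segments Array `[n x C x len]` (or a single `[C x len]` matrix /
#'   length-`len` vector).
#' @return Same shape, each channel of each segment standardized to mean 0
#'   and standard deviation 1. Constant channels are zero-filled with a
#'   warning.
#' @export
normalize_segments <- function(segments) {
  single <- FALSE
  if (is.null(dim(segments))) {
    segments <- array(segments, dim = c(1, 1, length(segments)))
    single <- TRUE
  } else if (length(dim(segments)) == 2) {
    segments <- array(segments, dim = c(1, dim(segments)))
    single <- TRUE
  }
  d <- dim(segments)
  flat <- matrix(aperm(segments, c(3, 1, 2)), nrow = d[3])  # len x (n*C)
  mu <- colMeans(flat)
  sdv <- apply(flat, 2, stats::sd)
  const <- sdv < 1e-12
  if (any(const)) {
    rlang::warn(sprintf("%d constant channel(s) zero-filled during normalization",
                        sum(const)))
    sdv[const] <- 1
    flat[, const] <- matrix(mu[const], d[3], sum(const), byrow = TRUE)
  }
  flat <- (flat - matrix(mu, d[3], length(mu), byrow = TRUE)) /
    matrix(sdv, d[3], length(sdv), byrow = TRUE)
  out <- aperm(array(flat, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  if (single) out <- array(out[1, , ], dim = d[2:3])
  out
}

#' Map a self-report score to a stress class
#'
#' Scores 0-4 indicate relaxation or little stress (class 0), 5-7 medium
#' stress (class 1) and 8 high stress (class 2).
#'
#' @param score Integer vector of questionnaire scores in 0-8.
#' @return Integer vector of classes in `{0, 1, 2}`.
#' @export
#' @examples
#' score_to_class(c(0, 4, 5, 7, 8))
score_to_class <- function(score) {
  assert_that(is.numeric(score) && all(!is.na(score)) &&
                all(score == floor(score)) && all(score >= 0 & score <= 8),
              "scores must be integers in [0, 8]")
  as.integer(ifelse(score <= 4, 0L, ifelse(score <= 7, 1L, 2L)))
}

modality_channels <- list(ppg = paste0("PPG", 1:3), ecg = "ECG", eeg = "EEG")

#' Build the labeled segment set for a cohort
#'
#' Runs the full preprocessing chain per session: each channel of each
#' requested modality is resampled to the fixed 230,400-sample grid,
#' band-pass filtered with its modality's [filter_spec()], the channels are
#' stacked (PPG contributes 3, ECG 1, EEG 1), the record is cut into 10 s
#' windows of 2,560 samples and each window is z-scored per channel. The
#' session's stress class labels all of its 90 segments.
#'
#' @param cohort A `stress_cohort` from [generate_cohort()] (in-memory or
#'   on-disk), or a list of `raw_session` objects.
#' @param modalities Modalities to include, in `c("ppg", "ecg", "eeg")`
#'   order of channel stacking.
#' @param target_len Fixed grid length in samples.
#' @param rate Working rate in Hz after resampling.
#' @param window_s Segment duration in seconds.
#' @param filters Named list of [filter_spec()]s per modality.
#' @return An object of class `segment_set`: list with `segments`
#'   (`[n x C x window]` array), `labels` (integer classes), `provenance`
#'   (tibble: participant, scenario, difficulty, score, segment index),
#'   `channel_map` and `rate`.
#' @export
build_segment_set <- function(cohort,
                              modalities = c("ppg", "ecg", "eeg"),
                              target_len = 230400L,
                              rate = 256,
                              window_s = 10,
                              filters = list(ppg = filter_spec("ppg"),
                                             ecg = filter_spec("ecg"),
                                             eeg = filter_spec("eeg"))) {
  modalities <- intersect(c("ppg", "ecg", "eeg"), modalities)
  assert_that(length(modalities) > 0, "no valid modality requested")
  sessions <- NULL
  manifest <- NULL
  if (inherits(cohort, "stress_cohort")) {
    manifest <- cohort$manifest
    sessions <- cohort$sessions
  } else if (is.list(cohort) && all(vapply(cohort, inherits, TRUE, "raw_session"))) {
    sessions <- cohort
  } else {
    rlang::abort("cohort must be a stress_cohort or a list of raw_session objects")
  }
  n_sess <- if (!is.null(sessions)) length(sessions) else nrow(manifest)
  wlen <- round(window_s * rate)
  seg_per <- target_len %/% wlen
  channel_map <- unlist(modality_channels[modalities], use.names = FALSE)
  C <- length(channel_map)

  segs <- array(NA_real_, dim = c(n_sess * seg_per, C, wlen))
  labels <- integer(n_sess * seg_per)
  prov <- vector("list", n_sess)
  for (i in seq_len(n_sess)) {
    s <- if (!is.null(sessions)) sessions[[i]] else
      read_session_dir(manifest$path[i], modalities = modalities)
    missing <- setdiff(modalities, names(s))
    if (length(missing) > 0) {
      rlang::abort(sprintf(
        "session participant %s scenario %s lacks modality: %s",
        s$participant_id, s$scenario, paste(missing, collapse = ", ")))
    }
    chans <- matrix(0, target_len, C)
    col <- 1L
    for (m in modalities) {
      x <- as.matrix(s[[m]])
      for (j in seq_len(ncol(x))) {
        g <- resample_to_grid(x[, j], target_len)
        chans[, col] <- bandpass(g, filters[[m]], rate)
        col <- col + 1L
      }
    }
    sseg <- segment_signal(chans, window_s = window_s, rate = rate)
    sseg <- normalize_segments(sseg)
    rows <- (i - 1L) * seg_per + seq_len(seg_per)
    segs[rows, , ] <- sseg
    labels[rows] <- s$class
    prov[[i]] <- tibble(participant_id = s$participant_id,
                        scenario = s$scenario,
                        difficulty = s$difficulty,
                        score = s$score,
                        segment = seq_len(seg_per))
  }
  structure(list(segments = segs,
                 labels = labels,
                 provenance = dplyr::bind_rows(prov),
                 channel_map = channel_map,
                 rate = rate,
                 window_s = window_s),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat("<segment_set> ", d[1], " segments x ", d[2], " channels x ", d[3],
      " samples @ ", x$rate, " Hz\n", sep = "")
  cat("  channels: ", paste(x$channel_map, collapse = ", "), "\n", sep = "")
  cat("  classes: ", paste(sprintf("%d:%d", 0:2,
                                   tabulate(factor(x$labels, 0:2), 3)),
                           collapse = "  "), "\n", sep = "")
  invisible(x)
}

# Select channels of a segment_set by signal combination, e.g. "ecg+eeg".
#' Subset a segment set to a signal combination
#'
#' @param segset A `segment_set`.
#' @param combination Signal combination string such as `"ecg"` or
#'   `"ppg+ecg+eeg"`.
#' @return A `segment_set` with only the requested channels.
#' @export
select_channels <- function(segset, combination) {
  mods <- strsplit(tolower(combination), "\\+")[[1]]
  mods <- trimws(mods)
  bad <- setdiff(mods, names(modality_channels))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown signal combination component: %s",
                         paste(bad, collapse = ", ")))
  }
  mods <- intersect(c("ppg", "ecg", "eeg"), mods)
  want <- unlist(modality_channels[mods], use.names = FALSE)
  missing <- setdiff(want, segset$channel_map)
  if (length(missing) > 0) {
    rlang::abort(sprintf("segment set lacks channels: %s",
                         paste(missing, collapse = ", ")))
  }
  idx <- match(want, segset$channel_map)
  out <- segset
  out$segments <- segset$segments[, idx, , drop = FALSE]
  out$channel_map <- want
  out
}
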