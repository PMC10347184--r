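# Plain-text session storage. One directory per session holding ppg.csv
# (t + 3 channels), ecg.csv and eeg.csv (t + 1 channel) plus a meta.txt
# key-value sidecar, emulating the text dumps the acquisition programs of
# the original devices produce.

session_dirname <- function(s) {
  sprintf("p%02d_s%d", s$participant_id, s$scenario)
}

#' Write a raw session to a plain-text directory
#'
#' @param session A `raw_session` (see [generate_cohort()]).
#' @param dir Parent directory; the session is written to a
#'   `p<participant>_s<scenario>` subdirectory.
#' @return The session directory path, invisibly usable in a manifest.
#' @seealso [read_session_dir()]
#' @export
write_session <- function(session, dir) {
  assert_that(inherits(session, "raw_session"), "session must be a raw_session")
  path <- file.path(dir, session_dirname(session))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_channel_csv <- function(x, rate, file, names) {
    x <- as.matrix(x)
    df <- data.frame(t = (seq_len(nrow(x)) - 1) / rate)
    df[names] <- round(x, 6)
    utils::write.csv(df, file.path(path, file), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(session$ppg)) {
    write_channel_csv(session$ppg, session$rates[["ppg"]], "ppg.csv",
                      paste0("PPG", 1:3))
  }
  if (!is.null(session$ecg)) {
    write_channel_csv(session$ecg, session$rates[["ecg"]], "ecg.csv", "ECG")
  }
  if (!is.null(session$eeg)) {
    write_channel_csv(session$eeg, session$rates[["eeg"]], "eeg.csv", "EEG")
  }
  meta <- c(participant = session$participant_id,
            scenario = session$scenario,
            difficulty = session$difficulty,
            score = session$score,
            class = session$class,
            duration_s = session$duration_s,
            ppg_rate = session$rates[["ppg"]],
            ecg_rate = session$rates[["ecg"]],
            eeg_rate = session$rates[["eeg"]])
  writeLines(paste(names(meta), meta, sep = ": "), file.path(path, "meta.txt"))
  path
}

read_meta <- function(file) {
  lines <- readLines(file)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

read_channel_csv <- function(file, expect_cols) {
  if (!file.exists(file)) {
    rlang::abort(sprintf("missing session file: %s", file))
  }
  df <- tryCatch(utils::read.csv(file),
                 error = function(e) rlang::abort(sprintf(
                   "parse error in %s: %s", file, conditionMessage(e))))
  assert_that(all(expect_cols %in% names(df)),
              sprintf("%s lacks columns %s", file,
                      paste(setdiff(expect_cols, names(df)), collapse = ", ")))
  bad <- which(!stats::complete.cases(df[expect_cols]))
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed rows in %s at lines %s", file,
                         paste(utils::head(bad + 1L, 5), collapse = ", ")))
  }
  if (any(diff(df$t) <= 0)) {
    rlang::abort(sprintf("non-monotone timestamps in %s (first at line %d)",
                         file, which(diff(df$t) <= 0)[1] + 2L))
  }
  df
}

#' Read a raw session from its plain-text directory
#'
#' Inverse of [write_session()]: parses the per-device CSV files and the
#' key-value metadata sidecar back into a `raw_session`. Malformed rows and
#' non-monotone timestamps are rejected with the offending file and line.
#'
#' @param path Session directory containing `ppg.csv`, `ecg.csv`,
#'   `eeg.csv` (whichever modalities were recorded) and `meta.txt`.
#' @param modalities Modalities to load; defaults to every channel file
#'   present in the directory.
#' @return A `raw_session`.
#' @export
read_session_dir <- function(path, modalities = NULL) {
  meta_file <- file.path(path, "meta.txt")
  if (!file.exists(meta_file)) {
    rlang::abort(sprintf("missing session file: %s", meta_file))
  }
  meta <- read_meta(meta_file)
  if (is.null(modalities)) {
    modalities <- c("ppg", "ecg", "eeg")[file.exists(file.path(
      path, c("ppg.csv", "ecg.csv", "eeg.csv")))]
  }
  rates <- c(ppg = as.numeric(meta$ppg_rate), ecg = as.numeric(meta$ecg_rate),
             eeg = as.numeric(meta$eeg_rate))
  out <- list(participant_id = as.integer(meta$participant),
              scenario = as.integer(meta$scenario),
              difficulty = meta$difficulty,
              score = as.integer(meta$score),
              class = as.integer(meta$class),
              duration_s = as.numeric(meta$duration_s),
              rates = rates)
  if ("ppg" %in% modalities) {
    df <- read_channel_csv(file.path(path, "ppg.csv"), paste0("PPG", 1:3))
    out$ppg <- as.matrix(df[paste0("PPG", 1:3)])
  }
  if ("ecg" %in% modalities) {
    out$ecg <- read_channel_csv(file.path(path, "ecg.csv"), "ECG")$ECG
  }
  if ("eeg" %in% modalities) {
    out$eeg <- read_channel_csv(file.path(path, "eeg.csv"), "EEG")$EEG
  }
  structure(out, class = "raw_session")
}

#' Write / read a cohort manifest
#'
#' The manifest is the single table every downstream stage consumes: one
#' row per session with participant, scenario, difficulty, self-report
#' score, stress class, durations, native rates and (for on-disk cohorts)
#' the session directory path.
#'
#' @param manifest A manifest tibble (see [generate_cohort()]).
#' @param file CSV file path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(manifest, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
}
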