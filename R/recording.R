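#' Two-channel evoked-EMG recording
#'
#' Container for a synchronized pair of channels: the EMG signal (in
#' microvolts, at the electrode) and the stimulus trigger channel, sampled
#' at a common rate. This is the raw input of the CMAP pipeline.
#'
#' @param emg Numeric vector of EMG samples (uV).
#' @param trigger Numeric vector of trigger-channel samples (arbitrary
#'   units), same length as `emg`.
#' @param fs Sampling rate in Hz (default 2000).
#' @param meta Named list of free-form annotations (subject id, condition
#'   label, amplifier gain, simulator ground truth, ...).
#' @return An object of class `cmap_recording`.
#' @examples
#' rec <- recording(emg = rnorm(100), trigger = rep(0, 100))
#' rec
#' @export
recording <- function(emg, trigger, fs = 2000, meta = list()) {
  emg <- as.numeric(emg)
  trigger <- as.numeric(trigger)
  if (length(emg) < 1L || length(emg) != length(trigger))
    stop("emg and trigger must have identical length >= 1")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  bad <- which(!is.finite(emg) | !is.finite(trigger))
  if (length(bad))
    stop("non-finite sample at index ", bad[1L])
  structure(list(emg = emg, trigger = trigger, fs = fs, meta = meta),
            class = "cmap_recording")
}

#' @export
print.cmap_recording <- function(x, ...) {
  cat(sprintf("Two-channel recording: %d samples at %g Hz (%.3f s)\n",
              length(x$emg), x$fs, length(x$emg) / x$fs))
  if (length(x$meta)) {
    shown <- x$meta[!vapply(x$meta, is.numeric, TRUE) |
                      lengths(x$meta) == 1L]
    if (length(shown))
      cat("meta:", paste(names(shown), unlist(lapply(shown, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Epoch window geometry
#'
#' Defines the trigger-relative segmentation window and the sub-window used
#' for peak-to-peak feature extraction. Times are in milliseconds relative
#' to the trigger; windows are half-open `[start, end)`. The defaults match
#' the usual evoked-EMG protocol: epochs from -5 to 20 ms around each
#' stimulus, with the CMAP peak-to-peak amplitude measured between 1 and
#' 15 ms after stimulus onset.
#'
#' @param pre_ms Duration before the trigger (>= 0), default 5.
#' @param post_ms Duration after the trigger, default 20.
#' @param feature_start_ms Start of the Vpp window after onset, default 1.
#' @param feature_end_ms End of the Vpp window, default 15.
#' @return An object of class `epoch_window`.
#' @export
epoch_window <- function(pre_ms = 5, post_ms = 20,
                         feature_start_ms = 1, feature_end_ms = 15) {
  if (pre_ms < 0) stop("pre_ms must be >= 0")
  if (!(post_ms > feature_end_ms && feature_end_ms > feature_start_ms &&
        feature_start_ms >= 0))
    stop("require post_ms > feature_end_ms > feature_start_ms >= 0")
  structure(list(pre_ms = pre_ms, post_ms = post_ms,
                 feature_start_ms = feature_start_ms,
                 feature_end_ms = feature_end_ms),
            class = "epoch_window")
}

# number of samples before trigger / total epoch length, for a window at fs
.window_samples <- function(window, fs) {
  pre_n <- floor(window$pre_ms * fs / 1000)
  len <- round((window$pre_ms + window$post_ms) * fs / 1000)
  list(pre_n = pre_n, len = len)
}

#' Read a two-channel recording from CSV or EDF
#'
#' The CSV dialect has the header `time_s,emg_uV,trigger`, one row per
#' sample; the sampling rate is inferred from the time column (which must
#' be uniform within 1 ppm) unless `fs` is given. EDF files are matched on
#' channel labels (`"EMG"` and `"TRIG"` by default, case-insensitive).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs Optional sampling rate override (required for CSV files whose
#'   time column is absent or non-uniform).
#' @param emg_channel,trig_channel EDF channel labels (case-insensitive).
#' @param gain Amplifier gain already applied to the stored EMG samples;
#'   samples are divided by it so the returned EMG is in uV at the
#'   electrode. Default 1 (file already at electrode scale).
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL,
                           emg_channel = "EMG", trig_channel = "TRIG",
                           gain = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    rec <- read_edf(path, emg_channel = emg_channel,
                    trig_channel = trig_channel)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("time_s", "emg_uV", "trigger")
    if (!all(need %in% names(df)))
      stop("CSV must have header 'time_s,emg_uV,trigger'; found: ",
           paste(names(df), collapse = ","))
    if (nrow(df) < 1L) stop("empty recording file: ", path)
    bad <- which(!is.finite(df$emg_uV) | !is.finite(df$trigger))
    if (length(bad))
      stop("non-finite sample at row ", bad[1L], " of ", path)
    if (is.null(fs)) {
      dt <- diff(df$time_s)
      if (length(dt) == 0L)
        stop("cannot infer fs from a single row; pass fs explicitly")
      if (any(!is.finite(dt)) || any(abs(dt / dt[1L] - 1) > 1e-6) ||
          dt[1L] <= 0)
        stop("time column not uniform within 1 ppm; pass fs explicitly")
      fs <- 1 / dt[1L]
    }
    rec <- recording(df$emg_uV, df$trigger, fs = fs,
                     meta = list(source = path))
  }
  if (gain != 1) {
    rec$emg <- rec$emg / gain
    rec$meta$gain <- gain
  }
  rec
}

#' Write a two-channel recording to CSV or EDF
#'
#' @param rec A [recording()].
#' @param path Output path; the format is chosen by extension unless
#'   `format` is given.
#' @param format `"auto"`, `"csv"` or `"edf"`. CSV is lossless; EDF stores
#'   16-bit samples (quantized) and pads the recording to whole seconds.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "cmap_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    n <- length(rec$emg)
    df <- data.frame(time_s = (seq_len(n) - 1L) / rec$fs,
                     emg_uV = rec$emg, trigger = rec$trigger)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
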