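#' Detect stimulus triggers on the trigger channel
#'
#' Finds rising-edge crossings of an adaptive threshold placed between the
#' channel's minimum and maximum, suppressing re-crossings (contact chatter)
#' within a refractory period. The default refractory of 200 ms sits far
#' below the ~1 s interstimulus interval and far above the 500 us pulse
#' width, so every stimulus yields exactly one detection. A crossing must
#' hold for two consecutive samples (debounce): TTL pulses last >= 1 ms
#' (two samples at 2 kHz), while single-sample noise excursions above
#' threshold are thereby rejected.
#'
#' @param rec A [recording()].
#' @param threshold_fraction Crossing level as a fraction of the channel
#'   range, in (0, 1); default 0.5.
#' @param refractory_ms Minimum spacing between detections, default 200.
#' @return Strictly increasing integer vector of sample indices (1-based,
#'   the first sample at or above threshold).
#' @export
detect_triggers <- function(rec, threshold_fraction = 0.5,
                            refractory_ms = 200) {
  stopifnot(inherits(rec, "cmap_recording"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  tr <- rec$trigger
  r <- range(tr)
  if (diff(r) == 0) stop("no trigger dynamics: trigger channel is flat")
  thr <- r[1L] + threshold_fraction * diff(r)
  above <- tr >= thr
  held <- above & c(above[-1L], TRUE)  # two-sample debounce
  cross <- which(held & !c(FALSE, above[-length(above)]))
  if (!length(cross)) return(integer(0))
  refr_n <- refractory_ms * rec$fs / 1000
  keep <- cross[1L]
  for (i in cross[-1L]) {
    if (i - keep[length(keep)] > refr_n) keep <- c(keep, i)
  }
  keep
}

#' Segment a recording into trigger-aligned epochs
#'
#' Cuts one epoch per trigger using the window geometry, and assigns each
#' epoch its stimulus-intensity index (position within the repeating
#' ascending train of `n_levels` intensities) and its train index. Triggers
#' are grouped into trains purely positionally: the protocol delivers the
#' intensities in ascending order within each train, so triggers
#' 1..n_levels are train 1, the next n_levels train 2, and so on.
#'
#' @param rec A [recording()].
#' @param triggers Integer sample indices from [detect_triggers()].
#' @param window An [epoch_window()].
#' @param n_levels Number of intensities per train (default 5).
#' @param condition_index Nerve condition of this recording (0 = initial,
#'   1..3 = damage levels); taken from `rec$meta$condition_index` if absent.
#' @return List of `cmap_epoch` objects. Epochs whose window would cross a
#'   recording edge are dropped with a warning, never padded.
#' @export
segment_epochs <- function(rec, triggers, window = epoch_window(),
                           n_levels = 5L, condition_index = NULL) {
  stopifnot(inherits(rec, "cmap_recording"), inherits(window, "epoch_window"))
  n_trig <- length(triggers)
  if (n_trig == 0L || n_trig %% n_levels != 0L)
    stop("expected a multiple of ", n_levels, " triggers, found ", n_trig)
  if (is.null(condition_index))
    condition_index <- rec$meta$condition_index %||% 0L
  ws <- .window_samples(window, rec$fs)
  offsets <- seq.int(-ws$pre_n, length.out = ws$len)
  intensity <- rep(seq_len(n_levels), times = n_trig %/% n_levels)
  train <- rep(seq_len(n_trig %/% n_levels), each = n_levels)
  out <- vector("list", n_trig)
  dropped <- integer(0)
  for (k in seq_len(n_trig)) {
    idx <- triggers[k] + offsets
    if (idx[1L] < 1L || idx[length(idx)] > length(rec$emg)) {
      dropped <- c(dropped, k)
      next
    }
    out[[k]] <- structure(
      list(samples = rec$emg[idx], fs = rec$fs,
           intensity_index = intensity[k], train_index = train[k],
           condition_index = condition_index, trigger_index = triggers[k],
           pre_n = ws$pre_n),
      class = "cmap_epoch")
  }
  if (length(dropped)) {
    warning(length(dropped), " epoch(s) dropped: window crosses a ",
            "recording edge (triggers ",
            paste(triggers[dropped], collapse = ", "), ")")
    out <- out[-dropped]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grand-average epochs across trains, per stimulus intensity
#'
#' Pointwise mean of the epoch waveforms sharing an intensity index. The
#' pipeline always averages waveforms first and extracts the peak-to-peak
#' amplitude from the average (max - min is nonlinear, so the reverse order
#' gives a different, noisier estimate).
#'
#' @param epochs List of `cmap_epoch` from [segment_epochs()].
#' @return Named list (one element per intensity index, names `"1"`..) of
#'   averaged `cmap_epoch` objects, each carrying `n_averaged`.
#' @export
grand_average <- function(epochs) {
  if (!length(epochs)) stop("no epochs to average")
  fs <- unique(vapply(epochs, `[[`, 0, "fs"))
  len <- unique(vapply(epochs, function(e) length(e$samples), 0L))
  cond <- unique(vapply(epochs, function(e) as.numeric(e$condition_index), 0))
  if (length(fs) != 1L || length(len) != 1L || length(cond) != 1L)
    stop("epochs must share fs, length and condition_index")
  ints <- vapply(epochs, `[[`, 0L, "intensity_index")
  levels <- sort(unique(ints))
  out <- lapply(levels, function(l) {
    grp <- epochs[ints == l]
    if (!length(grp)) stop("empty epoch group for intensity ", l)
    m <- rowMeans(vapply(grp, `[[`, numeric(len), "samples"))
    e <- grp[[1L]]
    e$samples <- m
    e$train_index <- NA_integer_
    e$n_averaged <- length(grp)
    e
  })
  names(out) <- as.character(levels)
  out
}

#' Peak-to-peak CMAP amplitude of an epoch
#'
#' Subtracts the pre-stimulus baseline (mean of the samples before the
#' trigger) and returns max - min over the samples whose trigger-relative
#' time lies in the half-open feature window
#' `[feature_start_ms, feature_end_ms)`.
#'
#' @param epoch A `cmap_epoch`.
#' @param window An [epoch_window()]; its feature window must lie inside
#'   the epoch.
#' @return Non-negative amplitude in uV.
#' @export
extract_vpp <- function(epoch, window = epoch_window()) {
  stopifnot(inherits(epoch, "cmap_epoch"), inherits(window, "epoch_window"))
  t_ms <- (seq_along(epoch$samples) - 1L - epoch$pre_n) / epoch$fs * 1000
  feat <- t_ms >= window$feature_start_ms & t_ms < window$feature_end_ms
  if (!any(feat)) stop("empty feature window")
  if (window$feature_end_ms > max(t_ms) + 1000 / epoch$fs)
    stop("feature window extends past the epoch")
  base <- mean(epoch$samples[t_ms < 0])
  if (!is.finite(base)) base <- 0  # no pre-stimulus samples (pre_ms = 0)
  s <- epoch$samples[feat] - base
  max(s) - min(s)
}

#' Per-intensity CMAP amplitudes from a raw recording
#'
#' Convenience wrapper running the full front end: trigger detection,
#' segmentation, grand averaging across trains, and peak-to-peak
#' extraction.
#'
#' @inheritParams segment_epochs
#' @inheritParams detect_triggers
#' @return Numeric vector of grand-averaged Vpp (uV), one per intensity,
#'   with the number of averaged trains as attribute `n_averaged`.
#' @export
vpp_from_recording <- function(rec, window = epoch_window(), n_levels = 5L,
                               threshold_fraction = 0.5,
                               refractory_ms = 200) {
  trig <- detect_triggers(rec, threshold_fraction, refractory_ms)
  ep <- segment_epochs(rec, trig, window, n_levels)
  avg <- grand_average(ep)
  v <- vapply(avg, extract_vpp, 0, window = window)
  attr(v, "n_averaged") <- vapply(avg, `[[`, 0L, "n_averaged")
  v
}
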