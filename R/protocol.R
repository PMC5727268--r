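#' Graded stimulus schedule
#'
#' The stimulation protocol: five intensities expressed as percent of the
#' motor threshold (MT), delivered in ascending order within each train,
#' with `n_trains` repetitions. Defaults follow the standard multi-CMAP
#' protocol: P1..P5 = 100..140 %MT, 500 us pulses, ~1 s interstimulus
#' interval and ~5 s between trains, 4 trains.
#'
#' @param mt Motor threshold intensity (mA), > 0.
#' @param levels_pct_mt Five strictly increasing percentages, first = 100.
#' @param pulse_width_us Pulse width, default 500.
#' @param isi_s Interstimulus interval within a train (s), default 1.
#' @param inter_train_s Gap between trains (s), default 5.
#' @param n_trains Number of trains, default 4.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(mt = 1, levels_pct_mt = c(100, 110, 120, 130, 140),
                              pulse_width_us = 500, isi_s = 1,
                              inter_train_s = 5, n_trains = 4L) {
  if (mt <= 0) stop("mt must be > 0")
  if (any(diff(levels_pct_mt) <= 0)) stop("levels must be strictly increasing")
  if (levels_pct_mt[1L] != 100) stop("first level must be 100 %MT")
  if (n_trains < 1L) stop("n_trains must be >= 1")
  structure(list(mt = mt, levels_pct_mt = levels_pct_mt,
                 pulse_width_us = pulse_width_us, isi_s = isi_s,
                 inter_train_s = inter_train_s, n_trains = as.integer(n_trains)),
            class = "stimulus_schedule")
}

#' Load-cell calibration model
#'
#' Affine map from the digital load-cell reading to force in grams. The
#' default coefficients are the calibration of the compression tool:
#' force = 0.6556 x + 2.7617.
#'
#' @param slope Grams per digital count, > 0.
#' @param intercept Grams.
#' @return An object of class `loadcell_calibration`.
#' @export
loadcell_calibration <- function(slope = 0.6556, intercept = 2.7617) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
  structure(list(slope = slope, intercept = intercept),
            class = "loadcell_calibration")
}

#' Convert a digital load-cell reading to force
#'
#' @param x Digital count(s) read from the load cell (finite).
#' @param cal A [loadcell_calibration()].
#' @return Force in grams, `cal$slope * x + cal$intercept`.
#' @examples
#' loadcell_to_force(0)   # intercept: 2.7617 g
#' loadcell_to_force(10)  # 9.3177 g
#' @export
loadcell_to_force <- function(x, cal = loadcell_calibration()) {
  stopifnot(inherits(cal, "loadcell_calibration"))
  if (any(!is.finite(x))) stop("x must be finite")
  cal$slope * x + cal$intercept
}

#' Graded damage schedule from a measured maximum
#'
#' Divides the maximum injury level (the level at which the 140 %MT CMAP
#' disappears) into graded steps. The default fractions (1/3, 2/3, 1)
#' reproduce the reported compression levels 30/60/90 g for a 90 g maximum;
#' the alternative halving scheme (1/3, 1/2, 1) is available via
#' `fractions`. Compression levels are rounded to the nearest gram,
#' incision levels to the nearest percent.
#'
#' @param max_level Measured maximum (> 0): grams for compression, percent
#'   tissue removed for incision.
#' @param modality `"compression"` or `"incision"`.
#' @param fractions Strictly increasing fractions in (0, 1], last = 1.
#' @return Numeric vector of graded levels.
#' @examples
#' make_damage_schedule(90, "compression")        # 30 60 90
#' make_damage_schedule(63.2, "incision")         # 21 42 63
#' @export
make_damage_schedule <- function(max_level,
                                 modality = c("compression", "incision"),
                                 fractions = c(1 / 3, 2 / 3, 1)) {
  modality <- match.arg(modality)
  if (!is.finite(max_level) || max_level <= 0)
    stop("max_level must be > 0")
  if (any(diff(fractions) <= 0) || any(fractions <= 0) ||
      fractions[length(fractions)] != 1)
    stop("fractions must be strictly increasing in (0, 1] with last = 1")
  round(fractions * max_level)
}

#' Motor-threshold surrogate from an intensity sweep
#'
#' The experimental MT criterion (visible muscle twitch) is replaced by a
#' computational surrogate: the smallest tested intensity whose CMAP
#' peak-to-peak amplitude exceeds `k` times the recording noise SD.
#'
#' @param intensity Strictly increasing tested intensities (mA).
#' @param vpp CMAP Vpp at each intensity (uV).
#' @param noise_sd Noise standard deviation (uV).
#' @param k Criterion multiplier, default 3.
#' @return MT in the units of `intensity`.
#' @export
find_motor_threshold <- function(intensity, vpp, noise_sd, k = 3) {
  if (length(intensity) != length(vpp))
    stop("intensity and vpp must have equal length")
  if (any(diff(intensity) <= 0))
    stop("intensities must be strictly increasing")
  hit <- which(vpp > k * noise_sd)
  if (!length(hit))
    stop("MT not reached: no intensity exceeds ", k, " x noise SD")
  intensity[hit[1L]]
}
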