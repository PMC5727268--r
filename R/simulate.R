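#' Synthetic axon population
#'
#' A nerve is modelled as a population of motor axons, each with a
#' stimulation threshold (lognormal, in units of the motor threshold MT:
#' median 1.0 so half the population is recruited at 100 %MT) and a unit
#' contribution to the muscle's peak-to-peak response (lognormal,
#' right-skewed, as is standard for motor-unit sizes). Increasing stimulus
#' intensity recruits axons of increasing threshold, producing the
#' recruitment curve.
#'
#' @param n_axons Number of axons, default 200.
#' @param threshold_median Median threshold in MT units, default 1.0.
#' @param threshold_sigma Lognormal sdlog of thresholds, default 0.25.
#' @param amp_median_uv Median per-axon Vpp contribution (uV), default 3.
#' @param amp_sigma Lognormal sdlog of unit amplitudes, default 0.5.
#' @param thresholds,amps Explicit per-axon values overriding the draws
#'   (useful for closed-form test cases).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return An object of class `axon_population`.
#' @export
axon_population <- function(n_axons = 200L, threshold_median = 1.0,
                            threshold_sigma = 0.25, amp_median_uv = 3,
                            amp_sigma = 0.5, thresholds = NULL, amps = NULL,
                            seed = NULL) {
  if (n_axons < 1L) stop("n_axons must be >= 1")
  if (threshold_median <= 0 || threshold_sigma <= 0 || amp_median_uv <= 0 ||
      amp_sigma <= 0)
    stop("distribution parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(thresholds))
    thresholds <- stats::rlnorm(n_axons, log(threshold_median),
                                threshold_sigma)
  if (is.null(amps))
    amps <- stats::rlnorm(length(thresholds), log(amp_median_uv), amp_sigma)
  if (length(amps) != length(thresholds))
    stop("thresholds and amps must have equal length")
  structure(list(thresholds = thresholds, amps = amps),
            class = "axon_population")
}

#' Graded conduction-block injury model
#'
#' Injury at level L blocks each axon with probability
#' `(1 - selectivity) * B + selectivity * (threshold rank > 1 - B)`, where
#' `B = block_fraction[L + 1]`. The expected blocked fraction is exactly
#' `B` at any selectivity. Selectivity 0 blocks axons uniformly at random
#' (pure proportional scaling of the recruitment curve -- invisible to the
#' scale-invariant per-trial normalization); selectivity 1 removes the
#' highest-threshold axons outright, so the surviving population saturates
#' at lower intensities and the suprathreshold recruitment segment
#' flattens, which is what the slope feature detects. Defaults grade the
#' selectivity with severity so the maximally injured nerve's curve is
#' essentially flat.
#'
#' An optional multiplicative `threshold_shift` (>= 1) raises surviving
#' axons' thresholds; note this *steepens* the normalized 100-140 %MT
#' segment (it moves recruitment into the window) and is off (1) by
#' default.
#'
#' @param block_fraction Blocked fraction per damage level 0..3,
#'   non-decreasing in \[0, 1); default `c(0, 0.15, 0.45, 0.75)`.
#' @param selectivity Threshold-rank selectivity of the block per level, in
#'   \[0, 1\]; default `c(0, 0.7, 0.85, 1)`.
#' @param threshold_shift Multiplicative threshold increase for surviving
#'   axons per level, >= 1, non-decreasing; default all 1.
#' @return An object of class `injury_model`.
#' @export
injury_model <- function(block_fraction = c(0, 0.15, 0.45, 0.75),
                         selectivity = c(0, 0.7, 0.85, 1),
                         threshold_shift = c(1, 1, 1, 1)) {
  if (length(block_fraction) != 4L || any(diff(block_fraction) < 0) ||
      any(block_fraction < 0) || any(block_fraction >= 1))
    stop("block_fraction must be 4 non-decreasing values in [0, 1)")
  if (length(selectivity) != 4L || any(selectivity < 0) ||
      any(selectivity > 1))
    stop("selectivity must be 4 values in [0, 1]")
  if (length(threshold_shift) != 4L || any(threshold_shift < 1) ||
      any(diff(threshold_shift) < 0))
    stop("threshold_shift must be 4 non-decreasing values >= 1")
  structure(list(block_fraction = block_fraction, selectivity = selectivity,
                 threshold_shift = threshold_shift), class = "injury_model")
}

# Bernoulli conduction-block mask for one nerve at one damage level
.block_mask <- function(pop, injury, level) {
  b <- injury$block_fraction[level + 1L]
  g <- injury$selectivity[level + 1L]
  n <- length(pop$thresholds)
  q <- rank(pop$thresholds, ties.method = "first") / n
  p <- (1 - g) * b + g * (q > 1 - b)
  stats::runif(n) < p
}

#' Simulate grand-averaged CMAP amplitudes for one nerve condition
#'
#' For each scheduled intensity P (in MT units), the response is the summed
#' unit amplitude of non-blocked axons whose (possibly shifted) threshold
#' is at most P, plus Gaussian amplitude noise truncated at zero. The
#' blocking mask is sampled once per call (one nerve, one damage level).
#'
#' @param pop An [axon_population()].
#' @param injury An [injury_model()].
#' @param level Damage level 0..3.
#' @param schedule A [stimulus_schedule()].
#' @param noise_sd_uv Amplitude noise SD (uV), default 15.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of 5 Vpp values (uV) with the blocking mask as
#'   attribute `"blocked"`.
#' @export
simulate_amplitudes <- function(pop, injury, level, schedule = stimulus_schedule(),
                                noise_sd_uv = 15, seed = NULL) {
  stopifnot(inherits(pop, "axon_population"), inherits(injury, "injury_model"))
  if (!level %in% 0:3) stop("level must be 0..3")
  if (!is.null(seed)) set.seed(seed)
  blocked <- .block_mask(pop, injury, level)
  shift <- injury$threshold_shift[level + 1L]
  th <- pop$thresholds * shift
  p_units <- schedule$levels_pct_mt / 100
  v <- vapply(p_units, function(p) sum(pop$amps[!blocked & th <= p]), 0)
  if (noise_sd_uv > 0)
    v <- pmax(v + stats::rnorm(length(v), 0, noise_sd_uv), 0)
  attr(v, "blocked") <- blocked
  v
}

#' Biphasic CMAP waveform template
#'
#' Half-sine positive phase followed by a broader half-sine negative phase,
#' starting `onset_ms` after the stimulus. When sampled, the template is
#' normalized so its peak-to-peak amplitude within the feature window is
#' exactly 1; scaling it by a programmed Vpp therefore programs the epoch's
#' extracted amplitude.
#'
#' @param onset_ms Response latency after the trigger, default 3.
#' @param pos_width_ms,neg_width_ms Phase widths (ms), defaults 2 and 4.
#' @param pos_fraction Positive share of the peak-to-peak range, default
#'   0.6 (so a 500 uV CMAP peaks at +300 and -200 uV).
#' @return An object of class `cmap_waveform`.
#' @export
cmap_waveform <- function(onset_ms = 3, pos_width_ms = 2, neg_width_ms = 4,
                          pos_fraction = 0.6) {
  if (onset_ms < 0 || pos_width_ms <= 0 || neg_width_ms <= 0)
    stop("waveform durations must be positive")
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop("pos_fraction must be in (0, 1)")
  structure(list(onset_ms = onset_ms, pos_width_ms = pos_width_ms,
                 neg_width_ms = neg_width_ms, pos_fraction = pos_fraction),
            class = "cmap_waveform")
}

# sample the template on the fs grid (trigger-relative offsets >= 0),
# normalized to unit Vpp within the feature window
.sample_waveform <- function(wf, fs, window = epoch_window()) {
  dur_ms <- wf$onset_ms + wf$pos_width_ms + wf$neg_width_ms
  if (dur_ms >= window$post_ms)
    stop("waveform (latency + duration = ", dur_ms,
         " ms) does not fit in the epoch window")
  k <- 0:ceiling(dur_ms * fs / 1000)
  t <- k * 1000 / fs
  s <- numeric(length(t))
  inpos <- t >= wf$onset_ms & t < wf$onset_ms + wf$pos_width_ms
  s[inpos] <- wf$pos_fraction *
    sin(pi * (t[inpos] - wf$onset_ms) / wf$pos_width_ms)
  t0 <- wf$onset_ms + wf$pos_width_ms
  inneg <- t >= t0 & t < t0 + wf$neg_width_ms
  s[inneg] <- -(1 - wf$pos_fraction) * sin(pi * (t[inneg] - t0) / wf$neg_width_ms)
  feat <- t >= window$feature_start_ms & t < window$feature_end_ms
  vpp <- max(s[feat]) - min(s[feat])
  if (vpp <= 0) stop("waveform has no peak-to-peak range in the feature window")
  s / vpp
}

#' Simulation configuration
#'
#' @param seed Master seed; all randomness in [generate_cohort()] and
#'   [simulate_recording()] flows from it.
#' @param noise_sd_uv Additive noise SD (uV): applied at the Vpp level in
#'   [simulate_amplitudes()] and at the sample level in
#'   [simulate_recording()]. Default 15.
#' @param fs Sampling rate (Hz), default 2000.
#' @param n_subjects Cohort size, default 16.
#' @param schedule A [stimulus_schedule()].
#' @param window An [epoch_window()].
#' @param waveform A [cmap_waveform()].
#' @param pop_jitter_sigma,pop_jitter_amp Lognormal sdlog of the
#'   between-subject jitter on threshold spread and unit-amplitude scale
#'   (defaults 0.1 and 0.2).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd_uv = 15, fs = 2000,
                       n_subjects = 16L, schedule = stimulus_schedule(),
                       window = epoch_window(), waveform = cmap_waveform(),
                       pop_jitter_sigma = 0.1, pop_jitter_amp = 0.2) {
  if (noise_sd_uv < 0) stop("noise_sd_uv must be >= 0")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  wf_end <- waveform$onset_ms + waveform$pos_width_ms + waveform$neg_width_ms
  if (wf_end >= window$post_ms)
    stop("waveform does not fit in the epoch window")
  structure(list(seed = seed, noise_sd_uv = noise_sd_uv, fs = fs,
                 n_subjects = as.integer(n_subjects), schedule = schedule,
                 window = window, waveform = waveform,
                 pop_jitter_sigma = pop_jitter_sigma,
                 pop_jitter_amp = pop_jitter_amp),
            class = "sim_config")
}

#' Simulate a full trigger-aligned two-channel recording
#'
#' Builds a continuous EMG trace containing `n_trains x 5` biphasic CMAPs
#' scaled to the condition's simulated amplitudes (fixed across trains:
#' same nerve, same recruitment), rectangular trigger pulses at the
#' programmed stimulus times, and additive white sample noise. Ground truth
#' (trigger indices and programmed per-intensity Vpp) is carried in `meta`.
#'
#' @inheritParams simulate_amplitudes
#' @param cfg A [sim_config()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A [recording()] with `meta$trigger_index` and
#'   `meta$programmed_vpp`.
#' @export
simulate_recording <- function(pop, injury, level, cfg = sim_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sch <- cfg$schedule
  fs <- cfg$fs
  vpp <- simulate_amplitudes(pop, injury, level, sch,
                             noise_sd_uv = cfg$noise_sd_uv)
  n_lev <- length(sch$levels_pct_mt)
  train_starts <- 1 + (seq_len(sch$n_trains) - 1L) *
    ((n_lev - 1L) * sch$isi_s + sch$inter_train_s)
  pulse_times <- as.vector(vapply(train_starts, function(t0)
    t0 + (seq_len(n_lev) - 1L) * sch$isi_s, numeric(n_lev)))
  duration_s <- ceiling(max(pulse_times) + 1)
  n <- as.integer(duration_s * fs)
  trig_idx <- as.integer(round(pulse_times * fs)) + 1L
  if (max(trig_idx) + cfg$window$post_ms * fs / 1000 > n)
    stop("schedule too long for the recording duration")

  template <- .sample_waveform(cfg$waveform, fs, cfg$window)
  emg <- numeric(n)
  amp_per_pulse <- rep(vpp, times = sch$n_trains)
  for (k in seq_along(trig_idx)) {
    idx <- trig_idx[k] + seq_along(template) - 1L
    emg[idx] <- emg[idx] + amp_per_pulse[k] * template
  }
  if (cfg$noise_sd_uv > 0)
    emg <- emg + stats::rnorm(n, 0, cfg$noise_sd_uv)
  trigger <- numeric(n)
  pulse_len <- max(1L, as.integer(round(0.001 * fs)))  # 1 ms TTL pulse
  for (ti in trig_idx) trigger[ti:(ti + pulse_len - 1L)] <- 5
  recording(emg, trigger, fs = fs,
            meta = list(trigger_index = trig_idx,
                        programmed_vpp = as.numeric(vpp),
                        condition_index = level))
}

#' Generate a synthetic cohort of CMAP amplitude matrices
#'
#' Draws one axon population per subject (with between-subject jitter on
#' the threshold spread and unit-amplitude scale), applies the injury model
#' at all four damage levels, and returns one [cmap_matrix()] per subject.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param injury An [injury_model()].
#' @param pop_args Named list of overrides for [axon_population()].
#' @return List of [cmap_matrix()] with ground truth (per-subject
#'   populations and injury model) in attribute `"ground_truth"`.
#' @export
generate_cohort <- function(cfg = sim_config(), injury = injury_model(),
                            pop_args = list()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- vector("list", cfg$n_subjects)
  mats <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    args <- utils::modifyList(
      list(threshold_sigma = 0.25 * exp(stats::rnorm(1, 0, cfg$pop_jitter_sigma)),
           amp_median_uv = 3 * exp(stats::rnorm(1, 0, cfg$pop_jitter_amp))),
      pop_args)
    pops[[s]] <- do.call(axon_population, args)
    vpp <- t(vapply(0:3, function(lev)
      as.numeric(simulate_amplitudes(pops[[s]], injury, lev, cfg$schedule,
                                     noise_sd_uv = cfg$noise_sd_uv)),
      numeric(length(cfg$schedule$levels_pct_mt))))
    mats[[s]] <- cmap_matrix(vpp, schedule = cfg$schedule,
                             subject_id = sprintf("s%02d", s))
  }
  names(mats) <- vapply(mats, `[[`, "", "subject_id")
  attr(mats, "ground_truth") <- list(populations = pops, injury = injury,
                                     seed = cfg$seed)
  mats
}
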