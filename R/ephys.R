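# Field-EPSP slope extraction, input/output curves, and theta-burst LTP
# quantification, plus synthetic recording generators.

#' fEPSP slope from a voltage trace
#'
#' Slope is the voltage difference between two cursors separated by 1 ms,
#' placed on the middle portion of the ascending phase. The ascending phase
#' is delimited by the first crossings of 10% and 90% of the
#' baseline-to-peak amplitude (the rise phase); the trace must be strictly
#' increasing across it, and the cursor pair is centered at its midpoint.
#' Voltages at cursor positions are linearly interpolated.
#'
#' @param time_ms Sample times (ms), strictly increasing.
#' @param voltage_mV Voltages (mV), same length.
#' @param sep_ms Cursor separation (default 1 ms).
#' @param onset_frac Onset threshold as a fraction of baseline-to-peak
#'   amplitude (default 0.1); the phase ends at `1 - onset_frac`.
#' @return Slope in mV/ms.
#' @export
fepsp_slope <- function(time_ms, voltage_mV, sep_ms = 1, onset_frac = 0.1) {
  stopifnot(length(time_ms) == length(voltage_mV), length(time_ms) >= 2L)
  if (diff(range(time_ms)) < sep_ms) {
    stop("trace shorter than the cursor separation", call. = FALSE)
  }
  peak_i <- which.max(voltage_mV)
  peak_v <- voltage_mV[peak_i]
  base_v <- voltage_mV[1L]
  amp <- peak_v - base_v
  if (amp <= 0 || peak_i < 2L) stop("no detectable ascending phase", call. = FALSE)
  lo <- base_v + onset_frac * amp
  hi <- base_v + (1 - onset_frac) * amp
  pre <- voltage_mV[seq_len(peak_i)]
  onset_i <- which(pre >= lo)[1L]
  end_i <- which(pre >= hi)[1L]
  if (is.na(onset_i) || is.na(end_i) || end_i <= onset_i) {
    stop("no detectable ascending phase", call. = FALSE)
  }
  if (any(diff(voltage_mV[onset_i:end_i]) <= 0)) {
    stop("ascending phase is not monotone", call. = FALSE)
  }
  mid <- (time_ms[onset_i] + time_ms[end_i]) / 2
  ca <- max(mid - sep_ms / 2, min(time_ms))
  cb <- ca + sep_ms
  if (cb > max(time_ms)) {
    cb <- max(time_ms)
    ca <- cb - sep_ms
  }
  va <- approx(time_ms, voltage_mV, xout = ca)$y
  vb <- approx(time_ms, voltage_mV, xout = cb)$y
  (vb - va) / sep_ms
}

#' Synthetic fEPSP waveform (sigmoid rise)
#'
#' `v(t) = amplitude / (1 + exp(-(t - t0)/tau))`; the maximum rise is
#' `amplitude / (4 tau)` mV/ms at the midpoint.
#'
#' @param amplitude_mV Peak amplitude (mV).
#' @param tau_ms Rise time constant (ms).
#' @param t0_ms Midpoint time (ms).
#' @param duration_ms Trace duration (ms).
#' @param sample_khz Sampling rate (kHz; default 10).
#' @return data.frame(time_ms, voltage_mV).
#' @export
simulate_fepsp_trace <- function(amplitude_mV = 2, tau_ms = 0.5, t0_ms = 5,
                                 duration_ms = 15, sample_khz = 10) {
  t <- seq(0, duration_ms, by = 1 / sample_khz)
  data.frame(time_ms = t,
             voltage_mV = amplitude_mV / (1 + exp(-(t - t0_ms) / tau_ms)))
}

#' Input/output curve
#'
#' Mean fEPSP slope per stimulus intensity plus the overall least-squares
#' I/O slope (response slope per uA).
#'
#' @param intensity_uA Stimulus intensity per sweep (uA).
#' @param slope_mV_per_ms fEPSP slope per sweep (mV/ms).
#' @param grid Expected intensity grid; default 100-350 uA in 50 uA steps.
#' @return List of class `io_curve`: `curve` (data.frame intensity_uA,
#'   mean_slope, n), `io_slope` (fitted line slope), `grid`.
#' @export
io_curve <- function(intensity_uA, slope_mV_per_ms,
                     grid = seq(100, 350, by = 50)) {
  stopifnot(length(intensity_uA) == length(slope_mV_per_ms))
  if (any(diff(grid) <= 0)) stop("intensity grid must be strictly increasing", call. = FALSE)
  if (length(unique(intensity_uA)) < 2L) {
    stop("need responses at >= 2 intensities", call. = FALSE)
  }
  agg <- aggregate(slope_mV_per_ms, by = list(intensity_uA = intensity_uA), FUN = mean)
  names(agg)[2] <- "mean_slope"
  agg$n <- as.integer(table(intensity_uA)[as.character(agg$intensity_uA)])
  agg <- agg[order(agg$intensity_uA), ]
  fit <- lm(slope_mV_per_ms ~ intensity_uA)
  structure(list(curve = agg, io_slope = unname(coef(fit)[2]), grid = grid),
            class = "io_curve")
}

#' Construct an LTP recording
#'
#' @param sweep_time_s Sweep times (s), ascending.
#' @param slope_mV_per_ms Per-sweep fEPSP slope (mV/ms).
#' @param tbs_time_s Time of theta-burst stimulation (s).
#' @param baseline_min Baseline window length before TBS (min, default 10).
#' @param intensity_uA Optional per-sweep stimulus intensity.
#' @param tbs_pattern Metadata string describing the induction protocol.
#' @return List of class `ltp_recording`.
#' @export
ltp_recording <- function(sweep_time_s, slope_mV_per_ms, tbs_time_s,
                          baseline_min = 10, intensity_uA = NULL,
                          tbs_pattern = "10 trains of 5 pulses at 100 Hz, repeated at 5 Hz") {
  stopifnot(length(sweep_time_s) == length(slope_mV_per_ms))
  if (is.unsorted(sweep_time_s, strictly = TRUE)) {
    stop("sweeps must be strictly time-ordered", call. = FALSE)
  }
  if (!any(sweep_time_s < tbs_time_s)) stop("need >= 1 baseline sweep", call. = FALSE)
  if (tbs_time_s - baseline_min * 60 < min(sweep_time_s) - 1e-9) {
    stop("baseline window must precede TBS within the recording", call. = FALSE)
  }
  structure(list(sweep_time_s = sweep_time_s,
                 slope_mV_per_ms = slope_mV_per_ms,
                 tbs_time_s = tbs_time_s, baseline_min = baseline_min,
                 intensity_uA = intensity_uA, tbs_pattern = tbs_pattern),
            class = "ltp_recording")
}

#' Normalize an LTP recording to its baseline
#'
#' Each sweep's slope expressed as percent of the mean slope during the
#' pre-TBS baseline window (default final 10 min before TBS).
#'
#' @param rec An [ltp_recording()].
#' @return data.frame(time_min, pct_baseline); `time_min` is minutes relative
#'   to TBS.
#' @export
normalize_ltp <- function(rec) {
  stopifnot(inherits(rec, "ltp_recording"))
  in_baseline <- rec$sweep_time_s < rec$tbs_time_s &
    rec$sweep_time_s >= rec$tbs_time_s - rec$baseline_min * 60
  base_mean <- mean(rec$slope_mV_per_ms[in_baseline])
  if (!is.finite(base_mean) || base_mean == 0) {
    stop("zero baseline mean", call. = FALSE)
  }
  data.frame(time_min = (rec$sweep_time_s - rec$tbs_time_s) / 60,
             pct_baseline = 100 * rec$slope_mV_per_ms / base_mean)
}

#' LTP magnitude (final-window mean)
#'
#' Mean of the normalized slopes in the final `final_min` minutes of the
#' post-TBS recording (default 5 min).
#'
#' @param normalized data.frame from [normalize_ltp()].
#' @param final_min Final-window length (min).
#' @param min_post_min Required post-TBS duration (min, default 30).
#' @return LTP as percent of baseline.
#' @export
ltp_value <- function(normalized, final_min = 5, min_post_min = 30) {
  post <- normalized[normalized$time_min > 0, , drop = FALSE]
  if (nrow(post) == 0L || max(post$time_min) < min_post_min) {
    stop("insufficient post-TBS duration (need >= ", min_post_min, " min)",
         call. = FALSE)
  }
  last <- max(post$time_min)
  mean(post$pct_baseline[post$time_min > last - final_min])
}

#' Between-group LTP test
#'
#' Two-tailed t-test on per-slice LTP values.
#'
#' @param ltp_a,ltp_b Numeric vectors of per-slice [ltp_value()] results.
#' @param flavor See [two_tailed_t()].
#' @export
ltp_group_test <- function(ltp_a, ltp_b, flavor = "student") {
  two_tailed_t(ltp_a, ltp_b, flavor = flavor)
}

#' Simulate an LTP recording
#'
#' Sweeps every `cadence_s` seconds (default 20 s): a baseline period, TBS,
#' then a post-TBS period in which slopes are multiplied by the potentiation
#' factor (optionally decaying exponentially toward a plateau). Gaussian
#' noise with SD `noise_sd` (as a fraction of the baseline slope) is added
#' per sweep.
#'
#' @param baseline_slope Baseline fEPSP slope (mV/ms).
#' @param potentiation Post-TBS multiplicative factor (1 = no LTP).
#' @param noise_sd Per-sweep noise SD as a fraction of `baseline_slope`.
#' @param baseline_min,post_min Durations (min); post must be >= 30.
#' @param cadence_s Inter-sweep interval (s).
#' @param decay_to Optional plateau factor the potentiation decays to.
#' @param decay_tau_min Decay time constant (min).
#' @param seed Integer seed.
#' @return An [ltp_recording()].
#' @export
simulate_recording <- function(baseline_slope = 0.5, potentiation = 1.5,
                               noise_sd = 0, baseline_min = 10, post_min = 30,
                               cadence_s = 20, decay_to = NULL,
                               decay_tau_min = 10, seed = 1L) {
  if (baseline_min < 10 || post_min < 30) {
    stop("durations must cover >= 10 min baseline and >= 30 min post-TBS",
         call. = FALSE)
  }
  set.seed(seed)
  tbs_time <- baseline_min * 60
  times <- seq(0, tbs_time + post_min * 60, by = cadence_s)
  factor <- ifelse(times <= tbs_time, 1, potentiation)
  if (!is.null(decay_to)) {
    post <- times > tbs_time
    dt_min <- (times[post] - tbs_time) / 60
    factor[post] <- decay_to + (potentiation - decay_to) * exp(-dt_min / decay_tau_min)
  }
  slopes <- baseline_slope * factor +
    rnorm(length(times), sd = noise_sd * baseline_slope)
  ltp_recording(times, slopes, tbs_time_s = tbs_time, baseline_min = baseline_min)
}
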