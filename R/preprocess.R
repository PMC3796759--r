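#' Full-wave rectify an EMG recording
#'
#' Replaces every sample by its absolute value; shape, rate and labels are
#' unchanged. Idempotent.
#'
#' @param rec An [emg_recording()].
#' @return The rectified `emg_recording`.
#' @export
rectify <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  rec$samples <- abs(rec$samples)
  rec
}

#' Zero-phase low-pass filter an EMG recording
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), so the envelope is smoothed without shifting the
#' response onset in time. The default 32 Hz cutoff suits rectified surface
#' EMG sampled at 1 kHz.
#'
#' @param rec An [emg_recording()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `rate / 2`.
#' @param order Filter order (default 4).
#' @return The filtered `emg_recording`.
#' @export
emg_lowpass <- function(rec, cutoff_hz = 32, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rec$rate / 2)
    stop_synergy("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
                 cutoff_hz, rec$rate / 2, class = "invalid_parameter")
  bf <- signal::butter(order, cutoff_hz / (rec$rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (without it even a DC channel is distorted);
  # the pad must cover the filter's settling time, which scales with
  # rate/cutoff
  npad <- min(as.integer(3 * order * ceiling(rec$rate / cutoff_hz)),
              ncol(rec$samples) - 1L)
  rec$samples <- t(apply(rec$samples, 1L, function(ch) {
    head_pad <- 2 * ch[1L] - ch[(npad + 1L):2L]
    tail_pad <- 2 * ch[length(ch)] - ch[(length(ch) - 1L):(length(ch) - npad)]
    y <- signal::filtfilt(bf, c(head_pad, ch, tail_pad))
    y[(npad + 1L):(npad + length(ch))]
  }))
  rownames(rec$samples) <- rec$muscles
  rec
}

#' Normalize processed EMG by experiment-wide per-muscle maxima
#'
#' Divides each muscle channel, in every trial, by that muscle's maximum
#' processed amplitude over all supplied recordings, so the per-muscle
#' maximum across the experiment equals 1. Apply after rectification and
#' low-pass filtering.
#'
#' @param recs List of [emg_recording()] objects sharing the same muscle
#'   ordering.
#' @param method `"global_max"` (default): the maximum over all samples of
#'   all trials. `"mean_of_trial_max"`: the mean across trials of per-trial
#'   maxima — an alternative reading of "maximum mean" normalization.
#' @return The list of recordings, scaled.
#' @export
normalize_emg <- function(recs, method = c("global_max", "mean_of_trial_max")) {
  method <- match.arg(method)
  stopifnot(length(recs) >= 1L, all(vapply(recs, inherits, TRUE, "emg_recording")))
  muscles <- recs[[1L]]$muscles
  for (r in recs)
    if (!identical(r$muscles, muscles))
      stop_synergy("all recordings must share the muscle ordering",
                   class = "invalid_input")
  trial_max <- vapply(recs, function(r) apply(r$samples, 1L, max),
                      numeric(length(muscles)))
  trial_max <- matrix(trial_max, nrow = length(muscles))
  scale <- switch(method,
                  global_max = apply(trial_max, 1L, max),
                  mean_of_trial_max = rowMeans(trial_max))
  if (any(scale <= 0))
    stop_synergy("muscle(s) %s identically zero across all recordings",
                 paste(muscles[scale <= 0], collapse = ", "),
                 class = "degenerate_channel")
  lapply(recs, function(r) { r$samples <- r$samples / scale; r })
}

#' Extract the analysis window around the perturbation trigger
#'
#' Cuts the activation matrix used for synergy extraction: `duration_ms` of
#' samples starting `latency_ms` after the trigger (defaults: a 160 ms
#' window starting 40 ms after displacement onset, the latency of the
#' automatic posture response). Sample indices use the half-open interval
#' `[start, start + t)`. Small negative values left by zero-phase filtering
#' of a rectified signal are clipped to zero.
#'
#' @param rec A processed [emg_recording()] with `trigger_time` set.
#' @param latency_ms Response latency after the trigger, in ms.
#' @param duration_ms Window length in ms; the matrix gets
#'   `round(duration_ms * rate / 1000)` columns.
#' @return An [activation_matrix()].
#' @export
extract_window <- function(rec, latency_ms = 40, duration_ms = 160) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(rec$trigger_time))
    stop_synergy("recording has no trigger_time", class = "invalid_input")
  t_cols <- as.integer(round(duration_ms * rec$rate / 1000))
  if (t_cols < 1L)
    stop_synergy("window shorter than one sample", class = "invalid_parameter")
  start <- as.integer(round((rec$trigger_time + latency_ms / 1000) * rec$rate)) + 1L
  if (start < 1L || start + t_cols - 1L > ncol(rec$samples))
    stop_synergy("window [%d, %d) exceeds recording of %d samples",
                 start, start + t_cols, ncol(rec$samples),
                 class = "out_of_range")
  vals <- rec$samples[, start:(start + t_cols - 1L), drop = FALSE]
  vals[vals < 0] <- 0
  activation_matrix(vals, rate = rec$rate,
                    window = c(latency_ms, duration_ms),
                    muscles = rec$muscles)
}

#' Run the full preprocessing chain on a set of trials
#'
#' Rectification, zero-phase low-pass filtering, experiment-wide
#' normalization across all supplied trials, and trigger-locked windowing,
#' in that order.
#'
#' @param recs List of raw [emg_recording()] objects with triggers set.
#' @param cutoff_hz,order Low-pass filter settings (see [emg_lowpass()]).
#' @param latency_ms,duration_ms Window settings (see [extract_window()]).
#' @param norm_method Normalization reading (see [normalize_emg()]).
#' @return List of [activation_matrix()] objects, one per trial.
#' @export
preprocess_trials <- function(recs, cutoff_hz = 32, order = 4,
                              latency_ms = 40, duration_ms = 160,
                              norm_method = "global_max") {
  proc <- lapply(recs, function(r) emg_lowpass(rectify(r), cutoff_hz, order))
  proc <- normalize_emg(proc, method = norm_method)
  lapply(proc, extract_window, latency_ms = latency_ms,
         duration_ms = duration_ms)
}
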