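#' Multichannel EMG recording for one trial
#'
#' Container for raw or processed surface-EMG signals of a single trial:
#' a channels-by-time sample matrix, the sampling rate, ordered muscle
#' labels and (optionally) the perturbation-trigger time.
#'
#' @param samples Numeric matrix, one row per muscle channel, one column per
#'   sample. Raw signals may be of arbitrary sign; rectified/processed
#'   signals are non-negative.
#' @param rate Sampling frequency in Hz (positive scalar).
#' @param muscles Character vector of channel labels, one per row of
#'   `samples`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param trigger_time Perturbation onset in seconds from the start of the
#'   recording, or `NULL` if unknown.
#'
#' @return An object of class `emg_recording`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(600), nrow = 6), rate = 1000)
#' rec
#' @export
emg_recording <- function(samples, rate, muscles = NULL, trigger_time = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_synergy("samples must be a finite numeric matrix", class = "invalid_input")
  if (nrow(samples) < 1L || ncol(samples) < 2L)
    stop_synergy("need at least 1 channel and 2 samples", class = "invalid_input")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_synergy("rate must be a positive scalar (Hz)", class = "invalid_parameter")
  if (is.null(muscles)) muscles <- paste0("ch", seq_len(nrow(samples)))
  if (length(muscles) != nrow(samples))
    stop_synergy("one muscle label per channel required", class = "invalid_input")
  if (!is.null(trigger_time)) {
    if (!is.numeric(trigger_time) || length(trigger_time) != 1L ||
        trigger_time < 0 || trigger_time > ncol(samples) / rate)
      stop_synergy("trigger_time outside the recording", class = "invalid_parameter")
  }
  rownames(samples) <- muscles
  structure(list(samples = samples, rate = rate,
                 muscles = as.character(muscles),
                 trigger_time = trigger_time),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("  muscles:", paste(x$muscles, collapse = ", "), "\n")
  if (!is.null(x$trigger_time))
    cat(sprintf("  trigger at %.3f s\n", x$trigger_time))
  invisible(x)
}

#' Windowed non-negative muscle activation matrix
#'
#' The m-by-t non-negative matrix fed to factorization: m muscles by t
#' samples, cut from a processed recording around the perturbation trigger.
#'
#' @param values Non-negative numeric matrix (muscles x samples).
#' @param rate Sampling frequency in Hz.
#' @param window Numeric length-2 vector `c(start, duration)` in ms relative
#'   to the trigger, or `NULL` when the matrix was not cut from a recording.
#' @param muscles Optional channel labels.
#'
#' @return An object of class `activation_matrix`.
#' @export
activation_matrix <- function(values, rate = 1000, window = NULL,
                              muscles = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_synergy("values must be a finite numeric matrix", class = "invalid_input")
  if (any(values < 0))
    stop_synergy("activation matrix must be non-negative", class = "invalid_input")
  if (!is.null(muscles)) rownames(values) <- muscles
  structure(list(values = values, rate = rate, window = window),
            class = "activation_matrix")
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("<activation_matrix> %d muscles x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$rate))
  if (!is.null(x$window))
    cat(sprintf("  window: %g ms after trigger, %g ms long\n",
                x$window[1], x$window[2]))
  invisible(x)
}

#' @export
as.matrix.activation_matrix <- function(x, ...) x$values

# Accept either an activation_matrix or a plain matrix in analysis entry
# points.
as_activation_values <- function(M) {
  if (inherits(M, "activation_matrix")) M$values else as.matrix(M)
}
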