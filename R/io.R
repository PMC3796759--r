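#' Read a trial's EMG from CSV
#'
#' Expects one column per muscle (header row = muscle labels) and one row
#' per sample; the sampling rate and trigger time are not stored in the CSV
#' and must be supplied.
#'
#' @param file Path to the CSV.
#' @param rate Sampling rate in Hz.
#' @param trigger_time Perturbation onset in seconds, or `NULL`.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(file, rate, trigger_time = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  emg_recording(t(as.matrix(df)), rate = rate, muscles = colnames(df),
                trigger_time = trigger_time)
}

#' Write a recording or activation matrix to CSV
#'
#' Same layout as [read_emg_csv()]: one column per muscle, one row per
#' sample.
#'
#' @param x An [emg_recording()] or [activation_matrix()].
#' @param file Output path.
#' @export
write_emg_csv <- function(x, file) {
  vals <- if (inherits(x, "emg_recording")) x$samples else as_activation_values(x)
  df <- as.data.frame(t(vals))
  names(df) <- rownames(vals) %||% paste0("ch", seq_len(nrow(vals)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-list views used by the CLI's JSON output (matrices row-major).
decomposition_to_list <- function(d) {
  rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
  list(W = rows(d$W), C = rows(d$C),
       L = d$L, n = d$n, seed = d$seed, restarts_used = d$restarts_used)
}

report_to_list <- function(r) {
  list(id = r$id, p = r$p, n = r$n, L = unname(r$L),
       reached_threshold = r$reached_threshold, threshold = r$threshold,
       ssi = r$ssi, ssi_c = r$ssi_c, sci = unname(r$sci),
       sci_mean = r$sci_mean, sci_sd = r$sci_sd,
       permutations = lapply(r$ensemble$permutations, as.integer),
       score = r$score, session = r$session)
}
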