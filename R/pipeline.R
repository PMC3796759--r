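#' Filter trials by balance score
#'
#' Keeps only trials whose visually-assigned balance score equals
#' `target_score` (+1 by default: the participant moved a hand but kept
#' both feet planted), truncated to the first `count` qualifying trials so
#' every participant contributes the same number. Scores follow the
#' four-level scale \{-2, -1, +1, +2\}.
#'
#' @param trials List of trials (any type).
#' @param scores Numeric vector of per-trial scores, same length.
#' @param target_score Score value to keep (default +1).
#' @param count Maximum number of trials to keep (default 5).
#' @return List with `trials` (the kept trials), `kept` (their indices),
#'   and `available` (how many qualified before truncation).
#' @export
filter_trials <- function(trials, scores, target_score = 1, count = 5) {
  stopifnot(length(trials) == length(scores))
  if (!all(scores %in% c(-2, -1, 1, 2)))
    stop_synergy("scores must be on the scale {-2, -1, +1, +2}",
                 class = "invalid_input")
  idx <- which(scores == target_score)
  if (length(idx) < 2L)
    stop_synergy("fewer than 2 trials with score %+d", target_score,
                 class = "insufficient_trials")
  if (length(idx) < count)
    warning(sprintf("only %d trials with score %+d available (requested %d)",
                    length(idx), target_score, count))
  kept <- idx[seq_len(min(count, length(idx)))]
  list(trials = trials[kept], kept = kept, available = length(idx))
}

#' Analyze one participant's trials end to end
#'
#' Runs the per-trial synergy analysis for one participant: selects a
#' common synergy-space dimension (the smallest n whose similarity L
#' exceeds `threshold` in every trial, so each trial individually meets the
#' fit criterion), decomposes each trial at that dimension, matches the
#' synergies across trials, and computes SSI, SSI_c and per-trial SCI.
#'
#' @param trials List of >= 2 [activation_matrix()] objects (or plain
#'   non-negative matrices) with a consistent muscle set. Raw
#'   [emg_recording()] trials should first go through
#'   [preprocess_trials()].
#' @param threshold Similarity threshold for dimension selection.
#' @param restarts,max_iter,tol NMF settings (see [nmf()]).
#' @param seed Top-level seed, expanded deterministically per (trial,
#'   dimension).
#' @param n Fix the dimension instead of selecting it (skips the search).
#' @param id,score,session Optional metadata carried into the report:
#'   participant identifier, mean balance score, session label/number.
#' @return A `participant_report`: list with `id`, `n`, `L` (per trial at
#'   the chosen n), `L_curve` (trial-wise L per candidate dimension),
#'   `reached_threshold`, `ssi`, `ssi_c`, `sci`, `sci_mean`, `sci_sd`,
#'   `score`, `session`, `p`, `ensemble`.
#' @export
run_participant <- function(trials, threshold = 75, restarts = 20,
                            max_iter = 2000, tol = 1e-6, seed = 1,
                            n = NULL, id = NULL, score = NULL,
                            session = NULL) {
  stopifnot(length(trials) >= 2L)
  mats <- lapply(trials, as_activation_values)
  m <- nrow(mats[[1L]])
  for (M in mats)
    if (nrow(M) != m)
      stop_synergy("trials disagree on the number of muscles",
                   class = "invalid_input")

  decomp_at <- function(k) lapply(seq_along(mats), function(j)
    nmf(mats[[j]], k, restarts = restarts, max_iter = max_iter, tol = tol,
        seed = derive_seed(seed, j * 131L + k)))

  L_curve <- NULL
  reached <- TRUE
  if (is.null(n)) {
    decs <- NULL
    L_curve <- matrix(NA_real_, length(mats), m - 1L,
                      dimnames = list(NULL, paste0("n", seq_len(m - 1L))))
    for (k in seq_len(m - 1L)) {
      cand <- decomp_at(k)
      L_curve[, k] <- vapply(cand, `[[`, numeric(1), "L")
      if (all(L_curve[, k] > threshold)) {
        n <- k
        decs <- cand
        break
      }
    }
    if (is.null(decs)) {           # no dimension met the criterion in all trials
      n <- m - 1L
      decs <- decomp_at(n)
      reached <- FALSE
    }
  } else {
    decs <- decomp_at(n)
  }

  ens <- synergy_ensemble(decs)
  structure(list(id = id, p = length(trials), n = ens$n,
                 L = vapply(decs, `[[`, numeric(1), "L"),
                 L_curve = L_curve, reached_threshold = reached,
                 threshold = threshold,
                 ssi = ens$ssi, ssi_c = ens$ssi_c,
                 sci = ens$sci, sci_mean = ens$sci_mean, sci_sd = ens$sci_sd,
                 score = score, session = session, ensemble = ens),
            class = "participant_report")
}

#' @export
print.participant_report <- function(x, ...) {
  cat(sprintf("<participant_report>%s %d trials, n = %d\n",
              if (is.null(x$id)) "" else paste0(" ", x$id), x$p, x$n))
  cat(sprintf("  L: %s\n", paste(sprintf("%.1f", x$L), collapse = ", ")))
  cat(sprintf("  SSI = %.3f  SSI_c = %.3f  SCI = %.3f +/- %.3f\n",
              x$ssi, x$ssi_c, x$sci_mean, x$sci_sd))
  if (!is.null(x$score)) cat(sprintf("  score = %g\n", x$score))
  invisible(x)
}

# Least-squares line and Pearson r of y against x.
ls_trend <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_synergy("trend undefined: constant predictor or response",
                 class = "zero_variance")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = pearson_r(x, y), n = length(x))
}

#' Correlate the synergy indices with balance scores
#'
#' For each index (SSI, SSI_c, mean SCI) fits the least-squares line
#' against the participants' mean balance scores and reports its slope,
#' intercept and Pearson r.
#'
#' @param reports List of >= 3 `participant_report` objects with `score`
#'   set.
#' @return Data frame with one row per index: `index`, `slope`,
#'   `intercept`, `r`, `n`.
#' @export
correlate_index_with_scores <- function(reports) {
  stopifnot(all(vapply(reports, inherits, TRUE, "participant_report")))
  if (length(reports) < 3L)
    stop_synergy("need at least 3 scored participants", class = "invalid_input")
  scores <- vapply(reports, function(r) {
    if (is.null(r$score)) stop_synergy("report without score",
                                       class = "invalid_input")
    r$score
  }, numeric(1))
  index_trends(reports, scores)
}

#' Track the synergy indices across training sessions
#'
#' Fits the least-squares trend of each index against the session number,
#' pooling all supplied reports. On a training schedule in which the
#' synergy space consolidates (cross-trial W variability shrinks) while the
#' commands diversify, SSI and SCI trend upward and SSI_c downward.
#'
#' @param session_reports List of `participant_report` objects with
#'   `session` set (numeric session index); at least 2 distinct sessions.
#' @return Data frame with one row per index: `index`, `slope`,
#'   `intercept`, `r`, `n`.
#' @export
track_sessions <- function(session_reports) {
  stopifnot(all(vapply(session_reports, inherits, TRUE, "participant_report")))
  sessions <- vapply(session_reports, function(r) {
    if (is.null(r$session)) stop_synergy("report without session label",
                                         class = "invalid_input")
    as.numeric(r$session)
  }, numeric(1))
  if (length(unique(sessions)) < 2L)
    stop_synergy("need at least 2 distinct sessions", class = "insufficient_data")
  index_trends(session_reports, sessions)
}

index_trends <- function(reports, x) {
  vals <- list(ssi = vapply(reports, `[[`, numeric(1), "ssi"),
               ssi_c = vapply(reports, `[[`, numeric(1), "ssi_c"),
               sci = vapply(reports, `[[`, numeric(1), "sci_mean"))
  rows <- lapply(names(vals), function(nm) {
    tr <- ls_trend(x, vals[[nm]])
    data.frame(index = nm, slope = tr$slope, intercept = tr$intercept,
               r = tr$r, n = tr$n)
  })
  do.call(rbind, rows)
}

#' Flatten participant reports to a summary table
#'
#' @param reports List of `participant_report` objects.
#' @return Data frame, one row per report: id, session, p, n, mean L, SSI,
#'   SSI_c, SCI mean/SD, score.
#' @export
summarize_reports <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    id = if (is.null(r$id)) NA_character_ else as.character(r$id),
    session = if (is.null(r$session)) NA_real_ else as.numeric(r$session),
    p = r$p, n = r$n, L_mean = mean(r$L),
    ssi = r$ssi, ssi_c = r$ssi_c,
    sci_mean = r$sci_mean, sci_sd = r$sci_sd,
    score = if (is.null(r$score)) NA_real_ else r$score)))
}
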