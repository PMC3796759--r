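#' Pearson correlation coefficient
#'
#' Computed explicitly as
#' `r = sum((x - mean(x)) * (y - mean(y))) / (m * S_x * S_y)` with
#' population standard deviations (denominator m). Algebraically this
#' equals the usual sample Pearson coefficient; the explicit form mirrors
#' the definition used by the stability indices.
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  m <- length(x)
  if (m != length(y) || m < 2L)
    stop_synergy("x and y must have equal length >= 2", class = "invalid_input")
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx < 1e-12 || sy < 1e-12)
    stop_synergy("Pearson correlation undefined for a constant vector",
                 class = "zero_variance")
  sum((x - mean(x)) * (y - mean(y))) / (m * sx * sy)
}

#' Match synergies across trials by maximizing stability
#'
#' NMF recovers synergies up to column order, so before comparing trials
#' the columns must be aligned ("re-sorted"). The first trial is the
#' reference; for every other trial the column permutation maximizing the
#' summed Pearson correlation with the reference synergies is found by
#' exhaustive search over all n! permutations (n is small, so the search is
#' exact). Ties are broken by the lexicographically smallest permutation.
#' The same permutation must then be applied to the rows of that trial's C.
#'
#' @param W_list List of p non-negative m x n synergy matrices (p >= 2,
#'   shared dimensions).
#' @return List of p integer permutations; element 1 is the identity.
#' @export
match_synergies <- function(W_list) {
  stopifnot(is.list(W_list), length(W_list) >= 1L)
  n <- ncol(W_list[[1L]])
  m <- nrow(W_list[[1L]])
  for (W in W_list)
    if (ncol(W) != n || nrow(W) != m)
      stop_synergy("all trials must share the synergy dimensions",
                   class = "invalid_ensemble")
  ref <- W_list[[1L]]
  perms <- permutations_lex(n)
  out <- vector("list", length(W_list))
  out[[1L]] <- seq_len(n)
  for (j in seq_along(W_list)[-1L]) {
    best_score <- -Inf
    best_perm <- perms[[1L]]
    for (p in perms) {
      score <- sum(vapply(seq_len(n), function(i)
        pearson_r(ref[, i], W_list[[j]][, p[i]]), numeric(1)))
      if (score > best_score + 1e-12) {        # strict: first (lex-least) wins ties
        best_score <- score
        best_perm <- p
      }
    }
    out[[j]] <- best_perm
  }
  out
}

#' Build a matched per-trial synergy ensemble
#'
#' Collects one participant's per-trial decompositions, aligns the synergy
#' columns across trials via [match_synergies()] (applying the same
#' permutation to the command rows), and computes the three indices: SSI,
#' SSI_c and per-trial SCI.
#'
#' @param decompositions List of p `synergy_decomposition` objects with the
#'   same m and n, p >= 2.
#' @return A `synergy_ensemble`: list with the aligned `decompositions`,
#'   `permutations`, `ssi`, `ssi_c`, `sci` (per trial), `sci_mean`,
#'   `sci_sd`, `p`, `n`.
#' @export
synergy_ensemble <- function(decompositions) {
  stopifnot(is.list(decompositions),
            all(vapply(decompositions, inherits, TRUE, "synergy_decomposition")))
  p <- length(decompositions)
  if (p < 2L)
    stop_synergy("an ensemble needs at least 2 trials", class = "invalid_ensemble")
  n <- decompositions[[1L]]$n
  perms <- match_synergies(lapply(decompositions, `[[`, "W"))
  aligned <- Map(function(d, pm) {
    d$W <- d$W[, pm, drop = FALSE]
    d$C <- d$C[pm, , drop = FALSE]
    d
  }, decompositions, perms)
  ens <- structure(list(decompositions = aligned, permutations = perms,
                        p = p, n = n),
                   class = "synergy_ensemble")
  ens$ssi <- compute_ssi(ens)
  ens$ssi_c <- compute_ssic(ens)
  ens$sci <- if (n >= 2L)
    vapply(aligned, function(d) compute_sci(d$W), numeric(1)) else
    rep(NA_real_, p)
  ens$sci_mean <- mean(ens$sci)
  ens$sci_sd <- sd(ens$sci)
  ens
}

#' @export
print.synergy_ensemble <- function(x, ...) {
  cat(sprintf("<synergy_ensemble> p = %d trials, n = %d synergies\n", x$p, x$n))
  cat(sprintf("  SSI = %.3f  SSI_c = %.3f  SCI = %.3f (mean of %d trials)\n",
              x$ssi, x$ssi_c, x$sci_mean, x$p))
  invisible(x)
}

# Mean over components i of the mean pairwise Pearson correlation over all
# unordered trial pairs (l, q) — shared backbone of SSI and SSI_c.
mean_pairwise_r <- function(vecs_by_trial, n) {
  p <- length(vecs_by_trial)
  pairs <- utils::combn(p, 2L)
  mean(vapply(seq_len(n), function(i) {
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      l <- pairs[1L, k]; q <- pairs[2L, k]
      pearson_r(vecs_by_trial[[l]][, i], vecs_by_trial[[q]][, i])
    }, numeric(1)))
  }, numeric(1)))
}

#' Synergy stability index (SSI)
#'
#' Mean, over synergies, of the mean Pearson correlation between matched
#' synergy vectors across all unordered trial pairs:
#' `SSI = (1/n) sum_i [ 2/(p(p-1)) sum_{l<q} r(W_l^(i), W_q^(i)) ]`.
#' SSI = 1 when every trial uses exactly the same synergies; values near 1
#' mean the participant reuses a fixed region of synergy space. Pearson
#' values are not clipped, so adversarial inputs can push SSI below 0; a
#' warning is raised in that case.
#'
#' @param ensemble A matched `synergy_ensemble`, or a list of m x n synergy
#'   matrices already aligned.
#' @return The SSI (scalar).
#' @export
compute_ssi <- function(ensemble) {
  W_list <- if (inherits(ensemble, "synergy_ensemble"))
    lapply(ensemble$decompositions, `[[`, "W") else ensemble
  if (length(W_list) < 2L)
    stop_synergy("SSI needs at least 2 trials", class = "invalid_ensemble")
  val <- mean_pairwise_r(W_list, ncol(W_list[[1L]]))
  if (val < 0)
    warning("SSI below 0: synergies anti-correlated across trials")
  val
}

#' Neural-command stability index (SSI_c)
#'
#' The SSI statistic applied to the command time courses: mean pairwise
#' Pearson correlation of the matched rows of C across trials. SSI_c = 1
#' when the commands are identical in every trial.
#'
#' @param ensemble A matched `synergy_ensemble`, or a list of n x t command
#'   matrices already aligned.
#' @return The SSI_c (scalar).
#' @export
compute_ssic <- function(ensemble) {
  C_list <- if (inherits(ensemble, "synergy_ensemble"))
    lapply(ensemble$decompositions, `[[`, "C") else ensemble
  if (length(C_list) < 2L)
    stop_synergy("SSI_c needs at least 2 trials", class = "invalid_ensemble")
  # command i is row i; transpose so the shared backbone reads columns
  val <- mean_pairwise_r(lapply(C_list, t), nrow(C_list[[1L]]))
  if (val < 0)
    warning("SSI_c below 0: commands anti-correlated across trials")
  val
}

#' Synergy coordination index (SCI)
#'
#' Size of the synergy space, measured as the mean inner product over all
#' unordered pairs of unit synergy vectors:
#' `SCI = 2/(n(n-1)) sum_{i<j} W^(i) . W^(j)`.
#' SCI = 1 when all synergy vectors coincide (smallest possible space) and
#' SCI = 0 when they are mutually orthogonal (largest).
#'
#' @param W Non-negative m x n matrix with unit-norm columns, n >= 2.
#' @return The SCI (scalar in \[0, 1\]).
#' @export
compute_sci <- function(W) {
  W <- as.matrix(W)
  n <- ncol(W)
  if (n < 2L)
    stop_synergy("SCI undefined for fewer than 2 synergies",
                 class = "undefined_index")
  norms <- sqrt(colSums(W^2))
  if (any(abs(norms - 1) > 1e-6))
    stop_synergy("SCI requires unit-norm synergy columns",
                 class = "invalid_input")
  G <- crossprod(W)
  sum(G[upper.tri(G)]) / (n * (n - 1) / 2)
}
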