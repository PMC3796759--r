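#' Non-negative matrix factorization of an activation matrix
#'
#' Decomposes a non-negative m-by-t muscle activation matrix M into a
#' synergy matrix W (m x n, unit-norm columns) and a neural-command matrix
#' C (n x t), M ~ W C, using Lee-Seung multiplicative updates on the
#' squared Frobenius objective. NMF is non-convex, so several random
#' restarts are run and the solution with the highest similarity L is
#' returned. Deterministic given `seed`.
#'
#' @param M An [activation_matrix()] or plain non-negative matrix.
#' @param n Number of synergies, `1 <= n < m`.
#' @param restarts Number of random restarts (default 20).
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Stop a restart when the relative change in residual norm
#'   falls below this.
#' @param seed Integer seed; restart r uses a child seed derived from
#'   `(seed, r)`.
#' @return A `synergy_decomposition`: list with `W`, `C`, `L`, `n`,
#'   `restarts_used`, `seed`, `iterations` (of the winning restart).
#' @examples
#' M <- abs(matrix(rnorm(6 * 40), 6)) %*% abs(matrix(rnorm(40 * 40), 40)) / 40
#' dec <- nmf(M, n = 2, restarts = 5, seed = 1)
#' dec$L
#' @export
nmf <- function(M, n, restarts = 20, max_iter = 2000, tol = 1e-6, seed = 1) {
  V <- as_activation_values(M)
  if (any(V < 0))
    stop_synergy("input matrix has negative entries", class = "invalid_input")
  m <- nrow(V)
  if (!is.numeric(n) || n < 1L || n >= m)
    stop_synergy("n must satisfy 1 <= n < m = %d", m, class = "invalid_parameter")
  n <- as.integer(n)
  eps <- 1e-12

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, r), {
      W <- matrix(runif(m * n), m, n)
      C <- matrix(runif(n * ncol(V)), n, ncol(V))
      res_prev <- Inf
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        C <- C * (crossprod(W, V)) / (crossprod(W, W %*% C) + eps)
        W <- W * (V %*% t(C)) / (W %*% tcrossprod(C) + eps)
        res <- sqrt(sum((V - W %*% C)^2))
        if (is.finite(res_prev) &&
            abs(res_prev - res) <= tol * max(res_prev, eps)) break
        res_prev <- res
      }
      list(W = W, C = C, iterations = it)
    })
    L <- tryCatch(similarity_L(V, fit$W, fit$C), error = function(e) -Inf)
    if (is.null(best) || L > best$L)
      best <- list(W = fit$W, C = fit$C, L = L, iterations = fit$iterations)
  }
  if (!is.finite(best$L))
    stop_synergy("factorization degenerate: reconstruction has a zero muscle row",
                 class = "degenerate_synergy")

  wc <- normalize_synergies(best$W, best$C)
  rownames(wc$W) <- rownames(V)
  structure(list(W = wc$W, C = wc$C, L = best$L, n = n,
                 restarts_used = as.integer(restarts), seed = as.integer(seed),
                 iterations = best$iterations),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("<synergy_decomposition> %d muscles, n = %d synergies, L = %.2f\n",
              nrow(x$W), x$n, x$L))
  invisible(x)
}

#' Rescale synergies to unit norm
#'
#' Scales each column of W to unit Euclidean norm and the corresponding row
#' of C by the inverse factor, leaving the product W C unchanged.
#'
#' @param W Non-negative m x n matrix with no all-zero column.
#' @param C Non-negative n x t matrix.
#' @return List with rescaled `W` and `C`.
#' @export
normalize_synergies <- function(W, C) {
  W <- as.matrix(W); C <- as.matrix(C)
  stopifnot(ncol(W) == nrow(C))
  norms <- sqrt(colSums(W^2))
  if (any(norms < 1e-12))
    stop_synergy("all-zero synergy column", class = "degenerate_synergy")
  list(W = sweep(W, 2L, norms, "/"), C = C * norms)
}

#' Similarity L between measured and reconstructed muscle patterns
#'
#' Reconstruction-quality index on a 0-100 scale:
#' `L = 100 * (1 - mean_i [ mean_j E_ij^2 / mean_j M'_ij^2 ])` with
#' `M' = W C` and `E = M - M'`. The per-muscle ratio makes L sensitive to
#' every muscle being well reconstructed, not just the loudest ones.
#' L = 100 iff E = 0.
#'
#' @param M Measured activation matrix (object or plain matrix).
#' @param W,C The decomposition.
#' @return The similarity L (scalar).
#' @export
similarity_L <- function(M, W, C) {
  V <- as_activation_values(M)
  Mp <- W %*% C
  stopifnot(all(dim(V) == dim(Mp)))
  denom <- rowMeans(Mp^2)
  if (any(denom < 1e-300))
    stop_synergy("reconstructed muscle row identically zero; L undefined",
                 class = "undefined_ratio")
  E <- V - Mp
  100 * (1 - mean(rowMeans(E^2) / denom))
}

#' Select the synergy-space dimension from the L criterion
#'
#' Runs NMF at each candidate dimension n = 1, ..., m-1 and returns the
#' smallest n whose best-of-restarts similarity exceeds `threshold`
#' (default L > 75), together with the full L-versus-n curve. If no
#' dimension below m reaches the threshold, m - 1 is reported with
#' `reached_threshold = FALSE`.
#'
#' @param M An [activation_matrix()] or plain non-negative matrix.
#' @param threshold Similarity threshold in (0, 100).
#' @param full_curve If `TRUE` (default) the L curve is computed for every
#'   candidate dimension; if `FALSE` the search stops at the first dimension
#'   over the threshold.
#' @inheritParams nmf
#' @return A `dimension_selection`: list with `n`, `L` (the curve, one value
#'   per candidate dimension evaluated), `threshold`, `reached_threshold`.
#' @export
select_dimension <- function(M, threshold = 75, restarts = 20,
                             max_iter = 2000, tol = 1e-6, seed = 1,
                             full_curve = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 100)
    stop_synergy("threshold must lie in (0, 100)", class = "invalid_parameter")
  V <- as_activation_values(M)
  m <- nrow(V)
  if (m < 2L)
    stop_synergy("need at least 2 muscles to select a dimension",
                 class = "invalid_input")
  Ls <- rep(NA_real_, m - 1L)
  chosen <- NA_integer_
  for (k in seq_len(m - 1L)) {
    Ls[k] <- nmf(V, k, restarts = restarts, max_iter = max_iter,
                 tol = tol, seed = derive_seed(seed, k))$L
    if (is.na(chosen) && Ls[k] > threshold) {
      chosen <- k
      if (!full_curve) break
    }
  }
  reached <- !is.na(chosen)
  structure(list(n = if (reached) chosen else m - 1L,
                 L = Ls[!is.na(Ls)],
                 threshold = threshold,
                 reached_threshold = reached),
            class = "dimension_selection")
}

#' @export
print.dimension_selection <- function(x, ...) {
  cat(sprintf("<dimension_selection> n = %d (threshold L > %g%s)\n",
              x$n, x$threshold,
              if (x$reached_threshold) "" else "; threshold NOT reached"))
  cat("  L curve:", paste(sprintf("%.1f", x$L), collapse = ", "), "\n")
  invisible(x)
}
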