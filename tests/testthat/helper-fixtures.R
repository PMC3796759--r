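# Shared fixture builders. Everything is generated in code; no stored data.

# A unit-norm non-negative 6-vector with support on the given coordinates.
unit6 <- function(idx, w = rep(1, length(idx))) {
  v <- numeric(6)
  v[idx] <- w
  v / sqrt(sum(v^2))
}

# A raw-looking recording: sinusoid mixtures with sign, trigger mid-way.
make_raw_recording <- function(seed = 1, n_ch = 6, secs = 1, rate = 1000,
                               trigger_time = 0.4) {
  withr::with_seed(seed, {
    ts <- seq(0, secs - 1 / rate, by = 1 / rate)
    samples <- t(vapply(seq_len(n_ch), function(i) {
      sin(2 * pi * runif(1, 1, 8) * ts + runif(1, 0, 2 * pi)) *
        runif(1, 0.5, 2) + rnorm(length(ts), sd = 0.1)
    }, numeric(length(ts))))
    emg_recording(samples, rate = rate, trigger_time = trigger_time)
  })
}

# A synergy_decomposition wrapper around explicit W and C (bypasses NMF)
# for index tests on hand-written matrices.
fake_decomposition <- function(W, C) {
  structure(list(W = W, C = C, L = 100, n = ncol(W),
                 restarts_used = 0L, seed = 0L, iterations = 0L),
            class = "synergy_decomposition")
}

# Brute-force SSI oracle: plain double loop over synergies and trial pairs,
# using stats::cor (independent of the package's pearson_r).
brute_ssi <- function(W_list) {
  n <- ncol(W_list[[1]])
  p <- length(W_list)
  vals <- c()
  for (i in seq_len(n)) {
    for (l in seq_len(p - 1)) for (q in (l + 1):p)
      vals <- c(vals, cor(W_list[[l]][, i], W_list[[q]][, i]))
  }
  # mean over pairs within synergy, then over synergies
  mean(tapply(vals, rep(seq_len(n), each = p * (p - 1) / 2), mean))
}
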