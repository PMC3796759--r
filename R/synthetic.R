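#' Construct a synergy matrix with a controlled pairwise angle
#'
#' Builds n non-negative unit-norm columns whose pairwise angles all equal
#' `pair_angle`. Each column mixes a shared random non-negative direction
#' `s` (supported on coordinates left free for it) with its own private
#' coordinate axis: `W^(i) = cos(a) s + sin(a) e_i` with
#' `cos(a)^2 = cos(pair_angle)`, which makes every pairwise inner product
#' exactly `cos(pair_angle)` while staying inside the non-negative orthant.
#' The private axes and the support of `s` are a seeded random permutation
#' of the muscle coordinates. For angles below 90 degrees the construction
#' needs at least one coordinate for the shared direction, hence m > n.
#'
#' @param m Number of muscles.
#' @param n Number of synergies, `1 <= n <= m`.
#' @param pair_angle Target angle between synergy columns, degrees in
#'   \[0, 90\].
#' @param seed Integer seed.
#' @return Non-negative m x n matrix with unit columns; pairwise column
#'   angles equal `pair_angle`.
#' @export
make_synergy_space <- function(m, n, pair_angle = 60, seed = 1) {
  if (n < 1L || m < n)
    stop_synergy("need m >= n >= 1", class = "invalid_parameter")
  if (pair_angle < 0 || pair_angle > 90)
    stop_synergy("pair_angle must lie in [0, 90] degrees",
                 class = "invalid_parameter")
  theta <- pair_angle * pi / 180
  with_seed(seed, {
    axes <- sample.int(m)
    if (n > 1L && pair_angle < 90 && m <= n)
      stop_synergy(
        "pair_angle %g infeasible for n = %d non-negative synergies in %d muscles",
        pair_angle, n, m, class = "infeasible_angle")
    W <- matrix(0, m, n)
    if (n == 1L || pair_angle == 90) {
      for (i in seq_len(n)) W[axes[i], i] <- 1
      if (n == 1L && m > 1L) {
        # spread a single synergy over several muscles so it looks EMG-like
        w <- runif(m)
        W[, 1L] <- w / sqrt(sum(w^2))
      }
    } else {
      shared_idx <- axes[(n + 1L):m]
      s <- runif(length(shared_idx), min = 0.2, max = 1)
      s <- s / sqrt(sum(s^2))
      a <- acos(sqrt(cos(theta)))
      for (i in seq_len(n)) {
        W[shared_idx, i] <- cos(a) * s
        W[axes[i], i] <- sin(a)
      }
    }
    W
  })
}

#' Generate burst-like neural commands
#'
#' One smooth non-negative burst per synergy: a Gaussian bump with seeded
#' random width (4-9% of the window, i.e. a burst lasting a few tens of ms
#' at 1 kHz) and amplitude (0.5-1), emulating the transient command
#' profiles of an automatic posture response. Burst centers are staggered —
#' synergy i's center sits near the midpoint of its own sub-interval of the
#' middle 70% of the window, with seeded jitter — mirroring the sequential
#' recruitment of functional muscle groups during a posture response and
#' keeping the commands temporally distinguishable (coincident bursts would
#' collapse the trial toward rank one and make the true dimension
#' unidentifiable, which would defeat the generator's purpose as ground
#' truth).
#'
#' @param n Number of synergies.
#' @param t Number of time samples, >= 8.
#' @param seed Integer seed.
#' @return Non-negative n x t matrix; every row has a positive maximum.
#' @export
make_commands <- function(n, t, seed = 1) {
  if (n < 1L) stop_synergy("n >= 1 required", class = "invalid_parameter")
  if (t < 8L) stop_synergy("t >= 8 required", class = "invalid_parameter")
  with_seed(seed, {
    ts <- seq_len(t)
    slots <- seq(0.15, 0.85, length.out = n + 1L) * t
    C <- t(vapply(seq_len(n), function(i) {
      mid <- (slots[i] + slots[i + 1L]) / 2
      jitter <- 0.15 * (slots[i + 1L] - slots[i])
      center <- runif(1, mid - jitter, mid + jitter)
      width <- runif(1, 0.04 * t, 0.09 * t)
      amp <- runif(1, 0.5, 1)
      amp * exp(-((ts - center)^2) / (2 * width^2))
    }, numeric(t)))
    matrix(C, nrow = n)
  })
}

#' Ground truth behind a synthetic cohort
#'
#' Bundles the true synergy space W*, true commands C*, and the three
#' variability scales that the generator applies per trial:
#' `sigma_W` (cross-trial perturbation of the synergy columns — how much
#' the used region of synergy space wanders), `sigma_C` (cross-trial
#' perturbation of the command time courses), and `noise_sd` (additive
#' observation noise on the assembled activation matrix). All scales are in
#' normalized-EMG units (signals live in roughly \[0, 1\]).
#'
#' @param m,n,t Muscles, synergies, time samples per trial.
#' @param pair_angle Angle between true synergy columns, degrees.
#' @param sigma_W,sigma_C,noise_sd Perturbation/noise scales (>= 0).
#' @param seed Integer seed for the ground truth and all derived trials.
#' @return A `synthetic_ground_truth`: list with `W_star`, `C_star` and the
#'   parameters.
#' @export
synthetic_ground_truth <- function(m = 6, n = 2, t = 160, pair_angle = 60,
                                   sigma_W = 0, sigma_C = 0, noise_sd = 0,
                                   seed = 1) {
  stopifnot(sigma_W >= 0, sigma_C >= 0, noise_sd >= 0)
  structure(list(
    W_star = make_synergy_space(m, n, pair_angle, seed = derive_seed(seed, 101L)),
    C_star = make_commands(n, t, seed = derive_seed(seed, 202L)),
    m = m, n = n, t = t, pair_angle = pair_angle,
    sigma_W = sigma_W, sigma_C = sigma_C, noise_sd = noise_sd,
    seed = as.integer(seed)),
    class = "synthetic_ground_truth")
}

#' Generate one synthetic trial from a ground truth
#'
#' Forward model `M = clip0( perturb(W*) %*% perturb(C*) + noise )`:
#' the synergy columns get additive Gaussian perturbations of scale
#' `sigma_W` (clipped at zero, then renormalized to unit columns); command
#' rows get additive Gaussian perturbations of scale `sigma_C`, temporally
#' smoothed to the command bandwidth (Gaussian kernel, SD 4% of the
#' window) so the perturbed drive stays a plausible slow envelope rather
#' than per-sample noise, then clipped at zero; Gaussian observation noise
#' of scale `noise_sd` is added before a final clip at zero —
#' rectified-EMG envelopes are non-negative. Fully deterministic given
#' `(gt$seed, trial_index)`.
#'
#' @param gt A [synthetic_ground_truth()].
#' @param trial_index Positive integer identifying the trial.
#' @return An [activation_matrix()] (rate 1000 Hz).
#' @export
make_trial <- function(gt, trial_index) {
  stopifnot(inherits(gt, "synthetic_ground_truth"), trial_index >= 1L)
  with_seed(derive_seed(gt$seed, 1000L + trial_index), {
    W <- gt$W_star + matrix(rnorm(gt$m * gt$n, sd = gt$sigma_W), gt$m, gt$n)
    W[W < 0] <- 0
    norms <- sqrt(colSums(W^2))
    norms[norms < 1e-12] <- 1
    W <- sweep(W, 2L, norms, "/")
    E_C <- matrix(rnorm(gt$n * gt$t), gt$n, gt$t)
    E_C <- t(apply(E_C, 1L, smooth_unit_sd, kernel_sd = 0.04 * gt$t))
    C <- gt$C_star + gt$sigma_C * matrix(E_C, nrow = gt$n)
    C[C < 0] <- 0
    M <- W %*% C + matrix(rnorm(gt$m * gt$t, sd = gt$noise_sd), gt$m, gt$t)
    M[M < 0] <- 0
    activation_matrix(M, rate = 1000, window = c(40, gt$t))
  })
}

#' Generate a synthetic participant with a skill profile
#'
#' Emulates the contrast observed between participants of different balance
#' skill: skilled responders reuse an almost fixed, tightly coordinated
#' region of synergy space while varying the neural command per trial;
#' unskilled responders wander across a wider synergy space with more
#' stereotyped commands. Profile defaults (normalized-EMG units, angle in
#' degrees):
#'
#' * `skilled`:   `sigma_W = 0.05`, `sigma_C = 0.35`, `pair_angle = 30`
#' * `unskilled`: `sigma_W = 0.30`, `sigma_C = 0.05`, `pair_angle = 75`
#'
#' Both use `noise_sd = 0.02`. Any parameter can be overridden.
#'
#' @param profile `"skilled"` or `"unskilled"`.
#' @param p Trials per participant (default 5).
#' @param m,n,t Geometry of each trial (defaults 6 muscles, 2 synergies,
#'   160 samples).
#' @param seed Integer seed.
#' @param sigma_W,sigma_C,pair_angle,noise_sd Optional overrides of the
#'   profile defaults.
#' @return List with `trials` (list of p [activation_matrix()]),
#'   `ground_truth`, and `profile`.
#' @export
make_participant <- function(profile = c("skilled", "unskilled"), p = 5,
                             m = 6, n = 2, t = 160, seed = 1,
                             sigma_W = NULL, sigma_C = NULL,
                             pair_angle = NULL, noise_sd = NULL) {
  if (!is.character(profile) || !profile[1L] %in% c("skilled", "unskilled"))
    stop_synergy("unknown profile '%s'", as.character(profile[1L]),
                 class = "invalid_parameter")
  profile <- match.arg(profile)
  if (p < 2L) stop_synergy("p >= 2 trials required", class = "invalid_parameter")
  defaults <- switch(profile,
    skilled   = list(sigma_W = 0.05, sigma_C = 0.35, pair_angle = 30),
    unskilled = list(sigma_W = 0.30, sigma_C = 0.05, pair_angle = 75))
  gt <- synthetic_ground_truth(
    m = m, n = n, t = t,
    pair_angle = if (is.null(pair_angle)) defaults$pair_angle else pair_angle,
    sigma_W = if (is.null(sigma_W)) defaults$sigma_W else sigma_W,
    sigma_C = if (is.null(sigma_C)) defaults$sigma_C else sigma_C,
    noise_sd = if (is.null(noise_sd)) 0.02 else noise_sd,
    seed = seed)
  list(trials = lapply(seq_len(p), make_trial, gt = gt),
       ground_truth = gt, profile = profile)
}

#' Generate a synthetic training schedule
#'
#' Emulates a participant improving over balance-training sessions: the
#' generator parameters are interpolated linearly from the unskilled
#' profile (session 1) to the skilled profile (last session) — cross-trial
#' synergy variability `sigma_W` shrinks, command variability `sigma_C`
#' grows, and the synergy pair angle tightens. Each session is an
#' independent cohort of `p` trials with its own derived seed.
#'
#' @param n_sessions Number of training sessions (>= 2).
#' @param p Trials per session.
#' @param m,n,t Trial geometry.
#' @param seed Integer seed.
#' @return List of length `n_sessions`; each element as returned by
#'   [make_participant()] plus a `session` number.
#' @export
make_training_cohort <- function(n_sessions = 5, p = 5, m = 6, n = 2,
                                 t = 160, seed = 1) {
  if (n_sessions < 2L)
    stop_synergy("need at least 2 sessions", class = "invalid_parameter")
  sw <- seq(0.30, 0.05, length.out = n_sessions)
  sc <- seq(0.05, 0.35, length.out = n_sessions)
  ang <- seq(75, 30, length.out = n_sessions)
  lapply(seq_len(n_sessions), function(s) {
    part <- make_participant("unskilled", p = p, m = m, n = n, t = t,
                             seed = derive_seed(seed, 9000L + s),
                             sigma_W = sw[s], sigma_C = sc[s],
                             pair_angle = ang[s])
    part$session <- s
    part
  })
}

# Smooth a noise series with a Gaussian kernel (circular convolution would
# wrap the burst structure, so plain truncated convolution with edge
# renormalization is used) and rescale to unit standard deviation, so the
# caller's sigma keeps its meaning after smoothing.
smooth_unit_sd <- function(x, kernel_sd) {
  t_len <- length(x)
  half <- max(1L, ceiling(3 * kernel_sd))
  k <- exp(-((-half:half)^2) / (2 * kernel_sd^2))
  y <- vapply(seq_len(t_len), function(i) {
    lo <- max(1L, i - half); hi <- min(t_len, i + half)
    kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    sum(x[lo:hi] * kk) / sum(kk)
  }, numeric(1))
  s <- sd(y)
  if (s < 1e-12) y else y / s
}
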