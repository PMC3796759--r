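---
title: "Methods: per-trial muscle-synergy extraction and the stability/coordination indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-trial muscle-synergy extraction and the stability/coordination indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergystab)
```

## The model

Surface EMG of `m` muscles over `t` samples is collected into a
non-negative activation matrix `M` (m x t). The muscle-synergy model
factorizes it as

```
M = W C + E,     W >= 0 (m x n),  C >= 0 (n x t),  n < m
```

with each synergy vector (column of `W`) scaled to unit Euclidean norm and
the commands (rows of `C`) carrying the corresponding magnitude. `W` spans
the *synergy space* — the fixed muscle groupings the nervous system
composes — and `C` is the time-varying neural drive of each grouping.
Unlike the common practice of factorizing trial-averaged EMG, this package
factorizes **each trial separately**, because the scientific questions it
serves are about the *consistency* of the synergy space across repeated
behaviors, which averaging would erase.

Reconstruction quality is scored per muscle and averaged:

```
L = 100 * (1 - (1/m) * sum_i  mean_j E_ij^2 / mean_j M'_ij^2),   M' = W C
```

The per-muscle normalization makes `L` sensitive to quiet muscles being
reconstructed badly, not only to the overall Frobenius error. `L = 100`
only for an exact reconstruction. The synergy-space dimension is chosen as
the smallest `n` whose best-of-restarts `L` exceeds a threshold, 75 by
default; the threshold is configurable so its influence can be examined.

## The three indices

With `p` trials decomposed at a common `n`, NMF leaves the column order
arbitrary, so trials are first aligned: trial 1 is the reference and each
other trial's columns are permuted to maximize the summed Pearson
correlation with the reference synergies. The search enumerates all `n!`
permutations (exact for the small `n` in play; ties go to the
lexicographically smallest permutation), and the chosen permutation is
applied to both `W`'s columns and `C`'s rows so their pairing stays
coherent. One permutation per trial (rather than one per synergy index) is
used precisely to preserve that pairing.

* **SSI** — mean over synergies of the mean pairwise Pearson correlation of
  matched synergy vectors over all unordered trial pairs. 1 means the same
  synergy space in every trial.
* **SSI_c** — the same statistic over the matched command rows; 1 means
  identical neural drives in every trial.
* **SCI** — mean pairwise inner product of the unit synergy columns within
  one trial, reported per trial with mean and SD. 1 means coincident
  synergy vectors (smallest possible synergy space), 0 means mutually
  orthogonal ones (largest).

The pairwise sums in all three definitions are read as **unordered** pairs
with prefactor `2/(p(p-1))` (equivalently `2/(n(n-1))`): only this reading
makes the identical-vector cases equal exactly 1, which the index ranges
require. Pearson values are not clipped; on adversarial inputs SSI or
SSI_c can fall below 0, and the package warns rather than silently
clamping, since the nominal [0, 1] range presumes matched non-negative
synergies.

The Pearson coefficient is implemented directly from its definition with
population standard deviations in the denominator; this is algebraically
identical to the usual sample coefficient, and the tests cross-check it
against `stats::cor`.

## Preprocessing

The chain is rectification, zero-phase low-pass filtering, experiment-wide
amplitude normalization, and trigger-locked windowing, with defaults
matching a lateral-perturbation posture protocol: 1 kHz sampling, 32 Hz
cutoff, a 160 ms analysis window starting 40 ms after platform onset (the
automatic-posture-response latency), six muscles.

Choices made where the procedure was open:

* **Filter design.** A 4th-order Butterworth applied forward-backward
  (`signal::filtfilt`). Zero-phase filtering is essential because a causal
  filter would delay the envelope and shift activity out of the short
  analysis window. `filtfilt` starts each pass from rest, so the signal is
  odd-reflection padded by about three filter time constants
  (`3 * order * rate / cutoff` samples) before filtering; without the pad
  even a constant channel comes back distorted at the edges.
* **Normalization.** Each muscle is divided by the maximum of its
  processed envelope over *all* trials of the experiment, so 1 means "this
  muscle's strongest activation seen anywhere in the session" and
  cross-trial amplitude comparisons stay meaningful. An alternative
  reading — dividing by the mean across trials of the per-trial maxima —
  is selectable (`method = "mean_of_trial_max"`); it changes only the
  per-muscle scale, not any correlation-based index.
* **Windowing.** A fixed observed latency rather than a per-trial onset
  detector, with half-open sample intervals `[start, start + t)`. Tiny
  negative excursions introduced by filtering a rectified signal are
  clipped at zero when the window is cut, since the factorization requires
  non-negative input.

## Factorization: numerical choices

Lee-Seung multiplicative updates on the squared Frobenius objective, the
canonical algorithm for this model. The residual is non-increasing under
these updates (a property the tests verify step by step). Specifics:

* initialization uniform in (0, 1]; 20 restarts by default, best L kept;
* convergence when the relative residual change drops below 1e-6, capped
  at 2000 iterations;
* denominators floored at 1e-12 to avoid division by zero;
* all randomness flows from one integer seed through a deterministic
  child-seed derivation per (trial, dimension, restart), so any analysis
  is bit-reproducible;
* L is undefined (an error) when a reconstructed muscle row is identically
  zero — a genuinely silent muscle carries no reconstruction information
  and normalized EMG of recorded muscles never does this.

## The synthetic-data generator

The generator exists so that every stage has a ground truth: it draws a
true synergy space `W*`, true burst-like commands `C*`, and per-trial
variability, then assembles `M = clip0(perturb(W*) perturb(C*) + noise)`.

* `make_synergy_space` constructs non-negative unit columns with an
  *exact* common pairwise angle by mixing a shared random direction with a
  private coordinate axis per synergy (`cos^2 a = cos(theta)`), so the SCI
  of the truth is `cos(theta)` by construction. Angles strictly between 0
  and 90 degrees need one spare coordinate (`m > n`).
* `make_commands` draws one Gaussian burst per synergy with width 4-9% of
  the window (a few tens of ms at 1 kHz) and centers staggered across the
  window, mirroring sequential recruitment during a posture response.
  Staggering is deliberate: coincident bursts would make the trial nearly
  rank-one and the true dimension unidentifiable, defeating the
  generator's purpose as ground truth.
* Perturbations are additive Gaussian, clipped at zero (rectified
  envelopes are non-negative): scale `sigma_W` on synergy columns (then
  renormalized), `sigma_C` on command rows, `noise_sd` on the assembled
  matrix. The command perturbation is temporally smoothed (Gaussian
  kernel, SD 4% of the window, rescaled to unit SD) before scaling:
  neural-drive variability lives at the command timescale, and per-sample
  white noise on `C` would instead raise a flat baseline that drags every
  trial toward rank one.

Skill profiles encode the qualitative contrast between good and poor
balance responders — a fixed, tightly coordinated synergy space with
variable commands versus a wandering, wide synergy space with stereotyped
commands:

| profile   | sigma_W | sigma_C | pair angle | noise_sd |
|-----------|---------|---------|------------|----------|
| skilled   | 0.05    | 0.35    | 30 deg     | 0.02     |
| unskilled | 0.30    | 0.05    | 75 deg     | 0.02     |

These values were fixed once as plausible normalized-EMG scales: `sigma_W
= 0.05` leaves synergy vectors correlated near 0.99 across trials while
`0.30` drops them toward 0.5-0.7; the angles bracket the cosine range
0.26-0.87 so the SCI contrast is unambiguous. `make_training_cohort`
interpolates linearly from the unskilled to the skilled parameter set
across sessions, emulating consolidation through training.

What the generator does **not** emulate: motor-unit action potentials,
electrode crosstalk, fatigue drift, trial-to-trial latency jitter, or any
platform dynamics. Passing tests on this generator show the *pipeline*
recovers what it is supposed to recover under the stated forward model;
they are not evidence about any particular recorded dataset.

## Pipeline conventions

* The common dimension for a participant is the smallest `n` whose L
  exceeds the threshold **in every analyzed trial** — this guarantees each
  trial individually meets the fit criterion. (The alternative, a
  mean-L-across-trials rule, is weaker: one badly fit trial could hide
  behind the average.) If no `n < m` qualifies, `m - 1` is reported with
  an explicit flag.
* Trials are filtered to a single balance-score level (+1 by default) and
  truncated to the first five, so heterogeneous response strategies are
  not mixed within one ensemble; scores are consumed as data, never
  computed.
* Index-versus-score and index-versus-session relations use plain
  least-squares lines and Pearson r, with no multiple-testing correction —
  the outputs are descriptive trends, not hypothesis tests.

## Problem sizes used in the test suite

The suite exercises the full geometry of the motivating protocol — 6
muscles, 160-sample windows, 5 trials per participant, dimension 2 — with
Monte-Carlo checks at 20 replicates and 4-10 NMF restarts per fit, sizes
chosen so the complete suite runs in about a minute while leaving the sign
tests enough replicates to resolve the index contrasts at p < 0.05.

## Worked example

```{r example}
gt <- synthetic_ground_truth(m = 6, n = 2, t = 160, pair_angle = 60,
                             sigma_W = 0.05, sigma_C = 0.10,
                             noise_sd = 0.05, seed = 42)
trials <- lapply(1:5, make_trial, gt = gt)
report <- run_participant(trials, threshold = 75, restarts = 10,
                          seed = 42, id = "S1")
report
compute_sci(gt$W_star)   # truth: cos(60 deg) = 0.5
```

## Known limitations

* Time-invariant synergies only; time-varying (waveform) synergy models
  are out of scope.
* The matching step is exact but factorial in `n`; fine for `n <= 6`,
  not meant for high-dimensional factor models.
* SSI/SSI_c compare trials within one participant and dimension; the
  package does not cluster or match synergies across participants.
* L is undefined when a reconstructed muscle row is exactly zero; such
  channels should be excluded before analysis.
* Because L normalizes per muscle, a channel that is quiet in a given
  trial keeps L low at *every* candidate dimension, and automatic
  dimension selection can then run up to its `m - 1` fallback. The
  statistic is doing its job — it refuses to call a fit good while a
  muscle is badly reconstructed — but it means AUTO selection presumes
  all recorded muscles participate meaningfully in the response, as they
  do after experiment-wide normalization of muscles chosen for the task.
  Extreme synthetic profiles (large `sigma_W` with clipping) can violate
  this; analyses of such cohorts should fix `n` explicitly.
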