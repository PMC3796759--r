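# synergystab

Muscle-synergy stability and coordination analysis of multichannel surface
EMG, built for posture-control experiments in which the same rapid motor
response (for example the automatic posture response to a sudden platform
displacement) is recorded over repeated trials. It is aimed at motor
neuroscientists and rehabilitation researchers who want to quantify not
just *which* muscle synergies a participant uses, but *how consistently*
they reuse them.

## The method

Each trial's preprocessed EMG is an `m x t` non-negative activation matrix
`M` (default geometry: 6 muscles, a 160 ms window at 1 kHz starting 40 ms
after the perturbation). Every trial is factorized separately,

    M = W C + E,    W ∈ R^(m×n)₊ with unit-norm columns,  C ∈ R^(n×t)₊,  n < m

by Lee–Seung multiplicative-update NMF with random restarts.
Reconstruction quality is the per-muscle similarity

    L = 100 · (1 − (1/m) Σᵢ  meanⱼ E²ᵢⱼ / meanⱼ M′²ᵢⱼ),    M′ = W C,

and the synergy-space dimension is the smallest `n` with `L > 75` in every
trial. After aligning synergies across the `p` trials (exact search over
column permutations maximizing Pearson correlation with the first trial),
three indices summarize the participant:

* **SSI** = (1/n) Σᵢ [ 2/(p(p−1)) Σ_{l<q} r(W_l⁽ⁱ⁾, W_q⁽ⁱ⁾) ] — stability
  of the synergy space across trials (1 = identical synergies every time);
* **SSI_c** — the same statistic over the matched command rows of `C`;
* **SCI** = 2/(n(n−1)) Σ_{i<j} W⁽ⁱ⁾·W⁽ʲ⁾ — size of the synergy space
  (1 = coincident synergy vectors, 0 = orthogonal).

Skilled balance responders typically show high SSI and SCI with low SSI_c
— a fixed, tightly coordinated synergy space driven by flexible commands —
and the package's pipeline relates the indices to balance scores and
training sessions by least-squares trends. A synthetic-EMG generator with
known ground truth (`make_participant`, `make_training_cohort`) makes the
whole pipeline verifiable without recorded data.

## Worked example

```r
library(synergystab)

gt <- synthetic_ground_truth(m = 6, n = 2, t = 160, pair_angle = 60,
                             sigma_W = 0.05, sigma_C = 0.10,
                             noise_sd = 0.05, seed = 42)
trials <- lapply(1:5, make_trial, gt = gt)
report <- run_participant(trials, threshold = 75, restarts = 10,
                          seed = 42, id = "S1")
report
#> <participant_report> S1 5 trials, n = 2
#>   L: 86.5, 88.9, 83.6, 90.2, 84.5
#>   SSI = 0.981  SSI_c = 0.888  SCI = 0.457 +/- 0.014
compute_sci(gt$W_star)
#> [1] 0.5
```

Reading the output: dimension selection tried `n = 1` (trial-wise L
67.7/64.1/48.8/71.1/63.6, below threshold) and settled on `n = 2`, where
every trial fits above 75. The five trials share almost the same synergy
space (SSI = 0.98, the generator perturbed the true synergies only by
σ_W = 0.05), the commands are more variable (SSI_c = 0.89 with σ_C = 0.10),
and the estimated synergy-space size SCI = 0.457 ± 0.014 recovers the
ground truth cos 60° = 0.5 to within the perturbation noise.

A thin CLI covers simulation and analysis from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","synergystab-cli.R",package="synergystab"))')" \
    simulate --profile skilled --participants 1 --trials 5 --seed 3 -o simdemo/
# then: ... run --n 2 --seed 3 -o report.json simdemo/p01_trial0*.csv
```

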