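Package: synergystab
Title: Muscle-Synergy Stability and Coordination Analysis of Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts muscle synergies from multichannel surface EMG by
    per-trial non-negative matrix factorization (Lee-Seung multiplicative
    updates), scores reconstructions with a per-muscle similarity index L,
    and selects the synergy-space dimension as the smallest giving L above
    a threshold. Quantifies how consistently a participant reuses the same
    synergy space across repeated trials (synergy stability index, SSI),
    the analogous stability of the neural commands (SSI_c), and the size of
    the synergy space via mean pairwise inner products of the unit synergy
    vectors (synergy coordination index, SCI). Includes an EMG preprocessing
    chain (rectification, zero-phase low-pass filtering, experiment-wide
    normalization, perturbation-locked windowing), a synthetic-EMG cohort
    generator with known ground truth, and a pipeline relating the indices
    to balance scores and training sessions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
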