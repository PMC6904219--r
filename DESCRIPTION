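Package: fidelitylink
Title: Linking Spectral Power to Single-Trial Pattern Fidelity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking trial-by-trial alpha/beta spectral power to the
    fidelity of stimulus-specific information carried by multivoxel activity
    patterns. Implements cross-validated Mahalanobis (crossnobis) searchlight
    representational similarity analysis with Ledoit-Wolf diagonal shrinkage,
    a single-trial stimulus-information statistic for perception and memory
    reinstatement, Morlet wavelet time-frequency power with z-baselining,
    IRASA fractal/oscillatory spectral decomposition with 1/f slope fitting,
    per-participant power-information regression, sign-flip and cluster-based
    permutation inference, and JZS Bayes factors. A synthetic-data generator
    with known ground truth (trial tables, voxel patterns with latent
    per-trial fidelity, coupled trial power, 1/f + oscillatory
    electrophysiology) supports end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
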