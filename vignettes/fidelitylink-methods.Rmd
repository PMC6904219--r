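---
title: "Linking spectral power to single-trial pattern fidelity: methods"
author: "fidelitylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking spectral power to single-trial pattern fidelity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidelitylink)
```

## The scientific question

Alpha/beta (8–30 Hz) power decreases are among the most reliable
electrophysiological signatures of task engagement. One influential account
holds that these desynchronisations are not an epiphenomenon but index the
fidelity with which cortex represents stimulus-specific information: the
deeper the power decrease on a trial, the sharper the multivoxel activity
pattern for the stimulus on that trial, both during perception and during
memory reinstatement. Testing this requires (i) a *single-trial* measure of
stimulus-specific information from fMRI activity patterns, (ii) a
single-trial measure of spectral power, and (iii) a within-participant
regression that links the two while controlling for confounds, followed by
group-level nonparametric inference.

`fidelitylink` implements this analysis chain end to end, together with a
synthetic-data generator with known ground truth so every stage — and the
pipeline as a whole — can be validated by simulation.

## Pattern estimation (GLM)

Voxel time-series are modelled by ordinary least squares against an
HRF-convolved design. Each event is a boxcar spanning the stimulus duration
(3 s by default, matching a short dynamic video at TR = 2 s), built on a
fine grid of TR/16 and convolved with the canonical double-gamma HRF
(response peak 6 s, undershoot 16 s, ratio 1:6 — the de-facto standard
parameterisation). `build_design_matrix()` supports one regressor per
condition or one per trial; the trial-wise variant is a least-squares-all
(LSA) design — a single model with one column per trial — rather than
least-squares-single, because LSA is exact in the noiseless limit and keeps
the residuals well-defined for covariance estimation. Residuals from
`estimate_betas()` feed the noise-covariance estimate below; no
autocorrelation modelling (prewhitening) is attempted, and run-wise means
are absorbed by the intercept column.

## Cross-validated Mahalanobis (crossnobis) distances

Representational distances between conditions $j$ and $k$ measured in two
independent folds A and B are computed as

$$d(j,k) = (\hat u_{jA} - \hat u_{kA})^\top \Sigma^{*-1}
           (\hat u_{jB} - \hat u_{kB}),$$

averaged over the two fold assignments (the two terms coincide for a
symmetric $\Sigma^*$). Because the noise in the two contrast estimates is
independent, $E[d] = 0$ when the conditions do not differ, and negative
estimates are legitimate; this unbiasedness is what makes the statistic
usable in small searchlights. Distances are not normalised by voxel count:
all downstream use is rank-based, hence scale-invariant.

$\Sigma^*$ is the residual covariance shrunk towards its diagonal,
$\Sigma^* = (1-\lambda) S + \lambda\,\mathrm{diag}(S)$, with the
analytically optimal (Ledoit–Wolf-type) weight
$\lambda = \sum_{i \ne j}\widehat{\mathrm{Var}}(s_{ij}) \big/
\sum_{i \ne j} s_{ij}^2$, clipped to $[0,1]$. The result is
positive-definite even with fewer residual samples than voxels. The
covariance source is GLM residuals (rather than condition-demeaned
patterns); this is exposed implicitly through what the caller passes to
`shrink_covariance()`.

## Searchlights and information maps

`build_searchlights()` collects, for each in-mask voxel, all in-mask voxels
within an inclusive Euclidean radius. On the default 3 × 3 × 4 mm grid a
10 mm radius yields exactly 121 voxels — the stencil is derived
analytically from the spacing — and centres retaining fewer than 60% of
that full count (spheres protruding outside the brain) are discarded.
Membership is symmetric, so dilating a cluster of centres by
`dilate_roi()` (the union of their searchlights) recovers every voxel that
contributed to the cluster's statistic.

At each centre, `searchlight_information_map()` correlates the crossnobis
distances among fold-wise condition patterns with a binary model RDM — 0
for same-stimulus pairs, 1 for different-stimulus pairs — using Spearman's
correlation (the model is ordinal, and ties are handled by average ranks,
i.e. Pearson on ranks), then applies the Fisher z-transform
($z = \operatorname{atanh}\rho$, with $|\rho|$ clipped to $1 - 10^{-10}$ so
$z$ stays finite). **Sign convention:** the model assigns *larger* values
to *different*-stimulus pairs, so structured patterns (same-stimulus
distances smallest) give $\rho > 0$; higher $z$ always means more
stimulus-specific information. Same-condition cross-fold pairs are included
in the correlation (their crossnobis distance vanishes identically, which
is exactly the model's prediction of zero); within-fold self-pairs are not.

Group-level map inference uses a voxelwise one-sample t-test with a
cluster-forming threshold and sign-flip max-cluster-mass permutation
correction (`cluster_permutation_test()` with a lattice adjacency) rather
than random-field theory: the permutation scheme is assumption-light,
exactly valid under sign symmetry, and is the same machinery used for the
electrophysiological feature maps.

## Single-trial information

`perception_trial_information()` scores each trial by the Mahalanobis
distances (under the shrunk training-fold covariance, which plays the role
of the discriminant weighting) from that trial's pattern to every pattern
in the *other* fold only, so trial and comparison noise never mix. The
distances are rank-correlated with the trial's own binary model (0 = same
stimulus as the trial, 1 = different) and Fisher z-transformed:
$z_{\text{info}} = \operatorname{atanh}\rho$, positive for informative
trials. Because the binary model is heavily tied, $|\rho|$ is capped below
1 even under perfect separation; `tie_limited_rho_max()` returns this
ceiling in closed form (for $m$ matching among $n$ comparisons, the Pearson
correlation of the perfectly separated average-rank vector with the model).

`retrieval_trial_information()` does the same for memory reinstatement:
distances from each single *remembered* retrieval trial to the perception
patterns, against the model that perception patterns of the retrieved
stimulus are near and all others far. Restricting to remembered trials is
essential — mixing remembered and forgotten trials would let memory-related
differences in both power and information masquerade as a trial-wise
coupling. A variant including forgotten trials exists behind
`include_forgotten = TRUE` but is off the headline path. Trials whose
statistic is undefined are returned as `NA` and are dropped (never imputed)
by the regression stage.

## Time–frequency power and IRASA

`morlet_tfr()` convolves each epoch with complex Morlet wavelets,
$\sigma_t = n_{\text{cycles}}/(2\pi f)$, unit energy, 6 cycles by default,
on the default grid 8–30 Hz in 0.5 Hz steps and −1 to 3 s in 25 ms steps.
Wavelets are truncated at ±5σ (truncation error below $10^{-5}$ of the
peak response); samples whose 3σ support crosses the epoch edge are flagged
invalid rather than mirror-padded, because all analysis windows avoid the
edges. The power of a unit sinusoid at the wavelet's centre frequency has
the closed form $\sigma_t \sqrt{\pi} / 2$, which the tests use as an
analytic oracle.

`baseline_ztransform()` z-scores power per electrode × frequency using the
mean and SD pooled over *all* time points and trials jointly, and
`band_window_average()` collapses to one value per trial — post-stimulus
(500–1500 ms) and pre-stimulus (−1000 to −375 ms) alpha/beta power in the
headline analysis; theta (3–7 Hz) or gamma (40–50 Hz) specificity controls
are the same code path with a different band argument. Re-applying the
z-transform is blocked by a state flag (though the operation is
algebraically idempotent).

`irasa_decompose()` separates each power spectrum into a fractal (1/f,
aperiodic) and an oscillatory component by irregular resampling: for each
factor $h$ in 1.1, 1.15, …, 1.9 (the published default set) the signal is
resampled by $h$ and $1/h$ (rational-factor polyphase resampling), the
geometric mean of the pair's Welch spectra leaves a power law untouched
while displacing narrowband peaks to $fh$ and $f/h$, and the median across
the $h$ set estimates the fractal spectrum. The oscillatory spectrum is the
residual (original − fractal), so the two components sum to the original by
construction. The 1/f slope and intercept come from least squares on
$\log_{10}$ PSD versus $\log_{10} f$ over 1–25 Hz (configurable), and
oscillatory band power is the mean oscillatory PSD over 8–25 Hz; the upper
limit respects the maximum derivable frequency, which the implementation
computes as $f_s / (2 h_{\max})$ — about a quarter of the sampling rate —
rather than hard-coding a value. Welch spectra use Hann windows with 50%
overlap; the default segment is $\min(1\text{ s}, T/h_{\max})$ so the most
heavily downsampled copy of an epoch of length $T$ still fits one segment.

`epoch_length_reliability()` quantifies how stable the fitted slope is as a
function of epoch length by simulating coloured noise at a known exponent:
short (~1 s) epochs give slope SDs an order of magnitude larger than 60 s
epochs, which is why condition-average spectra, not single short trials,
should feed 1/f conclusions.

## Linking power to information

`fit_link_regression()` regresses per-trial $z_{\text{info}}$ on four
z-scored predictors — post-stimulus power plus three confound regressors:
pre-stimulus power, BOLD amplitude, and confidence rating — and reports the
t-value of each ($\hat\beta / \mathrm{SE}$), which standardises effects
across regressors and participants. A median-split mode replaces the
continuous power regressor with a 0/1 above-median indicator as a
robustness check. Group inference contrasts the per-participant t-values
against zero with `group_permutation_ttest()`: sign-flipping, one-tailed
(left — a *negative* power–information relation is the directional
hypothesis), 2000 randomisations by default, with the +1 correction
$(b+1)/(m+1)$ that keeps sampled permutation p-values valid; for 12 or
fewer participants the full $2^n$ enumeration is used instead (exact).
Participants need at least 10 remembered and 10 forgotten trials
(`meets_inclusion_rule()`) to enter group analyses.

`confidence_power_correlation()` guards the confidence confound from the
other side: Spearman correlation (the ratings are ordinal 1–4; the
coefficient choice is ours) between power and confidence, Fisher
z-transformed per participant. `jzs_bayes_factor()` supplies evidence *for
the null* where the frequentist tests cannot: the default-prior
(Jeffreys–Zellner–Siow) Bayes factor for a one-sample t-test, Cauchy prior
scale $r = \sqrt{2}/2$ by default, computed by adaptive quadrature over the
mixing variable with the integrand evaluated in log space (the tails
underflow cleanly instead of producing `Inf × 0`); an independent
fixed-grid Simpson quadrature serves as the test oracle.

## The synthetic-data generator

The generator reproduces the statistical skeleton of a paired-associates
EEG-fMRI study, not its physiology:

* **Trial tables** (`make_trial_table()`): 4 blocks × 48 trials × 4
  stimuli by default, so each stimulus repeats 12 times per block; blocks
  alternate visual/auditory; a pair is *remembered* iff the response was
  correct and confidence exceeded 1 (rating 1 = "guess"). The default
  memory rate is 0.634, a typical group-mean recall level for this kind of
  paradigm.
* **Prototypes** (`make_stimulus_prototypes()`): stimulus patterns at the
  vertices of a regular simplex — equal norms, all pairwise distances
  exactly equal — randomly oriented in voxel space.
* **Fidelity**: per-trial pattern quality $f_t \in [0,1]$, Beta-distributed
  by moments (`draw_fidelity()`, default mean 0.5, SD 0.2). A Beta prior is
  bounded like a fidelity should be and covers the restricted-variance
  regime in which observed power–information correlations are strongly
  attenuated. The true distribution of trial-wise fidelity in real data is
  unknown; this is a modelling choice, exposed in the arguments.
* **BOLD forward model** (`simulate_bold_session()`): voxel signal
  $\sum_t f_t\,\mu_{s(t)}$ under the boxcar-convolved HRF plus temporally
  white, spatially correlated Gaussian noise (exponential spatial decay,
  `make_noise_cov()`). The same design-matrix code used for estimation
  generates the data, so GLM round-trip tests are exact in the noiseless
  limit.
* **Trial power** (`simulate_trial_power()`):
  $\text{post}_t = a - \beta f_t + \gamma_c \text{conf}_t +
  \gamma_b \text{bold}_t + \varepsilon_t$; pre-stimulus power is
  independent of fidelity by construction; confidence is an ordinal 1–4
  rating from quartile-thresholding a latent Gaussian correlated with
  fidelity (default latent correlation 0.3), so the confidence-confound
  pathway is testable.
* **Electrophysiology** (`simulate_eeg_epochs()`): coloured noise with PSD
  $\propto f^{-\chi}$, synthesised by scaling the FFT of white noise by
  $f^{-\chi/2}$ with the DC bin zeroed (exactly controllable), plus a
  random-phase sinusoid of known frequency and amplitude.

**Moderate-settings design.** The end-to-end validation uses 21
participants with 100 remembered trials each and fidelity SD 0.2. The
remaining knobs — prototype separation 3, voxel noise SD 1, coupling
$\beta = 1$, power noise SD 0.35 — were fixed once, by a design analysis
targeting a per-participant regression t of about −1 (group
$d_z \approx 0.9$, comparable to reliably detectable effects in studies of
this size), with single-trial pattern SNR kept realistically low (signal
norm roughly a quarter of the noise norm). Trial information is computed
against *trial-level* perception patterns (12 per stimulus per fold), not
condition averages, matching how single retrieval trials are compared with
all perception trials in practice.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: haemodynamic nonlinearity and saturation, scanner
drift and physiological noise, temporal autocorrelation of fMRI noise,
EEG–MRI artifacts and their correction, volume conduction and source
leakage, and any systematic relation between fidelity and the aperiodic
spectrum. Results on synthetic data validate the *statistical machinery*,
not the neuroscience.

## Validation design and problem sizes

The packaged validation suite (and `scripts/acceptance.R`) uses problem
sizes chosen to make Monte-Carlo error small relative to the quantities
checked while keeping a full run in the minutes range:

* Null calibration of the searchlight map test uses 500 simulated groups of
  24 subjects on a 5 × 5 × 3 mask (radius 5 mm). Twenty-four subjects is
  deliberate: per-subject map values are coarsely discrete (Spearman over
  ten heavily tied pairs), and below roughly 20 subjects the voxelwise
  t-test is visibly conservative; at 24 the nominal level holds.
* The sign-flip group test is calibrated on 2000 null draws of 12
  participants (the exact-enumeration branch), the cluster test on 500
  null 8 × 8 feature maps (250 inner permutations), and the
  confidence-correlation test on 1000 null groups.
* Pipeline power and false-positive rates use 60 replicate studies each;
  1/f reliability uses 60 replicates per epoch length at 200 Hz.

## Numerical choices

* Fisher z clipping at $|\rho| \le 1 - 10^{-10}$; Spearman ties by average
  ranks throughout.
* Permutation p-values: +1 correction when sampled; exact enumeration for
  $n \le 12$; all-zero input returns p = 1 with a warning.
* Collinearity: the link regression refuses condition numbers above
  $10^8$; the GLM names the offending columns via QR pivoting.
* The JZS integrand is evaluated in log space; integration failures raise
  an error with diagnostics rather than returning a number.
* Coloured-noise synthesis zeroes the DC bin; the resampling factors are
  represented as exact rationals on a 1/20 grid.
* Degenerate inputs fail loudly and specifically: zero-variance voxels,
  constant confidence, empty masks, events beyond the scan, frequencies at
  or above Nyquist.

## Known limitations

* The trial-wise GLM is least-squares-all only; with rapid designs and
  heavy regressor overlap least-squares-single can behave differently.
* Searchlights assume a regular grid (no surface-based geometry) and a
  single spacing per session.
* The cluster test's lattice adjacency covers regular feature grids;
  arbitrary sensor-neighbourhood graphs must be supplied by the caller as
  adjacency lists.
* Fixed-effects-free group inference: only the one-sample
  permutation/Bayes machinery is provided, no hierarchical models.
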