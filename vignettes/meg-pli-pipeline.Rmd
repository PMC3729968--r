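---
title: "Resting-state MEG connectivity with the phase lag index: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state MEG connectivity with the phase lag index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megconn)
```

## The analysis this package implements

`megconn` implements a complete resting-state MEG functional-connectivity
analysis of the kind used to compare clinical groups — here, a multiple
sclerosis (MS) patient group against matched healthy controls. The chain is:

1. **Source reconstruction.** Sensor recordings from a whole-head
   magnetometer array are projected into source space with a scalar
   (SAM-type) beamformer built on a homogeneous-sphere head model. Activity
   is summarized per cortical region of interest (ROI) of a 78-region
   AAL-style parcellation by the voxel with maximal power in each frequency
   band.
2. **Connectivity.** Region time series are band-filtered into six canonical
   bands (delta 0.5–4, theta 4–8, alpha1 8–10, alpha2 10–13, beta 13–30,
   gamma 30–48 Hz), instantaneous phases are extracted with the analytic
   signal, and pairwise coupling is quantified with the phase lag index
   (PLI): the absolute time-average of the sign of the wrapped phase
   difference. The PLI is 0 for any symmetric phase-difference distribution
   — including the zero-lag coupling produced spuriously by field spread —
   and 1 for a perfectly consistent non-zero lag, which is why it is the
   metric of choice when volume conduction is a concern.
3. **Summaries.** The per-subject, per-band 78×78 adjacency matrix is
   reduced to node strengths (mean PLI of a region with all others), a
   whole-brain mean, and within-network means for seven literature-based
   resting-state networks (RSNs): default mode, left/right fronto-parietal,
   executive control, sensorimotor, temporo-parietal and visual.
4. **Statistics.** Whole-brain means are compared between groups with
   Mann-Whitney tests; for bands with a whole-brain difference, post-hoc
   per-ROI permutation t-tests and per-RSN Mann-Whitney tests follow;
   band × RSN combinations with group differences are correlated (Spearman)
   with clinical covariates per group, and volumetric covariates are tested
   as effect modifiers in an interaction regression.

Because clinical MEG recordings cannot be shipped, the package carries a
synthetic-cohort generator whose implanted coupling structure makes every
downstream stage testable against known ground truth.

## The synthetic cohort

### Coupling model

Band-limited coupling is simulated as **phase-coupled narrowband
oscillators** rather than coupled dynamical systems (e.g. Kuramoto
networks). A narrowband carrier is synthesized in the frequency domain —
unit-amplitude spectral bins inside the band with uniform random phases —
which yields a stationary oscillation whose instantaneous phase decorrelates
on the band's coherence time (≈ 1/bandwidth). For a coupled ROI pair the
second ROI's phase is the first's minus a lag `lag_delta` (default π/2, the
lag at which the PLI is most sensitive) plus von Mises jitter with
concentration `jitter_kappa`. The expected PLI of such a pair is then a
one-dimensional integral with an obvious brute-force Monte-Carlo oracle
(`pli_vonmises_oracle()`), which is exactly why this model was chosen: the
estimator can be checked against an independent computation.

Two numerical points deserve note:

* **Jitter is held piecewise-constant** for one coherence time
  (`fs / bandwidth` samples) instead of being drawn independently per
  sample. Independent per-sample jitter is spectrally white; the band-pass
  filter of the measurement path would remove it almost entirely and
  silently push every measured PLI toward 1, erasing implanted group
  differences. Holding the draws keeps the jitter inside the band while the
  marginal distribution of the phase difference remains exactly von Mises,
  so the oracle still applies (with the number of independent draws, not
  samples, as the Monte-Carlo n).
* **Each band's oscillation is band-limited at generation** with the same
  spectral mask the measurement path applies. The jitter steps and the
  envelope normalization of the carriers otherwise place sidebands outside
  the nominal band, and those sidebands carry the coupling — enough to
  produce systematic spillover of, say, beta-band group effects into the
  gamma band. Masking the oscillation leaves the in-band content (and hence
  the implanted effects and the oracle phases) untouched while making
  out-of-band leakage exactly zero.
* **Within-RSN coupling is a star** around the network's first member. A
  fully coupled clique cannot be realized with arbitrary pairwise lags (the
  lag assignments are overdetermined), whereas a tree is always consistent.
  Group effects therefore enter the within-RSN mean PLI through the hub-leaf
  pairs; leaf-leaf pairs carry no consistent lag and contribute null-level
  values.

Every ROI additionally receives a unit-variance 1/f background (random-phase
spectral synthesis), and coupled-band oscillations are scaled to a
configurable power ratio against the in-band background power
(`amplitude_snr`, default 5). Sensor projection places one tangential dipole
per ROI at the ROI centroid (the radial component is silent in a spherical
conductor) and adds white Gaussian sensor noise at a configurable SNR
(default 5). Defaults follow the emulated recording protocol: 151
magnetometers at 625 Hz, epochs of 4096 samples (6.5536 s), 5 epochs per
subject, 21 patients and 17 controls.

### Implanted effects and covariates

The default effect specification mirrors the clinical findings the pipeline
is designed to detect: patients receive *weaker* alpha2-band coupling in the
default-mode and visual networks and *stronger* beta-band coupling in the
default-mode and temporo-parietal networks. Group strength is encoded in the
von Mises concentration (control vs patient κ of 2 vs 0.7, and reversed for
beta); each subject's κ is log-normally dispersed around the group value
(SD 0.5), and that same latent deviate drives the covariate links through a
Gaussian copula, making the links rank-preserving by construction.

Covariates are anchored to the descriptive statistics of the emulated
cohort: total thalamic volume 0.021 ± 0.001 L (controls) vs 0.019 ± 0.002 L
(patients), normalized brain volume 1.53 ± 0.07 vs 1.47 ± 0.05 L, gray
matter 0.84 ± 0.05 vs 0.81 ± 0.04 L, cognition z-score 0.04 ± 0.64 vs
−0.19 ± 0.84, EDSS ordinal 0–10 in half steps with patient median 2 (range
0–4.5; controls 0). Thalamic volume is positively linked to alpha2
visual-network coupling; EDSS positively and cognition negatively to beta
default-mode coupling. The default link strength is calibrated for a
population Spearman correlation of 0.58 (latent Pearson
`2 sin(π·0.58/6) ≈ 0.60`), the regime of interest for the
volume-connectivity association.

What the generator does **not** emulate: realistic head anatomy (a single
homogeneous sphere replaces subject MRIs), physiological and environmental
artifacts (cardiac, ocular, muscle — the synthetic data are artifact-free),
eyes-open/eyes-closed spectral differences, 1/f slope heterogeneity across
regions, and amplitude-amplitude coupling. Passing tests therefore
demonstrate that the pipeline recovers the structures it models, not that it
is robust to every pathology of real recordings.

## Forward model and beamformer

The lead field is the closed-form magnetic field of a current dipole in a
homogeneous conducting sphere, projected on each magnetometer normal. Tests
exploit its two structural properties — linearity in the dipole moment and
silence of radial dipoles — and cross-check values against an independent
route (numerical gradient of the magnetic scalar potential).

Beamformer weights follow the minimum-variance unit-gain construction
`w = C⁻¹l / (lᵀC⁻¹l)` with the dipole orientation chosen in the tangential
plane to maximize pseudo-power (the minimum-eigenvalue direction of the
projected 2×2 matrix `LᵀC⁻¹L`). The covariance is estimated from broadband
(0.5–48 Hz) data pooled over all epochs with a 1/n normalization (so
duplicated epochs change nothing), and regularized by diagonal loading,
`C + reg_fraction · mean(diag C) · I` with `reg_fraction = 0.05` by default
— the regularization level and the voxel sampling are configuration, as no
canonical values exist for the emulated setup. "Power" for per-band voxel
selection is the variance of the band-passed series summed over epochs, with
ties broken toward the lowest voxel index.

## Numerical choices in the connectivity stage

* **Filtering** is zero-phase spectral masking (FFT, zero out-of-band bins,
  inverse FFT). This is exactly zero-phase and idempotent; an IIR design at
  the delta band's normalized lower edge (0.5 Hz at 625 Hz sampling) is
  numerically fragile. Epochs must be at least three times the effective
  impulse-response length (3·fs/lo samples), and 1/(2·lo) seconds at each
  epoch edge are excluded from the PLI sample set to suppress wrap-around
  and Hilbert edge effects.
* **Phase** is the argument of the analytic signal per epoch, wrapped to
  (−π, π].
* **PLI** is computed per epoch and then averaged over the first five epochs
  (the epoch policy of the emulated protocol), with sign(0) contributing 0,
  so identical series give exactly 0. The hot pair loop is implemented in
  C++; the cohort-scale path evaluates the sign of the phase difference via
  `sign(Im(a_i · conj(a_j)))` on analytic signals, which is algebraically
  identical away from phase differences of exactly π.
* **Eq.-style RSN mean**: the mean over the N(N−1)/2 unordered within-RSN
  pairs. Node strength excludes the structural zero diagonal (divides by
  n−1); including it would only shrink every value by a constant factor.
* The shipped RSN memberships are best-effort reconstructions from the
  fMRI literature with two conventional adjustments (superior parietal
  gyrus in place of the precuneus in the fronto-parietal networks; inferior
  frontal gyrus split between pars opercularis → temporo-parietal and pars
  triangularis → fronto-parietal), kept mutually disjoint so that
  within-network connections are unique. They are configuration
  (`read_rsn_json()`), not ground truth.

## Statistical battery

`mann_whitney()` reports the exact U with mid-ranks for ties and a
two-sided p (exact for small untied samples, normal approximation with tie
correction otherwise). `permutation_roi_test()` builds the null from
pooled-variance t statistics under label permutation, enumerating all
assignments exhaustively when their number does not exceed `n_perm`
(default 5000) and always including the identity assignment, so p ≥
1/n_permutations; with the two-sided convention the smallest achievable p
for perfectly separated groups of 3+3 is 2/C(6,3), since the observed split
and its label-swapped mirror share the same |t|. The max-statistic
correction is available behind a flag but off by default — per-ROI values
are reported uncorrected, mirroring the exploratory post-hoc character of
the emulated analysis. Spearman correlations use mid-ranks and the
t approximation; normality checks are Lilliefors-type (parameters estimated
from the data), the convention when no a-priori normal parameters exist.
The optional outlier rule for correlation re-runs drops points with
|studentized residual| > 3 from a linear fit — a fixed, logged rule chosen
because no standard exists.

The post-hoc hierarchy is gated: RSN and per-ROI tests run only for bands
whose whole-brain test is significant at α = 0.05, and covariate
correlations only for band × RSN combinations with significant group
differences.

## Validation studies and their problem sizes

Three replicate-level studies back the package's statistical claims; all run
at the source level (generator ROI series → connectivity → statistics). The
forward/inverse stage is validated separately by its own contracts (unit
gain to 1e-8, radial-dipole silence, single-source round-trip correlation
≥ 0.999), so excluding it from the replicate loops changes nothing about
what the loops measure while keeping hundreds of cohorts computable. The
replicate path (`cohort_rsn_pli()`) also evaluates the PLI on a demodulated,
decimated analytic signal: only the in-band spectral bins are
inverse-transformed, at a short length chosen to oversample the band's
envelope at least fourfold. The common frequency shift cancels in the
pairwise conjugate product, so the phase differences entering the PLI are
exact; the sign average simply runs over a coarser (still
envelope-oversampled) time grid than `adjacency()` uses.

* **Type-I calibration of the cohort test** (`calibrate_mann_whitney()`):
  200 null cohorts (no implanted coupling, identical groups) of 21 + 17
  subjects with reduced recordings (4 ROIs, 2 epochs of 512 samples — under
  exchangeability the test level does not depend on these sizes), checked
  against the 99% binomial interval around 0.05.
* **Type-I calibration of the permutation test**
  (`calibrate_permutation_test()`): 200 exchangeable null datasets of
  38 × 10 values, 1000 permutations each, first-ROI rejection rate.
* **Power and link recovery** (`power_study()`): 50 cohorts at the full
  default conditions (21 + 17 subjects, 5 × 4096 samples at 625 Hz),
  restricted to the RSN member ROIs, testing every band × RSN combination
  with ungated Mann-Whitney tests. Implanted combinations must reject in at
  least 80% of replicates and non-implanted ones in at most 10%
  (uncorrected); the patient-group Spearman correlation between thalamic
  volume and alpha2 visual-network PLI must average within ±0.1 of the
  calibrated 0.58.

## Known limitations

* The sphere forward model cannot represent anatomy-specific field
  patterns; conclusions about localization accuracy do not transfer to real
  head models.
* The star coupling topology means within-RSN mean PLI mixes strongly
  coupled (hub) and null (leaf-leaf) pairs; absolute PLI levels are
  therefore lower than a clique would produce, though group contrasts and
  monotonicity in κ are unaffected.
* Brick-wall spectral masks have infinite attenuation in the
  transfer-function sense but finite-epoch spectral leakage bounds the
  achievable stop-band rejection for off-bin tones (≈ −42 dB for a 25 Hz
  tone against the alpha2 band at the default epoch length).
* PLI discards zero-lag physiological coupling by design; simulations with
  `lag_delta = 0` will correctly produce PLI ≈ 0.
* With five epochs per subject the per-pair PLI estimate retains a positive
  finite-sample floor (≈ √(2/(π·n_eff)) for n_eff independent phase
  stretches); group comparisons are unaffected (both groups share the
  floor), but absolute PLI values should not be read as unbiased coupling
  strengths.

## A minimal run

```{r example, eval = FALSE}
cfg <- study_config(n_patients = 21, n_controls = 17, seed = 42)
res <- run_study(cfg, out_dir = "results")
subset(res$tests, p < 0.05 & test == "mann_whitney")
```

The command-line entry point (`inst/cli/megconn.R`) wraps the same call:
`Rscript megconn.R run-all --out results --seed 42`.
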