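# megconn

Resting-state MEG functional connectivity with the phase lag index, from
sensor recordings to group statistics, with a fully synthetic, ground-truth
cohort for validation.

## The problem

Resting-state MEG studies of clinical populations — the motivating case is
relapsing-remitting multiple sclerosis against matched healthy controls —
ask whether band-limited phase coupling between cortical regions differs
between groups and whether those differences track clinical variables
(disability scores, cognition, thalamic and whole-brain atrophy). Two
methodological obstacles dominate: field spread inflates naive connectivity
metrics, and sensor-space results are hard to interpret anatomically. The
standard answer, implemented here, is an atlas-based beamformer analysis
combined with the **phase lag index** (PLI), a coupling metric blind to
zero-lag (volume-conducted) interactions:

```
PLI = | < sign( Δφ(t) ) > |,   Δφ wrapped to (−π, π]
```

PLI is 0 for any symmetric phase-difference distribution (no coupling, or
pure field spread) and 1 for a perfectly consistent non-zero lag. The
package implements the full chain:

* **Synthetic cohort** — 151-channel magnetometer-like recordings at
  625 Hz (epochs of 4096 samples), 78 cortical AAL-style ROIs, two groups
  (21 patients / 17 controls) with implanted band-specific phase coupling
  (alpha2 decrease, beta increase in designated resting-state networks) and
  covariates anchored to published cohort descriptives, monotonically
  linked to the implanted coupling.
* **Forward model & beamformer** — analytic dipole lead fields in a
  homogeneous sphere; scalar (SAM-type) minimum-variance weights with unit
  gain, optimized tangential orientation, broadband (0.5–48 Hz) covariance
  and diagonal-loading regularization; per-band maximum-power voxel
  selection per ROI.
* **Connectivity** — zero-phase band filtering in six canonical bands
  (delta through gamma), analytic-signal phases, per-epoch PLI averaged
  over 5 epochs, 78×78 adjacency matrices, node strength, whole-brain mean
  and within-RSN means for seven literature-based resting-state networks.
* **Group statistics** — Mann-Whitney group comparisons with a gated
  post-hoc hierarchy, per-ROI permutation t-tests (exhaustive for tiny
  groups, max-statistic correction optional), Spearman covariate
  correlations and effect-modification regression.

## Worked example

```r
library(megconn)

cfg <- study_config(n_patients = 21, n_controls = 17, level = "source",
                    bands = c("alpha2", "beta"), n_perm = 2000, seed = 42)
res <- run_study(cfg)
subset(res$tests, test == "mann_whitney" & scope == "whole_brain")
```

```
           test   band       scope statistic            p n1 n2   direction
1  mann_whitney alpha2 whole_brain        55 1.459474e-04 21 17  lower_in_x
18 mann_whitney   beta whole_brain       335 3.113844e-07 21 17 higher_in_x
```

The whole-brain PLI of the patient group (`x`) is lower in the alpha2 band
(U = 55, p = 1.5e-04) and higher in the beta band (U = 335, p = 3.1e-07),
so both bands pass the gate and the post-hoc battery runs. The
within-network tests localize the effects to the implanted networks (the
uncorrected exploratory battery can also surface chance hits, as in any
post-hoc screen):

```r
subset(res$tests, test == "mann_whitney" & p < 0.05 & scope != "whole_brain")
```

```
            test   band                scope statistic            p n1 n2   direction
11  mann_whitney alpha2         default_mode         6 2.084698e-09 21 17  lower_in_x
13  mann_whitney alpha2 frontoparietal_right       250 3.711278e-02 21 17 higher_in_x
17  mann_whitney alpha2               visual        15 4.753112e-08 21 17  lower_in_x
19  mann_whitney   beta         default_mode       314 2.227910e-05 21 17 higher_in_x
114 mann_whitney   beta     temporo_parietal       333 5.042190e-07 21 17 higher_in_x
```

The gated patient-group Spearman correlations then recover the implanted
clinical links — beta default-mode PLI rises with disability and falls with
cognition:

```
  band        scope   covariate   group        rho           p  n
  beta default_mode        edss patient  0.6180028 0.002829756 21
  beta default_mode cognition_z patient -0.6428571 0.001671525 21
```

In this particular cohort the thalamic-volume link with alpha2
visual-network PLI comes out at rho = 0.33 — single cohorts of 21 patients
scatter widely around the calibrated population value of 0.58; the
50-replicate recovery check in the test suite verifies the average. A run
with `out_dir =` writes the resolved config, covariates, adjacency
matrices, edge lists, test tables and a log; `inst/cli/megconn.R` wraps the
same call for the shell:

```sh
Rscript inst/cli/megconn.R run-all --out results --seed 42
```

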