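---
title: "Winner-take-all thalamic parcellation and thalamocortical group inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-take-all thalamic parcellation and thalamocortical group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

After a subcortical ischemic stroke, motor recovery depends not only on
motor-pathway damage but on reorganization across wider networks. The
thalamus relays somatosensory input to cortex and is a hub of resting-state
functional networks, so the strength of thalamocortical functional
connectivity — the Pearson correlation between resting-state BOLD time
series of a thalamic subregion and its cortical partner — is a candidate
marker of that reorganization. `thalparc` implements the full analysis
chain for a two-group (stroke patients vs. healthy controls) resting-state
study of this question:

1. **Denoising** of already-normalized 4D BOLD: discard of the first five
   frames, exclusion for head translation > 3 mm, linear detrending,
   0.01–0.08 Hz band-pass, and regression of motion, white-matter and CSF
   confounds. Global-signal regression and spatial smoothing are
   deliberately not performed.
2. **Lesion-side harmonization**: volumes of left-lesion patients are
   mirrored about the mid-sagittal plane so that the ipsilesional
   hemisphere is the right hemisphere in every patient, and every control
   is duplicated with a mirrored copy (32 subjects → 64 entries) to
   neutralize systematic hemispheric asymmetry.
3. **Winner-take-all (WTA) parcellation**: each thalamic voxel is
   correlated with the mean time series of six cortical ROIs (prefrontal,
   motor, temporal, posterior parietal, somatosensory, occipital; defined
   by grouping atlas labels) and labelled by its strongest partner.
   Individual correlation maps are Fisher-z averaged across the pooled
   sample (39 patients + 64 control entries = 103) and the argmax of the
   average defines the group parcellation.
4. **Group inference**: two-sample t tests on Fisher-z ROI-pair
   connectivity (12 tests: 2 sides × 6 ROIs); seed-to-voxel whole-brain
   z maps for the significant pairs, compared between groups with
   permutation cluster-level familywise-error correction; Pearson or
   Spearman correlation of connectivity with Fugl–Meyer Assessment (FMA)
   motor scores; and a split of patients on the NIHSS sensory item.

The change rate of motor function over one year of rehabilitation is
`CR-MF = (FMA_1yr − FMA_baseline) / (FMA_1yr + FMA_baseline)`, bounded in
[−1, 1], which damps the ceiling effect of the FMA scale.

# Statistical model and key formulas

* **Fisher transform.** All group statistics operate on
  `z = atanh(r) = ½·log((1+r)/(1−r))`, which is variance-stabilizing for
  Pearson correlations (`var(ẑ) ≈ 1/(df − 3)`).
* **Two-sample test.** Student's pooled-variance t by default (Welch
  selectable), two-tailed, α = 0.05, uncorrected across the 12 ROI-pair
  tests (an FDR flag exists but is off by default, mirroring the reference design).
* **Cluster-level FWE.** The voxelwise pooled-t map is thresholded at a
  one-sided cluster-forming p (default 0.001, the field convention; the
  reference analyses rarely state it), suprathreshold voxels are
  grouped under 26-connectivity, and the null distribution of the
  **maximum cluster extent** is built by permuting group labels. The
  corrected p of an observed cluster of extent k is
  `(1 + #{permutation max ≥ k}) / (1 + n_perm)`, with exact enumeration
  when fewer distinct label assignments exist than requested
  permutations. Permutation was chosen over Gaussian-random-field theory
  because it is exact under exchangeability and its calibration is
  directly testable; GRF would additionally require a smoothness estimate
  that is unavailable here.
* **Pearson/Spearman gate.** The behavioral correlation uses Pearson when
  both variables pass Shapiro–Wilk at α = 0.05, otherwise Spearman. The
  reference design allows either without fixing the rule;
  this gate is our explicit, deterministic choice.
* **Chi-square.** Demographic 2×2 tables use Pearson's chi-square without
  continuity correction, `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`, which
  reproduces the reference cohort statistics exactly at printed precision.

# The synthetic cohort: what it emulates

No real imaging data ship with the package, so validation rests on a generator
that plants known ground truth and on recovering it end-to-end.

**Anatomy.** A mirror-symmetric phantom (default 24³ voxels of 2 mm)
carries six bilateral cortical blocks and two thalamus blobs; each
thalamus is divided into six contiguous, mirror-symmetric sectors — the
planted "functional subregions". Symmetry makes mid-sagittal flips exact
axis reversals, so harmonization needs no interpolation.

**Signal.** Each cortical ROI r has a latent band-limited (0.01–0.08 Hz)
unit-variance source `s_r(t)`. Cortical voxels carry `s_r + ε`; a
thalamic voxel assigned to r carries `w·s_r + ε`, with ε white noise of
SD `noise_sd` (default 1). The mixing weight solves

```
r_pair = w / sqrt(w² + f_pass / n_subregion),   f_pass = 2·(high−low)·tr
```

so that the **post-band-pass** ROI-pair correlation equals the planted
target (`f_pass` is the in-band fraction of white-noise variance; the
band-pass removes the rest but passes the sources). Weights are
calibrated at the reference noise level 1: the defaults realize the
planted Fisher-z targets exactly, while `noise_sd` away from 1 genuinely
moves the SNR (0 is the noise-free limit with voxelwise r = 1) so that
noise-sweep properties are meaningful.

**Planted group structure.** Controls sit at a pair-level z of
`atanh(0.85) ≈ 1.26` for every pair — a strong but realistic
thalamocortical coupling for mean series over tens of voxels. Patients
are offset additively **on the z scale** (where inference operates):
−0.3 for somatosensory bilaterally, +0.3 for occipital bilaterally and
for ipsilesional temporal, 0 elsewhere — the direction pattern of the
study's findings, with |Δz| = 0.3 the magnitude its power examples use.
Each subject adds a N(0, 0.2²) deviation per (side, ROI); 0.2 is a
plausible between-subject spread for z at this coupling strength.

**Behavior.** FMA-UE baseline follows
`FMA = α + β·z(somatosensory, ipsilesional) + ε` with β = 30 points per
z unit and residual SD 11, calibrated so that the **measured**
correlation (after the ≈ `1/sqrt(df_eff − 3)` attenuation from estimating
z on band-passed series, `df_eff ≈ 2·(high−low)·T·tr`) is of the order of
the reference effect size (r ≈ 0.36); with the sensory-subgroup planting
adding aligned covariance the realized mean correlation is ≈ 0.45–0.5,
and only its **sign** is an acceptance quantity. One-year scores add a
recovery term that decreases with z, so CR-MF correlates negatively with
connectivity. The impaired-sensory subgroup (19 of 39, split on the
NIHSS sensory item) is planted 0.25 z lower and 15 FMA points lower than
the nonimpaired subgroup **mean-preservingly**, so the patient-group mean
stays exactly at the planted group effect.

**What the generator does not emulate.** No hemodynamic response, no
physiological (cardiac/respiratory) noise, no spatial autocorrelation of
voxel noise, no lesion geometry (the modelled patients have
thalamus-sparing lesions; lesion side is a tag), no registration error.
A green test therefore establishes that the analysis chain recovers
correlation structure, effects on the z scale, and calibrated error
rates — not that it is robust to artifacts the generator never produces.

# Numerical and design choices

* **Band-pass realization.** Zero-phase FFT masking of frequency bins
  outside [0.01, 0.08] Hz (DC removed). Exactly linear and phase-free;
  the normative contracts are the amplitude ones (a 0.04 Hz sinusoid
  retains > 90 %, a 0.2 Hz sinusoid < 10 %), verified against an FFT
  oracle. A Butterworth forward–backward filter would satisfy the same
  contracts; no filter-design library is available in the target
  environment and the FFT realization is the simplest operator that is
  exactly linear (the superposition property of the cleaning chain is
  tested bit-for-bit).
* **Stage order.** discard → detrend → band-pass → regress, fixed and
  recorded in a log attribute. Because regressing raw confounds after
  filtering can reintroduce out-of-band variance, confounds pass through
  the same detrend + band-pass before regression (constant columns are
  then dropped).
* **Motion criterion.** Translation-only, strict `> 3 mm` (a frame at
  exactly 3 mm passes); rotations are reported, not thresholded — the
  exclusion criterion is stated in millimetres only.
* **WTA ties and unassigned voxels.** Ties break to the lowest ROI
  index; voxels whose maximum correlation is ≤ 0 get label 0. Both rules
  are deterministic and documented; a convention had to be fixed.
* **Group map rule.** Argmax of Fisher-z-averaged correlation maps
  (convention of the connectivity-parcellation literature, smoother at
  boundaries); majority vote of individual winners is available as
  `method = "vote"` and agrees with the default away from boundaries in
  tests.
* **Parcellation sample.** Patients and flip-augmented controls pooled
  (39 + 64 = 103 entries), reproducing the described sample arithmetic.
* **Control duplication.** The 64 flip-augmented control entries are the
  default comparison group, as described — although the entries are 32
  subjects counted twice and thus not independent. An independence-safe
  mode (`control_mode = "independent"`: the 32 original subjects,
  hemispheres averaged on the z scale) is one flag away and is the mode
  used for type-I calibration, where treating duplicates as independent
  would be miscalibrated by construction.
* **Degenerate correlations.** Seed-to-voxel values with |r| at 1 (e.g.
  a one-voxel seed against itself) are masked out rather than carried as
  infinite z. Zero-variance voxels correlate 0 with a warning.
* **Calibration null maps.** Type-I calibration of the cluster test uses
  Gaussian null maps smoothed with a separable Gaussian (σ = 1 voxel):
  real stat maps are spatially autocorrelated, and on white noise the
  max-extent statistic is so discrete (extents 0–2) that the exact
  permutation test becomes arbitrarily conservative. The rejection rate
  is assessed per contrast at corrected p ≤ 0.05.
* **Grid compatibility.** Shapes must match and affines agree within
  1e-4; nothing is ever resampled. World convention is RAS+, cluster
  peaks are reported in world mm.
* **Configs.** The atlas grouping, ground truth and run configuration are
  JSON (no YAML parser is available in the target environment); any atlas
  can be plugged in by mapping its labels to the six ROI names plus
  `thalamus_left`/`thalamus_right`.
* **Flip-augmentation in the fast path.** `analyze_cohort()` reuses each
  control's cleaned series with hemispheres swapped instead of flipping
  the volume; on the phantom's mirror-symmetric masks this is exactly
  equivalent (cleaning is per-voxel and temporal) and the equivalence
  against the materializing pipeline is asserted in tests.

# Validation design

`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` share one
implementation (`criterion_*()` functions). The reference cohort's desk-checkable
statistics (five demographic chi-squares, the CR-MF of the group means,
cohort structure 39/17/22/32 → 39 + 64) are recomputed exactly. The
headline fMRI results depend on unavailable patient data, so they are
replaced by property criteria on the synthetic study: ≥ 95 % group-WTA
recovery (100 % noise-free), planted Δz recovered within ±0.05 over 20
replicate cohorts and doubling with the planted effect, permutation-FWE
and ROI-pair type-I rates inside [0.02, 0.09], and a positive measured
connectivity–FMA correlation in ≥ 95 % of 100 replicates. Replicate
counts follow that design; grids are scaled (24³ recovery, 16³
calibration and behavioral replicates) and the ROI-pair null uses the
generator's connectivity-level fast path (`simulate_pair_z()`, validated
against the BOLD path in the test suite) to keep the whole run inside CI
budgets.

# Known limitations

* The NIfTI layer reads/writes uncompressed single-file NIfTI-1 only
  (datatypes uint8/int16/int32/float32/float64); no `.nii.gz`, no DICOM,
  no surfaces.
* Inputs are assumed already in one common space; realignment,
  slice-timing and normalization are out of scope, as are scrubbing,
  despiking and smoothing.
* The doubled-control design reproduces the described procedure, and its
  degrees-of-freedom consequences are the user's to weigh; the
  independence-safe mode exists for that reason.
* Anatomical labelling of cluster peaks (nucleus or gyrus names) is not
  computed; peaks are reported as world-mm coordinates.
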