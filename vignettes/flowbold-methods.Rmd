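---
title: "Methods: periodic-design fMRI analysis of flow-motion selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periodic-design fMRI analysis of flow-motion selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowbold)
```

## The analysis problem

Block-design fMRI experiments on visual motion alternate two stimulus
conditions in fixed-length epochs — here 21-s blocks of coherent optic flow
against either a blank screen or a velocity-matched random-motion control —
so that a selective voxel's BOLD signal is periodic at the alternation
frequency (one cycle per 42 s, six cycles per 84-volume run at TR 3 s).
This package implements the complete analysis chain for such designs, from
stimulus synthesis to group statistics, and pairs every stage with a
synthetic-data generator that knows the ground truth, so each stage has a
recovery test. The intended users are developers of periodic-design
analysis pipelines (for example for awake-infant studies, where motion
scrubbing and phase statistics carry most of the inferential weight) who
need a desk-scale, fully testable reference implementation.

## Stimulus model

The coherent stimulus is a field of 100 limited-lifetime dots (1.3° wide,
half black and half white on a 20 cd/m² background at 0.85 contrast)
moving at a constant 5 deg/s across a 27 × 20° field with the central 2°
excluded. The flow trajectory morphs continuously over a 2-s cycle by
rotating each dot's velocity direction relative to its outward radial
direction through a uniformly advancing offset angle: offset 0 gives pure
expansion, 90° pure rotation, 180° pure contraction, and the intermediate
offsets give the inward and outward spirals. We chose the uniform angular
advance because it realises the named waypoint sequence
(expansion → spiral → rotation → spiral → contraction) with a single smooth
parameter and no reversal discontinuity; the handedness of the two spiral
arms follows from the advance direction and is fixed by convention, since
any fixed choice leaves the downstream analysis unchanged.

The random control re-assigns each frame's multiset of velocity vectors to
the dots by a fresh seeded permutation, so local motion energy is matched
exactly frame by frame while global coherence is destroyed. Shuffling is
re-drawn per frame rather than per dot-lifetime; this is an interpretation
(the alternative correlates a dot's direction over its lifetime), and the
per-frame reading is the stronger scrambler. Respawns (lifetime expiry,
field exit, entry into the exclusion zone) draw a uniform legal position by
rejection sampling capped at 1000 attempts, after which a density error is
raised; collision resolution respawns the later-indexed dot, and both
exclusion and collision are tested on dot centres. The
`motion_energy_summary()` flow index — the mean projection of unit
velocities onto the local flow direction — is 1 by construction for the
coherent condition and ~0 for the shuffled control, which the analysis
scripts print as a diagnostic.

## Hemodynamic model and the phase convention

The expected BOLD response is the condition boxcar convolved with a
single gamma-variate HRF (onset delay 2.5 s, shape 3, dispersion 1.25 s —
a standard default for block-design analyses). Because dummy volumes are
discarded before analysis, the retained series is in periodic steady state,
and the package uses the *circular* (steady-state) convolution, computed on
a 0.01-s grid and sampled at the TR, both as the GLM task regressor and as
the simulator's canonical response. This makes the amplitude contract
exact: a noise-free region simulated at amplitude *a* percent returns a
task beta of exactly *a*.

Response phase is read from the discrete Fourier transform at the task
fundamental. The convention is: phase grows with hemodynamic delay (a pure
lag of τ seconds adds 360·τ/42 degrees), values are wrapped to (−180, 180],
and the origin is anchored so that the canonical response model reads
**64°**, the value conventionally assigned to a standard adult hemodynamic
delay in this literature. The anchoring is computed at run time — the raw
FFT phase of the analysed series minus the raw FFT phase of the canonical
model, plus 64 — never stored. We anchored to the model rather than to a
geometric origin (block onset as cosine or sine) because no such simple
origin reproduces the conventional 64° figure under this HRF: numerically
they give 143.4°, 53.4°, 130.2° or 157.9° depending on the sampling
convention. Anchoring makes phases directly interpretable as deviations
from the standard hemodynamic model: a region preferring the *opposite*
condition appears 180° away (e.g. −116° for a counterphase region with
standard delay), and longer infant-like delays push the phase upward.

The signal-to-noise ratio is the amplitude at the fundamental divided by
the root-mean-square amplitude of the two adjacent frequency bins. Under
Gaussian white noise S/N² is F(2, 4)-distributed, which gives three useful
facts: expected *power* is equal across bins (the sense in which noise
S/N ≈ 1), the median S/N is ≈ 0.91 and the mean is √2·Γ(1.5)² ≈ 1.11, and
a per-estimate p-value and significance tier (p < 0.01, p < 0.05) follow
from the F tail. S/N is computed on the concatenated retained series, not
the period average, so the adjacent bins exist; this follows the reading
that the spectrum is taken before averaging.

## Preprocessing

Scrubbing interprets the 4-mm translation and 5° rotation thresholds as
absolute displacements per rigid-body parameter (the parameters are
positions, and summaries of their means and maxima only make sense on that
reading; framewise displacement is the documented alternative). For task
runs, removal operates on half-period (21-s, 7-TR) bins anchored at block
onsets — a bin goes if any of its time points is supra-threshold — and the
survivors are treated as independent segments with their period alignment
recorded. Resting runs drop single supra-threshold points. A run retaining
under half its duration is flagged unusable. Mean intensity adjustment
rescales each volume to the run's grand mean. The high-pass filter
projects out the constant and the first two whole-series Fourier pairs
(the GLM-Fourier approach, two cycles); it is an idempotent linear
projection and leaves the task fundamental untouched.

## GLM, clustering and group maps

Per-voxel ordinary least squares with the task regressor, six mean-centred
motion regressors when a trace exists, and one constant per segment.
Contrast t statistics are mapped to Z through the probit transform of the
exact t CDF (two-sided preserving, computed on the log scale). Cluster
extraction thresholds at Z = 1.96 for two-tailed α = 0.05, groups voxels
under 6-neighbour connectivity (the conservative choice; the alternative
18/26-neighbourhoods merge diagonal contacts), drops clusters below
81 mm³ — three 3-mm voxels — and reports voxel count, |Z|-weighted centre
of mass in millimetres from the grid centre (the synthetic stand-in for
the anterior-commissure origin), and peak Z, with positive and negative
excursions labelled separately. The multi-subject analysis is a
fixed-effects GLM: subjects' retained rows are concatenated with a shared
task column and subject-specific nuisance blocks, and the voxelwise
two-sided p-values are Benjamini–Hochberg corrected at q < 0.05 before the
cluster floor.

## Seed and correlation mask

The V1 seed is selected from the flow-versus-blank contrast at p < 0.001:
the largest positive cluster of at least three voxels in each hemisphere
(candidates may be restricted to a hint region), with the bilateral union
reported at the average of the two foci. Missing support in either
hemisphere is an error naming that hemisphere. The functional mask
cross-correlates the seed series with every voxel at delays of 0 and 3 s
(delays beyond 3 s are excluded by default, since in the source design
they add little new territory; the range is configurable) and takes the
union of voxels with |r| above the two-tailed critical value
r* = t*/√(df + t*²) at df = n−2 — which reproduces the conventional
|r| > 0.25 for series of length ≈ 63. Correlations are computed on
high-pass-filtered, z-scored series, consistent with the GLM
preprocessing. The effective df after scrubbing is whatever the overlap
provides; it is exposed rather than assumed.

## Vectorial phase statistics

Each subject-ROI response is the 2D vector (S/N·cos θ, S/N·sin θ). The
group resultant is the Cartesian mean; dispersion is the SD of the scatter
about the resultant, computed as the root-mean-square distance of the
points from it (the resultant is the mean point, so this is the 2D
standard deviation), and the associated phase variation is
arctan(SD/|resultant|). With unit-magnitude points at 40° angular spread
this recovers ≈ 38°, whereas the SD *around the mean distance* badly
overestimates (≈ 54°) — which settled the reading. Two groups are compared
by a pooled-variance Student t on signed angular deviations: each point's
wrapped deviation from its own group resultant supplies the variance, the
wrapped difference of resultant phases supplies the mean difference, and
the integer df is n₁+n₂−2. Whether the historical test operated on angles
or vector components is not documented; the angular-projection choice is
ours and is what the power analysis validates.

## Resting-state connectivity

ROI-mean series over retained points are high-passed and correlated
(Pearson, lag 0; negative values are meaningful after high-passing).
Group matrices average subject matrices elementwise. Significance uses the
super-subject construction: per-subject z-scored series concatenated per
ROI, correlated, with p from the t distribution at df = total length − 2;
for equal-length z-scored subjects the super-subject r equals the mean
per-subject r exactly (an identity the tests verify to 1e-10). Group
differences are cell-wise two-sample t tests on Fisher-z transformed
correlations (the transform is our variance-stabilising choice; a raw-r
mode exists behind a flag), flagged at p < 0.05 and p < 0.01.

## Synthetic data: what it emulates, and what it does not

`simulate_task_run()` places disjoint labelled regions on a 24 × 24 × 18
grid of 3-mm voxels (desk scale: full pipelines run in seconds) and gives
each region baseline × (1 + sign · amplitude/100 · r(t)), where r(t) is the
canonical response circularly shifted so its fundamental phase *is* the
region's phase parameter — implementing phase by time shift rather than
HRF re-parameterisation makes the generator parameter exactly the quantity
the estimator targets. Noise is AR(1)-coloured white noise plus a
sinusoidal drift with random phase per voxel (defaults: 0.5% SD, AR
coefficient 0.3, 0.3% drift over 128 s); the noise model is the package's
choice, as the source analyses leave it implicit. Motion is applied as a
rigid-body nearest-neighbour resample on spike volumes.
`simulate_rest_run()` draws ROI signals through the Cholesky factor of a
target correlation matrix, so the population matrix is the target exactly.

The generator does not emulate anatomy, partial-volume effects,
physiological noise, slice-timing offsets, or registration error — so
passing recovery tests demonstrate the *estimators* are correct and
calibrated, not that the pipeline is robust to those real-data nuisances.

## Study conditions frozen in the recovery experiments

The phase-recovery experiments (`simulate_phase_cohort()`,
`recover_group_phase()`) use 12 subjects, five cycles per subject (the
typical number of periods surviving scrubbing), one responsive 27-voxel
region, amplitude 1%, and a white-noise level set analytically so the
ROI-mean S/N is ≈ 2.5, the middle of the 2–3 range of reliable responses:
S/N ≈ √n·a₁·amp/(2·σ_roi) with a₁ the fundamental amplitude of the
unit-max canonical cycle. Generator group means of 82° with 40° dispersion
(a V6-like infant cohort) and −146° with 35° (a counterphase PIVC/PIC-like
cohort) are the reported study values; recovery to within 5° over 500
replicate cohorts is the acceptance condition, and the wrap-around regime
near ±180° is exercised by the second cohort. The replicated analyses in
`analysis/03_phase_statistics.R` use 100 replicates for the narrative;
tests use 300; the acceptance script uses the full 500.

## Numerical choices and degenerate inputs

* Fine-grid convolution at dt = 0.01 s bounds phase quantisation at
  ≈ 0.09°; harmonic aliasing through TR sampling keeps phase round trips
  within ≈ 0.6° of the target, well inside the 5° acceptance band.
* `wrap_deg()` maps to (−180, 180] with 180 kept positive, matching the
  sign conventions of reported counterphase values.
* Zero-resultant vector averages, all-zero contrasts, rank-deficient
  designs, constant series in correlations, empty ROIs, and non-PSD rest
  targets all raise explicit errors rather than propagating NaN.
* A shape-1 gamma with vanishing dispersion degenerates to a delta kernel,
  reproducing the boxcar regressor exactly (used by the identity tests).
* The t→Z probit map is computed via log tail probabilities and is finite
  for |t| into the hundreds; exact zeros map to Z = 0.

## Known limitations

Motion resampling is nearest-neighbour and is only applied to spike
volumes; sub-voxel motion is carried by the regressors, not the geometry.
The FFX group model assumes a common grid (registration is out of scope).
S/N on scrubbed runs treats the concatenated retained series as contiguous
when locating the fundamental bin, which blurs the spectrum when interior
half-periods are removed — the same compromise the source procedure makes.
Cluster inference uses a fixed volume floor, not permutation-calibrated
extent thresholds.
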