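# flowbold

An R package implementing the full analysis chain for **periodic
(block-design) fMRI studies of visual flow-motion selectivity**, exercised
end-to-end on synthetic BOLD data with known ground truth. It is written
for developers and reviewers of such pipelines — in particular the
awake-infant setting, where motion scrubbing, Fourier phase statistics and
seed-based masking carry most of the inferential weight — who need a
desk-scale, fully testable reference implementation in which every stage
has a recovery test against a generator that knows the truth.

## What it implements

* **Stimulus**: a random-dot optic-flow generator (100 dots, 5 deg/s,
  10-frame lifetime, 2-s cycle morphing expansion → spiral → rotation →
  spiral → contraction) and its velocity-shuffled random control with
  exactly matched per-frame motion energy.
* **Synthetic BOLD**: task runs (21-s alternation, TR 3 s, 84 volumes)
  with region-wise selectivity sign, amplitude and response phase, AR(1) +
  drift noise and optional motion spikes; resting runs whose ROI signals
  realise a prescribed correlation matrix exactly (Cholesky construction).
* **Preprocessing**: scrubbing at 4 mm / 5° with half-period cutting
  (single-point removal for rest), mean intensity adjustment, two-cycle
  Fourier high-pass.
* **GLM**: boxcar ⊗ gamma-HRF regressor plus six motion regressors;
  per-voxel OLS with `t = cᵀβ̂ / √(σ̂² cᵀ(XᵀX)⁻¹c)` mapped to Z by the
  probit transform of the exact t CDF; cluster thresholding at Z = 1.96
  (two-tailed α = 0.05) with an 81 mm³ floor (three 3-mm voxels);
  fixed-effects multi-subject maps with Benjamini–Hochberg FDR at
  q < 0.05.
* **Seed mask**: bilateral V1 seed from the flow-vs-blank contrast
  (p < 0.001) and the union of lagged seed-correlation maps at 0 and 3 s,
  thresholded at the critical `r* = t*/√(df + t*²)` (|r| ≈ 0.25 at
  df ≈ 61).
* **Phase metrics**: S/N = |F(f₀)| / RMS(|F(f₀−1)|, |F(f₀+1)|) and
  response phase at the fundamental under a convention anchored so the
  canonical hemodynamic response reads 64°; vectorial group statistics
  (resultant, 2D dispersion, phase SD = arctan(SD/|R|)) and two-group
  phase t tests on angular deviations.
* **Connectivity**: resting-state ROI correlation matrices, super-subject
  concatenation significance (equal to the mean per-subject r for
  equal-length z-scored subjects), and cell-wise two-group comparison on
  Fisher-z correlations.

The methods vignette (`vignettes/flowbold-methods.Rmd`) documents the
models, conventions, parameter defaults and their rationale.

## Worked example

Simulate one subject with a coherent-preferring V6-like region (phase
82°) and a counterphase PIVC-like region (−116°), then measure them:

```r
library(flowbold)
acq <- acquisition_spec()              # 21-s blocks, TR 3 s, 6 cycles

lay <- region_layout(regions = list(
  V6   = list(voxels = voxel_block(11:14, 5:7, 13:15), sign = 1,
              amplitude_pct = 1.5, phase_deg = 82),
  PIVC = list(voxels = voxel_block(5:7, 13:15, 10:12), sign = 1,
              amplitude_pct = 1.5, phase_deg = -116)))
run <- simulate_task_run(lay, acq, noise_spec(0.4, 0.2, 0.2), seed = 7)

tc <- extract_timecourse(run, lay$regions$V6$voxels)
sn_phase(highpass_fourier(tc, 2), acq)
#> <sn_phase> S/N = 137.84, phase = 82.0 deg (6 cycles, p<0.01)

tc2 <- extract_timecourse(run, lay$regions$PIVC$voxels)
sn_phase(highpass_fourier(tc2, 2), acq)
#> <sn_phase> S/N = 114.45, phase = -115.8 deg (6 cycles, p<0.01)
```

Both generator phases are recovered (82.0° and −115.8°), with the
counterphase region sitting ≈180° from the canonical 64°. A voxelwise GLM
with clustering on the same run returns the two injected regions as the
dominant clusters (41 and 33 voxels, |peak Z| > 11), plus small 3-voxel
noise clusters at the floor:

```r
d3 <- dim(run$data)[1:3]
Y <- t(matrix(run$data, prod(d3), acq$n_timepoints))
Y <- 100 * sweep(Y, 2, colMeans(Y), "/") - 100      # percent signal
fit <- fit_glm(Y, build_design(acq))
fit$zmap <- array(fit$zmap, d3)
write_roi_table(threshold_and_cluster(fit$zmap, alpha = 0.05,
                                      min_cluster_mm3 = 81))
#>    label hemi  n   chi   psi  zeta  Zpeak
#> 1   pos1    M 41   0.0 -19.4  13.5  11.74
#> ...
#> 5   neg1    L 33 -19.6   4.6   4.5 -15.50
```

Columns follow the reporting convention: voxel count `n`, centre of mass
in mm from the grid centre (`chi`, `psi`, `zeta`), and peak Z.

## The analysis workflow

Numbered drivers under `analysis/` run the full study sequence on
synthetic cohorts and write their tables under `results/`:

1. `01_stimulus.R` — stimulus generation and motion-energy diagnostics
   (coherent flow index 1.00, shuffled control ≈ 0, identical per-frame
   velocity multisets).
2. `02_task_pipeline.R` — six-subject cohort through scrubbing, seed
   selection, correlation masking, masked GLM, clustering, phase metrics
   and the FFX group map (all six selective regions recovered with the
   correct sign; V1 excluded).
3. `03_phase_statistics.R` — replicated group-phase recovery (82 ± 40°
   and −146 ± 35° cohorts) and the infant-like vs adult-like phase
   comparison.
4. `04_connectivity.R` — two nine-subject resting groups differing only
   in the sign of V1–MT+ coupling; matrices, super-subject significance
   and the cell-wise group test that singles out the V1–MT+ cells.

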