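acq <- acquisition_spec()

test_that("a null layout with noise off is constant at baseline", {
  lay <- region_layout(dim = c(6, 6, 2), regions = list(
    A = list(voxels = voxel_block(2:3, 2:3, 1), sign = 0, baseline = 150)))
  run <- simulate_task_run(lay, acq, noise_spec(0, 0, 0), seed = 1)
  expect_equal(dim(run$data), c(6, 6, 2, 84))
  a <- run$data[2, 2, 1, ]
  expect_true(all(a == 150))
  expect_true(all(run$data[1, 1, 1, ] == 100))
})

test_that("generator phase is recovered exactly from noise-free runs", {
  for (th in c(64, 82, -146, 179, -90)) {
    run <- simulate_task_run(tiny_layout(phase_deg = th), acq,
                             noise_spec(0, 0, 0), seed = 1)
    tc <- extract_timecourse(run, tiny_vox())
    est <- sn_phase(tc, acq)$phase_deg
    expect_lt(abs(wrap_deg(est - th)), 360 / acq$n_timepoints)
  }
})

test_that("noise calibrated for target S/N 3 recovers it within 15%", {
  # analytic white-noise level for ROI-mean S/N 3 (see simulate_phase_cohort)
  vox <- tiny_vox()
  cyc <- canonical_cycle(acq)
  a1 <- 2 * Mod(stats::fft(rep_len(cyc, 84))[7]) / 84
  # the amplitude-ratio estimator is inflated by E[(chi2_4/4)^(-1/2)] =
  # sqrt(2) Gamma(1.5)/Gamma(2) under white noise; fold that into the
  # calibration so the estimator's expectation is the target
  c4 <- sqrt(2) * gamma(1.5) / gamma(2)
  sd_pct <- sqrt(84) * a1 / (2 * 3) * sqrt(nrow(vox)) * c4
  ns <- noise_spec(sd_pct = sd_pct, ar1 = 0, drift_pct = 0)
  sns <- vapply(1:200, function(i) {
    run <- simulate_task_run(tiny_layout(), acq, ns, seed = 100 + i)
    sn_phase(extract_timecourse(run, vox), acq)$sn
  }, 1)
  expect_lt(abs(mean(sns) - 3) / 3, 0.15)
})

test_that("phase estimation is unbiased within 3 degrees at S/N >= 2", {
  cohorts <- simulate_phase_cohort(82, 0, n_subjects = 60,
                                   acq = acquisition_spec(n_cycles = 5),
                                   target_sn = 2.5, seed = 21)
  ph <- vapply(cohorts, function(p) p$phase_deg, 1) * pi / 180
  est <- atan2(mean(sin(ph)), mean(cos(ph))) * 180 / pi
  expect_lt(abs(wrap_deg(est - 82)), 5)
  expect_gt(mean(vapply(cohorts, function(p) p$sn, 1)), 2)
})

test_that("rest runs realise the target correlation structure", {
  lay <- region_layout(dim = c(6, 6, 2), regions = list(
    A = list(voxels = voxel_block(1:2, 1:2, 1)),
    B = list(voxels = voxel_block(4:5, 4:5, 1))))
  # identity target, long run: off-diagonals vanish
  acqL <- acquisition_spec("rest", n_timepoints = 5000)
  run <- simulate_rest_run(lay, diag(2), acqL,
                           noise_spec(0.1, 0, 0), seed = 2)
  M <- roi_correlation_matrix(run, list(A = voxel_block(1:2, 1:2, 1),
                                        B = voxel_block(4:5, 4:5, 1)),
                              highpass_cycles = 0)
  expect_lt(abs(M[1, 2]), 0.1)
  expect_equal(diag(unclass(M)), c(A = 1, B = 1))
  expect_equal(M[1, 2], M[2, 1])
  # 0.8 target at n = 120: mean sample r within 0.05 over replicates
  tgt <- matrix(c(1, 0.8, 0.8, 1), 2)
  acqR <- acquisition_spec("rest")
  rs <- vapply(1:300, function(i) {
    r <- simulate_rest_run(lay, tgt, acqR, noise_spec(0.05, 0, 0),
                           seed = 500 + i)
    roi_correlation_matrix(r, list(A = voxel_block(1:2, 1:2, 1),
                                   B = voxel_block(4:5, 4:5, 1)),
                           highpass_cycles = 0)[1, 2]
  }, 1)
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("a non-positive-semi-definite target is rejected", {
  lay <- region_layout(dim = c(6, 6, 2), regions = list(
    A = list(voxels = voxel_block(1:2, 1:2, 1)),
    B = list(voxels = voxel_block(4:5, 4:5, 1)),
    C = list(voxels = voxel_block(1:2, 4:5, 1))))
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(simulate_rest_run(lay, bad), "positive semi-definite")
})

test_that("motion traces respect thresholds without spikes and place spikes", {
  tr <- simulate_motion_trace(acq, seed = 4)
  expect_equal(dim(tr), c(84L, 6L))
  expect_lt(max(abs(tr[, 1:3])), 4)
  expect_lt(max(abs(tr[, 4:6])), 5)
  seg <- scrub_motion(tr, acq)
  expect_equal(seg$retained_fraction, 1)
  # one 6-mm spike mid-run removes exactly its half-period
  tr2 <- simulate_motion_trace(acq, spike_times = 30, spike_mm = 6, seed = 4)
  seg2 <- scrub_motion(tr2, acq)
  expect_equal(which(!seg2$retained), 29:35)
  expect_equal(seg2$retained_fraction, 11 / 12)
  # spikes everywhere: run flagged
  tr3 <- simulate_motion_trace(acq, spike_times = seq(1, 84, by = 7),
                               spike_mm = 10, seed = 4)
  seg3 <- scrub_motion(tr3, acq)
  expect_lt(seg3$retained_fraction, 0.5)
  expect_false(seg3$usable)
})

test_that("simulators are deterministic given the seed", {
  r1 <- simulate_task_run(tiny_layout(), acq, noise_spec(), seed = 77)
  r2 <- simulate_task_run(tiny_layout(), acq, noise_spec(), seed = 77)
  expect_identical(r1$data, r2$data)
  lay <- region_layout(dim = c(6, 6, 2), regions = list(
    A = list(voxels = voxel_block(1:2, 1:2, 1)),
    B = list(voxels = voxel_block(4:5, 4:5, 1))))
  s1 <- simulate_rest_run(lay, diag(2), seed = 5)
  s2 <- simulate_rest_run(lay, diag(2), seed = 5)
  expect_identical(s1$data, s2$data)
})
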