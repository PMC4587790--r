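acq <- acquisition_spec()

test_that("the design has the run's rows and a 14-TR periodic task column", {
  des <- build_design(acq)
  expect_equal(nrow(des$X), 84L)
  task <- des$X[, des$task_col]
  expect_equal(task[1:70], task[15:84], tolerance = 1e-12)
  # one removed half-period leaves 77 rows
  tr <- matrix(0, 84, 6); tr[30, 1] <- 6
  seg <- scrub_motion(tr, acq)
  expect_equal(nrow(build_design(acq, seg)$X), 77L)
})

test_that("a delta HRF reproduces the boxcar as the task regressor", {
  hrf_delta <- hrf_params(onset_delay = 0, shape = 1, scale = 1e-9)
  des <- build_design(acq, hrf = hrf_delta)
  task <- des$X[, 1]
  box <- rep(rep(c(1, 0), each = 7), 6)
  box <- (box - mean(box)) / max(abs(box - mean(box)))
  expect_equal(task, box, tolerance = 1e-6)
})

test_that("OLS matches the normal-equations oracle to 1e-8", {
  set.seed(31)
  seg <- run_segments(c(rep(TRUE, 42), rep(FALSE, 7), rep(TRUE, 35)), acq)
  tr <- matrix(rnorm(84 * 6, sd = 0.3), 84, 6)
  des <- build_design(acq, seg, trace = tr)
  Y <- matrix(rnorm(nrow(des$X) * 8), nrow(des$X), 8)
  fit <- fit_glm(Y, des)
  contrast <- c(1, rep(0, ncol(des$X) - 1))
  for (v in 1:8) {
    o <- oracle_ols(des$X, Y[, v], contrast)
    expect_equal(as.numeric(fit$beta)[v], o$eff, tolerance = 1e-8)
    expect_equal(as.numeric(fit$tmap)[v], o$t, tolerance = 1e-8)
    expect_equal(fit$df, o$df)
  }
})

test_that("noise-free amplitude is recovered exactly", {
  run <- simulate_task_run(tiny_layout(amplitude_pct = 1.7), acq,
                           noise_spec(0, 0, 0), seed = 1)
  d3 <- dim(run$data)[1:3]
  Y <- t(matrix(run$data, prod(d3), 84))
  Y <- 100 * sweep(Y, 2, colMeans(Y), "/") - 100   # percent signal
  fit <- fit_glm(Y, build_design(acq))
  idx <- flowbold:::.lin_index(tiny_vox(), d3)
  expect_equal(max(abs(as.numeric(fit$beta)[idx] - 1.7)), 0, tolerance = 1e-6)
})

test_that("type-I error of the Z map is calibrated under pure noise", {
  set.seed(41)
  Y <- matrix(rnorm(84 * 10000), 84)
  fit <- fit_glm(Y, build_design(acq))
  frac <- mean(abs(fit$zmap) >= 1.96)
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("an all-zero contrast is rejected", {
  des <- build_design(acq)
  expect_error(fit_glm(matrix(rnorm(84 * 2), 84), des,
                       contrast = rep(0, ncol(des$X))), "zero")
})

test_that("two-tailed alpha 0.05 maps to the 1.96 Z threshold", {
  z <- array(0, c(5, 5, 5))
  z[2, 2, 2] <- 1.95
  expect_length(threshold_and_cluster(z, alpha = 0.05,
                                      min_cluster_mm3 = 27), 0)
  z[2, 2, 2] <- 1.97
  expect_length(threshold_and_cluster(z, alpha = 0.05,
                                      min_cluster_mm3 = 27), 1)
})

test_that("clusters below the 81 mm^3 floor are dropped", {
  z <- array(0, c(6, 6, 6))
  z[2:3, 2, 2] <- 3          # 2 voxels = 54 mm^3 at 3 mm
  expect_length(threshold_and_cluster(z), 0)
  z[2:4, 2, 2] <- 3          # 3 voxels = 81 mm^3
  rois <- threshold_and_cluster(z)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$n, 3L)
  expect_length(threshold_and_cluster(array(0, c(6, 6, 6))), 0)
})

test_that("positive and negative excursions cluster separately with stats", {
  z <- array(0, c(8, 8, 4))
  z[2:4, 2, 2] <- c(2.5, 4, 3)
  z[6:8, 6, 3] <- -3
  rois <- threshold_and_cluster(z)
  expect_length(rois, 2)
  expect_equal(rois[[1]]$peak_z, 4)
  expect_equal(rois[[2]]$peak_z, -3)
  com_vox <- rois[[1]]$com_mm / 3 + (dim(z) + 1) / 2
  expect_equal(com_vox[2], 2)
  expect_gt(com_vox[1], 2.9)  # |Z|-weighted pull toward the peak at x=3
})

test_that("connected components match the brute-force flood-fill oracle", {
  set.seed(19)
  for (i in 1:5) {
    mask <- array(runif(1000) < 0.25, c(10, 10, 10))
    got <- connected_components(mask)
    want <- oracle_components(mask)
    d <- dim(mask)
    got_lin <- lapply(got, function(v)
      sort((v[, 3] - 1) * 100 + (v[, 2] - 1) * 10 + v[, 1]))
    expect_setequal(lapply(got_lin, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("FDR correction agrees with the hand-computed BH oracle", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.04, 0.2)
  rej <- stats::p.adjust(p, "BH") < 0.05
  expect_equal(rej, oracle_bh_reject(p, 0.05))
  expect_equal(sum(rej), 5L)
  set.seed(23)
  for (i in 1:20) {
    p <- runif(50)^2
    expect_equal(stats::p.adjust(p, "BH") <= 0.05 + 1e-12,
                 oracle_bh_reject(p, 0.05))
  }
})

test_that("a single-subject fixed-effects fit reduces to the single GLM", {
  run <- simulate_task_run(tiny_layout(), acq, noise_spec(0.5, 0, 0),
                           seed = 51)
  des <- build_design(acq)
  g <- fixed_effects_group(list(run), list(des), fdr_q = 0.05)
  d3 <- dim(run$data)[1:3]
  Y <- t(matrix(run$data, prod(d3), 84))
  single <- fit_glm(Y, des)
  expect_equal(as.numeric(g$tmap), as.numeric(single$tmap),
               tolerance = 1e-10)
})

test_that("group power grows with the number of subjects", {
  set.seed(61)
  runs <- lapply(1:6, function(s)
    simulate_task_run(tiny_layout(amplitude_pct = 0.5), acq,
                      noise_spec(3, 0, 0), seed = 600 + s))
  des <- build_design(acq)
  g <- fixed_effects_group(runs, rep(list(des), 6))
  idx <- flowbold:::.lin_index(tiny_vox(), c(8, 8, 4))
  singles <- vapply(runs, function(r) {
    Y <- t(matrix(r$data, prod(c(8, 8, 4)), 84))
    stats::median(abs(as.numeric(fit_glm(Y, des)$zmap)[idx]))
  }, 1)
  expect_gt(stats::median(abs(as.numeric(g$zmap)[idx])), stats::median(singles))
})
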