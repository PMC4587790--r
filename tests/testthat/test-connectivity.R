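rest_acq <- acquisition_spec("rest")

two_roi_layout <- function() {
  region_layout(dim = c(6, 6, 2), regions = list(
    A = list(voxels = voxel_block(1:2, 1:2, 1)),
    B = list(voxels = voxel_block(4:5, 4:5, 1))))
}

test_that("identical voxel sets correlate perfectly", {
  run <- simulate_rest_run(two_roi_layout(), diag(2), rest_acq,
                           noise_spec(0.2, 0, 0), seed = 3)
  vox <- voxel_block(1:2, 1:2, 1)
  M <- roi_correlation_matrix(run, list(A = vox, A2 = vox))
  expect_equal(M[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(unclass(M)), c(A = 1, A2 = 1))
})

test_that("generator round-trip recovers the target matrix within 0.05", {
  k <- 4
  tgt <- diag(k)
  tgt[1, 2] <- tgt[2, 1] <- 0.6
  tgt[3, 4] <- tgt[4, 3] <- -0.4
  lay <- region_layout(dim = c(8, 8, 2), regions = list(
    A = list(voxels = voxel_block(1:2, 1:2, 1)),
    B = list(voxels = voxel_block(5:6, 1:2, 1)),
    C = list(voxels = voxel_block(1:2, 5:6, 1)),
    D = list(voxels = voxel_block(5:6, 5:6, 1))))
  rois <- lapply(lay$regions, function(r) r$voxels)
  acc <- matrix(0, k, k)
  nrep <- 150
  for (i in seq_len(nrep)) {
    acqL <- acquisition_spec("rest", n_timepoints = 240)
    run <- simulate_rest_run(lay, tgt, acqL, noise_spec(0.05, 0, 0),
                             seed = 3000 + i)
    acc <- acc + unclass(roi_correlation_matrix(run, rois,
                                                highpass_cycles = 0))
  }
  expect_lt(max(abs(acc / nrep - tgt)), 0.05)
})

test_that("independent ROIs at n = 120 rarely exceed the 0.25 level", {
  set.seed(101)
  vals <- replicate(40, {
    S <- matrix(rnorm(120 * 6), 120)
    M <- roi_correlation_matrix(S, highpass_cycles = 0)
    abs(M[upper.tri(M)])
  })
  expect_gte(mean(vals < 0.25), 0.95)
})

test_that("constant series are rejected with the ROI named", {
  S <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_error(roi_correlation_matrix(S, highpass_cycles = 0),
               "constant ROI series")
})

test_that("one subject's super-subject equals its own matrix", {
  set.seed(102)
  S <- matrix(rnorm(120 * 4), 120)
  ss <- supersubject_significance(list(S))
  expect_equal(ss$r, unclass(roi_correlation_matrix(S, highpass_cycles = 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("equal-length z-scored subjects average their correlations", {
  set.seed(103)
  subs <- lapply(1:5, function(i) matrix(rnorm(80 * 3), 80))
  ss <- supersubject_significance(subs)
  per <- lapply(subs, function(S) stats::cor(S))
  expect_equal(ss$r, Reduce(`+`, per) / 5, tolerance = 1e-10)
  expect_equal(ss$n, 400L)
})

test_that("null super-subject p-values are calibrated", {
  set.seed(104)
  ps <- replicate(300, {
    subs <- lapply(1:3, function(i) matrix(rnorm(60 * 2), 60))
    supersubject_significance(subs)$p[1, 2]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05) , 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("identical groups flag no cells", {
  set.seed(105)
  mats <- lapply(1:6, function(i) stats::cor(matrix(rnorm(120 * 3), 120)))
  cmp <- compare_group_matrices(mats[1:3], mats[1:3])
  expect_true(all(cmp$tier == ""))
  expect_error(compare_group_matrices(mats[1], mats[2:3]), "at least 2")
})

test_that("an inverted correlation is flagged at p < 0.01 with specificity", {
  # one ROI pair generated at +0.6 in group A and -0.6 in group B
  k <- 3
  mk <- function(rho, seed) {
    tgt <- diag(k); tgt[1, 2] <- tgt[2, 1] <- rho
    set.seed(seed)
    S <- matrix(rnorm(120 * k), 120) %*% chol(tgt)
    stats::cor(S)
  }
  hits_target <- 0; hits_other <- 0
  nrep <- 200
  for (i in seq_len(nrep)) {
    A <- lapply(1:9, function(s) mk(0.6, i * 100 + s))
    B <- lapply(1:9, function(s) mk(-0.6, i * 100 + 50 + s))
    cmp <- compare_group_matrices(A, B)
    if (cmp$tier[1, 2] == "p<0.01") hits_target <- hits_target + 1
    if (cmp$p[1, 3] < 0.01 || cmp$p[2, 3] < 0.01) hits_other <- hits_other + 1
  }
  expect_gte(hits_target / nrep, 0.9)
  expect_lt(hits_other / nrep, 0.1)
  # symmetric twin carries the same flag
  A <- lapply(1:9, function(s) mk(0.6, 7000 + s))
  B <- lapply(1:9, function(s) mk(-0.6, 8000 + s))
  cmp <- compare_group_matrices(A, B)
  expect_equal(cmp$tier[1, 2], cmp$tier[2, 1])
})
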