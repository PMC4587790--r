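acq <- acquisition_spec()

test_that("uniform-region extraction returns the injected response shape", {
  run <- simulate_task_run(tiny_layout(amplitude_pct = 2), acq,
                           noise_spec(0, 0, 0), seed = 1)
  tc <- extract_timecourse(run, tiny_vox())
  want <- 2 * canonical_response(acq)
  # percent change about the run mean reproduces the unit-max shape
  expect_lt(max(abs(tc - 100 * (1 + want / 100) /
                      mean(1 + want / 100) + 100)), 1e-9)
  expect_equal(attr(tc, "tp_index"), 1:84)
})

test_that("opposite responses cancel in a two-voxel ROI", {
  lay <- region_layout(dim = c(4, 4, 2), regions = list(
    P = list(voxels = cbind(1, 1, 1), sign = 1, amplitude_pct = 1,
             phase_deg = 64),
    N = list(voxels = cbind(2, 1, 1), sign = -1, amplitude_pct = 1,
             phase_deg = 64)))
  run <- simulate_task_run(lay, acq, noise_spec(0, 0, 0), seed = 1)
  tc <- extract_timecourse(run, rbind(cbind(1, 1, 1), cbind(2, 1, 1)))
  expect_lt(max(abs(tc)), 1e-9)
  expect_error(extract_timecourse(run, matrix(0, 0, 3)), "empty ROI")
})

test_that("scrubbed extraction keeps only retained points with alignment", {
  run <- simulate_task_run(tiny_layout(), acq, noise_spec(0.2, 0, 0),
                           seed = 2)
  tr <- matrix(0, 84, 6); tr[30, 1] <- 6
  seg <- scrub_motion(tr, acq)
  tc <- extract_timecourse(run, tiny_vox(), seg)
  expect_length(tc, 77)
  expect_equal(attr(tc, "tp_index"), c(1:28, 36:84))
})

test_that("period averaging collapses cycles and drops partial ones", {
  one <- sin(2 * pi * (0:13) / 14)
  x <- rep(one, 5)
  expect_equal(period_average(x, 14), one, ignore_attr = TRUE)
  expect_equal(attr(period_average(x, 14), "n_cycles"), 5L)
  # 84-point series reduces to its 14-point cycle
  expect_length(period_average(rnorm(84), 14), 14)
  # scrubbing one half-period drops that cycle from the average
  x2 <- rep(one, 6)
  attr(x2, "tp_index") <- 1:84
  x3 <- x2[-(29:35)]
  attr(x3, "tp_index") <- setdiff(1:84, 29:35)
  expect_equal(attr(period_average(x3, 14), "n_cycles"), 5L)
  short <- rnorm(5); attr(short, "tp_index") <- 1:5
  expect_error(period_average(short, 14), "complete")
})

test_that("noise in the period average shrinks as 1/sqrt(cycles)", {
  set.seed(91)
  one <- cos(2 * pi * (0:13) / 14)
  rms <- function(k) {
    errs <- replicate(60, {
      x <- rep(one, k) + rnorm(14 * k)
      sqrt(mean((period_average(x, 14) - one)^2))
    })
    mean(errs)
  }
  expect_gt(rms(2) / rms(8), 1.6)   # expect about 2 = sqrt(8/2)
})

test_that("a pure fundamental has an effectively unbounded S/N", {
  x <- sin(2 * pi * 6 * (0:83) / 84)
  sp <- sn_phase(x, acq)
  expect_gt(sp$sn, 1e6)
  expect_equal(sp$tier, "p<0.01")
  expect_error(sn_phase(rnorm(14), acq), "3 stimulus cycles")
})

test_that("white-noise S/N reflects equal expected power across bins", {
  set.seed(92)
  stats <- replicate(2000, {
    A <- Mod(stats::fft(rnorm(84)))
    c(sn = A[7] / sqrt(mean(A[c(6, 8)]^2)), pf = A[7]^2, pn = mean(A[c(6, 8)]^2))
  })
  # power at the fundamental equals power at the flanking bins
  expect_lt(abs(mean(stats["pf", ]) / mean(stats["pn", ]) - 1), 0.1)
  # the amplitude-ratio estimator itself averages E sqrt(F(2,4)) = 1.11
  e_sn <- sqrt(2) * (sqrt(2) * gamma(1.5)) * (gamma(1.5) / (sqrt(2) * gamma(2)))
  expect_lt(abs(mean(stats["sn", ]) - e_sn), 0.1)
  expect_lt(abs(stats::median(stats["sn", ]) - 1), 0.1)
})

test_that("the canonical response reads 64 degrees", {
  sp <- sn_phase(canonical_response(acq), acq)
  expect_equal(sp$phase_deg, 64, tolerance = 1e-6)
})

test_that("circular shifts move phase by 360/period per TR, S/N fixed", {
  t84 <- 0:83
  x <- canonical_response(acq) + 0.3 * cos(2 * pi * 3 * t84 / 84) +
    0.15 * cos(2 * pi * 5 * t84 / 84 + 0.7) +
    0.1 * sin(2 * pi * 7 * t84 / 84)   # content in the flanking bins
  sp0 <- sn_phase(x, acq)
  for (s in c(1, 3, 7)) {
    xs <- c(x[(84 - s + 1):84], x[1:(84 - s)])   # delay by s TRs
    sp <- sn_phase(xs, acq)
    expect_equal(wrap_deg(sp$phase_deg - sp0$phase_deg - 360 * s / 14), 0,
                 tolerance = 1e-9)
    expect_equal(sp$sn, sp0$sn, tolerance = 1e-9)
  }
})

test_that("S/N and phase are invariant to scaling and offset", {
  set.seed(93)
  x <- canonical_response(acq) + 0.2 * rnorm(84)
  a <- sn_phase(x, acq)
  b <- sn_phase(5.5 * x + 300, acq)
  expect_equal(a$sn, b$sn, tolerance = 1e-9)
  expect_equal(a$phase_deg, b$phase_deg, tolerance = 1e-9)
})

test_that("negating a response flips its phase by 180 degrees", {
  x <- canonical_response(acq, phase_deg = 30)
  a <- sn_phase(x, acq)
  b <- sn_phase(-x, acq)
  expect_equal(wrap_deg(b$phase_deg - a$phase_deg - 180), 0,
               tolerance = 1e-9)
})

test_that("vector statistics summarise identical and dispersed clusters", {
  ident <- vector_stats(rep(2, 5), rep(82, 5))
  expect_equal(ident$phase_deg, 82)
  expect_lt(ident$phase_sd_deg, 1e-6)
  set.seed(94)
  th <- rnorm(10000, 82, 40)
  vs <- vector_stats(rep(1, 10000), th)
  expect_lt(abs(vs$phase_deg - 82), 2)
  expect_lt(abs(vs$phase_sd_deg - 40), 5)
  expect_error(vector_stats(c(1, 1), c(0, 180)), "zero resultant")
})

test_that("the resultant matches the circular-mean oracle for unit vectors", {
  set.seed(95)
  th <- runif(50, -170, 170)
  vs <- vector_stats(rep(1, 50), th)
  oracle <- atan2(mean(sin(th * pi / 180)), mean(cos(th * pi / 180))) *
    180 / pi
  expect_lt(abs(wrap_deg(vs$phase_deg - oracle)), 1)
})

test_that("identical groups give a null phase comparison", {
  g <- list(sn = rep(1, 6), phase_deg = c(60, 70, 80, 90, 100, 110))
  cmp <- compare_phase_groups(g, g)
  expect_equal(cmp$t, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
  expect_error(compare_phase_groups(list(sn = 1, phase_deg = 10), g),
               "at least 2")
})

test_that("a 30-degree group separation at 10-degree spread is detected", {
  set.seed(96)
  hits <- replicate(500, {
    a <- list(sn = rep(1, 12), phase_deg = rnorm(12, 60, 10))
    b <- list(sn = rep(1, 12), phase_deg = rnorm(12, 90, 10))
    compare_phase_groups(a, b)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
})
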