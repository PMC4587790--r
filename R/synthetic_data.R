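#' Region layout for synthetic BOLD volumes
#'
#' Describes a voxel grid and a set of disjoint named regions, each carrying
#' its ground truth: a selectivity sign (+1 prefers the first condition, -1
#' the second, 0 null), a response amplitude in percent signal change, a
#' hemodynamic response phase in degrees (the quantity [sn_phase()] targets)
#' and a baseline intensity.
#'
#' @param dim integer grid dimensions (3-vector).
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param regions named list; each element a list with fields `voxels` (an
#'   n x 3 integer matrix of 1-based voxel indices), `sign`, `amplitude_pct`,
#'   `phase_deg`, and optionally `baseline` and `hemisphere`.
#' @param baseline default baseline intensity for tissue outside the named
#'   regions.
#' @return An object of class `region_layout`.
#' @export
region_layout <- function(dim = c(24, 24, 18), voxel_mm = 3, regions = list(),
                          baseline = 100) {
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_mm > 0)
  dim <- as.integer(dim)
  seen <- integer(0)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    stopifnot(is.matrix(r$voxels), ncol(r$voxels) == 3)
    if (any(r$voxels < 1) || any(t(r$voxels) > dim))
      stop("region '", nm, "' has voxels outside the grid")
    if (!is.null(r$phase_deg) &&
        (r$phase_deg <= -180 || r$phase_deg > 180))
      stop("region '", nm, "' phase must lie in (-180, 180]")
    lin <- .lin_index(r$voxels, dim)
    if (any(lin %in% seen)) stop("regions must be disjoint ('", nm, "')")
    seen <- c(seen, lin)
    if (is.null(r$baseline)) regions[[nm]]$baseline <- baseline
    if (is.null(r$sign)) regions[[nm]]$sign <- 0
    if (is.null(r$amplitude_pct)) regions[[nm]]$amplitude_pct <- 1
    if (is.null(r$phase_deg)) regions[[nm]]$phase_deg <- .canonical_phase_deg
  }
  structure(list(dim = dim, voxel_mm = voxel_mm, regions = regions,
                 baseline = baseline),
            class = "region_layout")
}

.lin_index <- function(vox, dim) {
  (vox[, 3] - 1L) * dim[1] * dim[2] + (vox[, 2] - 1L) * dim[1] + vox[, 1]
}

#' Rectangular block of voxel indices
#'
#' Convenience constructor for region voxel sets: all voxels whose 1-based
#' indices fall within the closed ranges `x`, `y`, `z`.
#'
#' @param x,y,z integer index ranges (vectors; their `range()` is used).
#' @return An n x 3 integer matrix.
#' @export
voxel_block <- function(x, y, z) {
  as.matrix(expand.grid(i = as.integer(min(x):max(x)),
                        j = as.integer(min(y):max(y)),
                        k = as.integer(min(z):max(z))))
}

#' Default two-hemisphere motion-network layout
#'
#' A desk-scale 24 x 24 x 18 grid (3-mm voxels) housing the regions the
#' analysis reports: bilateral V1 along the posterior midline, bilateral MT+
#' laterally, a medial V6, bilateral PIVC and a midline PCu/Cu. Selectivity
#' signs and amplitudes depend on the emulated contrast: for
#' `"flow_vs_blank"` V1 responds strongly and the association regions
#' moderately (all positive); for `"coh_vs_random"` MT+, V6 and PCu/Cu
#' prefer coherent flow, PIVC prefers random motion (negative sign, i.e. a
#' counterphase response), and V1 is null.
#'
#' @param stimulus which block contrast the run emulates.
#' @param phase_deg response phase given to every responsive region
#'   (counterphase regions are wrapped +180 from it automatically when
#'   `counterphase_shift` is `TRUE`).
#' @param amplitude_pct response amplitude (percent signal) of the selective
#'   association regions.
#' @param counterphase_shift if `TRUE`, regions with `sign = -1` get phase
#'   `wrap_deg(phase_deg + 180)` and sign +1, making the sign convention
#'   explicit in the phase parameter instead.
#' @return A `region_layout`.
#' @export
default_layout <- function(stimulus = c("coh_vs_random", "flow_vs_blank"),
                           phase_deg = .canonical_phase_deg,
                           amplitude_pct = 1, counterphase_shift = FALSE) {
  stimulus <- match.arg(stimulus)
  reg <- function(vox, sign, amp, hemi) {
    list(voxels = vox, sign = sign, amplitude_pct = amp,
         phase_deg = phase_deg, hemisphere = hemi)
  }
  v1_amp <- if (stimulus == "flow_vs_blank") 2.5 else 0
  v1_sign <- if (stimulus == "flow_vs_blank") 1 else 0
  assoc_sign <- if (stimulus == "flow_vs_blank") 1 else 1
  pivc_sign <- if (stimulus == "flow_vs_blank") 1 else -1
  regions <- list(
    V1_L  = reg(voxel_block(9:11, 2:5, 8:10), v1_sign, v1_amp, "L"),
    V1_R  = reg(voxel_block(14:16, 2:5, 8:10), v1_sign, v1_amp, "R"),
    MT_L  = reg(voxel_block(3:5, 7:9, 8:10), assoc_sign, amplitude_pct, "L"),
    MT_R  = reg(voxel_block(20:22, 7:9, 8:10), assoc_sign, amplitude_pct, "R"),
    V6    = reg(voxel_block(11:14, 5:7, 13:15), assoc_sign, amplitude_pct, "M"),
    PIVC_L = reg(voxel_block(5:7, 13:15, 10:12), pivc_sign, amplitude_pct, "L"),
    PIVC_R = reg(voxel_block(18:20, 13:15, 10:12), pivc_sign, amplitude_pct, "R"),
    PCuCu = reg(voxel_block(11:14, 9:11, 14:16), assoc_sign, amplitude_pct, "M")
  )
  if (counterphase_shift) {
    for (nm in names(regions)) {
      if (regions[[nm]]$sign < 0) {
        regions[[nm]]$phase_deg <- wrap_deg(regions[[nm]]$phase_deg + 180)
        regions[[nm]]$sign <- 1
      }
    }
  }
  region_layout(regions = regions)
}

#' Noise specification for synthetic runs
#'
#' Additive voxel noise: white Gaussian noise (SD in percent of baseline)
#' passed through an AR(1) recursion, plus a sinusoidal low-frequency drift
#' with a random phase per voxel.
#'
#' @param sd_pct white-noise standard deviation, percent of baseline.
#' @param ar1 AR(1) coefficient in `[0, 0.95]`.
#' @param drift_pct peak drift amplitude, percent of baseline.
#' @param drift_period_s drift period in seconds.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_pct = 0.5, ar1 = 0.3, drift_pct = 0.3,
                       drift_period_s = 128) {
  stopifnot(sd_pct >= 0, ar1 >= 0, ar1 <= 0.95, drift_pct >= 0,
            drift_period_s > 0)
  structure(list(sd_pct = sd_pct, ar1 = ar1, drift_pct = drift_pct,
                 drift_period_s = drift_period_s), class = "noise_spec")
}

# noise matrix (n_timepoints x n_voxels), unit baseline percent scale
.noise_matrix <- function(n_tp, n_vox, noise, TR) {
  if (noise$sd_pct == 0 && noise$drift_pct == 0)
    return(matrix(0, n_tp, n_vox))
  eps <- matrix(stats::rnorm(n_tp * n_vox), n_tp, n_vox)
  if (noise$ar1 > 0) {
    eps <- apply(eps, 2, function(e)
      as.numeric(stats::filter(e, noise$ar1, method = "recursive")))
    eps <- eps * sqrt(1 - noise$ar1^2)  # restore unit marginal variance
  }
  out <- eps * noise$sd_pct
  if (noise$drift_pct > 0) {
    t <- (seq_len(n_tp) - 1) * TR
    ph <- stats::runif(n_vox, 0, 2 * pi)
    out <- out + noise$drift_pct *
      sin(outer(2 * pi * t / noise$drift_period_s, ph, "+"))
  }
  out
}

#' A 4D BOLD run container
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param acq the [acquisition_spec()] of the run.
#' @param voxel_mm isotropic voxel size in mm.
#' @param condition character vector of per-volume condition labels.
#' @param motion optional n x 6 motion trace (see [simulate_motion_trace()]).
#' @param seed generator seed, if the run is synthetic.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, acq, voxel_mm = 3, condition = NULL,
                     motion = NULL, seed = NA_integer_) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != acq$n_timepoints)
    stop("data has ", dim(data)[4], " volumes but the acquisition spec says ",
         acq$n_timepoints)
  if (!is.null(motion) && nrow(motion) != acq$n_timepoints)
    stop("motion trace length does not match the run")
  structure(list(data = data, acq = acq, voxel_mm = voxel_mm,
                 condition = condition, motion = motion, seed = seed),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s: %dx%dx%d voxels x %d volumes, TR %g s\n",
              x$acq$type, d[1], d[2], d[3], d[4], x$acq$TR))
  invisible(x)
}

#' Per-volume condition labels of a task run
#' @param acq a task [acquisition_spec()].
#' @return Character vector, `"A"` during first-condition blocks, `"B"`
#'   otherwise.
#' @export
condition_labels <- function(acq) {
  half <- period_tr(acq) / 2
  rep(rep(c("A", "B"), each = half), acq$n_cycles)
}

#' Simulate a block-design task run
#'
#' Every voxel of a responsive region carries
#' `baseline * (1 + sign * amplitude/100 * r(t))`, where `r(t)` is the
#' canonical periodic boxcar-convolved-with-HRF response circularly shifted
#' so that its fundamental phase equals the region's `phase_deg` (unit
#' maximum deviation, zero mean). Noise per [noise_spec()] is added to all
#' voxels. If a motion trace is supplied, volumes with non-zero motion are
#' rigid-body resampled (translation in mm plus rotation about the grid
#' centre, nearest-neighbour) and the trace is attached to the run.
#'
#' @param layout a [region_layout()].
#' @param acq a task [acquisition_spec()].
#' @param noise a [noise_spec()]; use `noise_spec(0, 0, 0)` for noise-free.
#' @param hrf an [hrf_params()].
#' @param motion optional motion trace from [simulate_motion_trace()].
#' @param seed integer seed.
#' @return A [bold_run()].
#' @export
simulate_task_run <- function(layout, acq = acquisition_spec(),
                              noise = noise_spec(), hrf = hrf_params(),
                              motion = NULL, seed = 1) {
  stopifnot(inherits(layout, "region_layout"), acq$type == "task")
  set.seed(seed)
  n_tp <- acq$n_timepoints
  nvox <- prod(layout$dim)
  base <- rep(layout$baseline, nvox)
  for (r in layout$regions)
    base[.lin_index(r$voxels, layout$dim)] <- r$baseline
  Y <- matrix(base, n_tp, nvox, byrow = TRUE)
  for (r in layout$regions) {
    if (r$sign == 0 || r$amplitude_pct == 0) next
    resp <- canonical_response(acq, hrf, phase_deg = r$phase_deg)
    idx <- .lin_index(r$voxels, layout$dim)
    Y[, idx] <- Y[, idx] *
      (1 + r$sign * r$amplitude_pct / 100 * resp)
  }
  Y <- Y + .noise_matrix(n_tp, nvox, noise, acq$TR) *
    matrix(base / 100, n_tp, nvox, byrow = TRUE)
  arr <- array(t(Y), dim = c(layout$dim, n_tp))
  if (!is.null(motion))
    arr <- .apply_motion(arr, motion, layout$voxel_mm, layout$baseline)
  bold_run(arr, acq, layout$voxel_mm, condition_labels(acq), motion, seed)
}

# rigid-body resample volumes with non-zero motion (nearest neighbour)
.apply_motion <- function(arr, motion, voxel_mm, fill) {
  d <- dim(arr)
  ctr <- (d[1:3] + 1) / 2
  grid <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                k = seq_len(d[3])))
  for (t in seq_len(d[4])) {
    m <- motion[t, ]
    if (all(abs(m) < 1e-12)) next
    R <- .rot3(m[4] * pi / 180, m[5] * pi / 180, m[6] * pi / 180)
    # inverse mapping: source = R^-1 (target - centre - translation) + centre
    shifted <- sweep(grid, 2, ctr)
    shifted <- sweep(shifted, 2, m[1:3] / voxel_mm)
    src <- round(sweep(shifted %*% R, 2, ctr, "+"))
    ok <- src[, 1] >= 1 & src[, 1] <= d[1] & src[, 2] >= 1 &
      src[, 2] <= d[2] & src[, 3] >= 1 & src[, 3] <= d[3]
    vol <- arr[, , , t]
    new <- rep(fill, nrow(grid))
    new[ok] <- vol[src[ok, , drop = FALSE]]
    arr[, , , t] <- array(new, d[1:3])
  }
  arr
}

.rot3 <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Simulate a resting-state run realising a target correlation matrix
#'
#' Region-mean signals are linear mixtures of independent Gaussian series
#' (via the Cholesky factor of the target), so their population correlation
#' matrix equals `target_corr` exactly. Each region's signal is embedded in
#' its voxels at `signal_pct` percent of baseline, and independent voxel
#' noise per [noise_spec()] is added everywhere.
#'
#' @param layout a [region_layout()]; region order follows
#'   `names(layout$regions)`.
#' @param target_corr symmetric positive semi-definite correlation matrix,
#'   one row per region.
#' @param acq a rest [acquisition_spec()].
#' @param noise a [noise_spec()] for voxel noise.
#' @param signal_pct amplitude of the shared region signal, percent of
#'   baseline.
#' @param seed integer seed.
#' @return A [bold_run()].
#' @export
simulate_rest_run <- function(layout, target_corr,
                              acq = acquisition_spec("rest"),
                              noise = noise_spec(ar1 = 0, drift_pct = 0),
                              signal_pct = 1, seed = 1) {
  stopifnot(inherits(layout, "region_layout"), acq$type == "rest")
  k <- length(layout$regions)
  target_corr <- as.matrix(target_corr)
  if (nrow(target_corr) != k || ncol(target_corr) != k)
    stop("target_corr must be ", k, " x ", k)
  if (max(abs(target_corr - t(target_corr))) > 1e-8 ||
      max(abs(diag(target_corr) - 1)) > 1e-8)
    stop("target_corr must be symmetric with unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_corr is not positive semi-definite")
  set.seed(seed)
  n_tp <- acq$n_timepoints
  L <- chol(target_corr + diag(1e-10, k))
  S <- matrix(stats::rnorm(n_tp * k), n_tp, k) %*% L
  nvox <- prod(layout$dim)
  base <- rep(layout$baseline, nvox)
  for (r in layout$regions)
    base[.lin_index(r$voxels, layout$dim)] <- r$baseline
  Y <- matrix(base, n_tp, nvox, byrow = TRUE)
  for (i in seq_len(k)) {
    r <- layout$regions[[i]]
    idx <- .lin_index(r$voxels, layout$dim)
    Y[, idx] <- Y[, idx] * (1 + signal_pct / 100 * S[, i])
  }
  Y <- Y + .noise_matrix(n_tp, nvox, noise, acq$TR) *
    matrix(base / 100, n_tp, nvox, byrow = TRUE)
  arr <- array(t(Y), dim = c(layout$dim, n_tp))
  bold_run(arr, acq, layout$voxel_mm, NULL, NULL, seed)
}

#' Simulate a six-parameter rigid-motion trace
#'
#' A smooth low-amplitude baseline drift (integrated and lightly smoothed
#' Gaussian steps, rescaled to stay well below the scrubbing thresholds)
#' plus optional spikes at given time points.
#'
#' @param acq an [acquisition_spec()].
#' @param spike_times integer time-point indices receiving spikes.
#' @param spike_mm translation magnitude (mm) of each spike, recycled.
#' @param spike_deg rotation magnitude (degrees) of each spike, recycled.
#' @param drift_mm peak absolute drift of the translation parameters.
#' @param seed integer seed.
#' @return An `n_timepoints` x 6 matrix with columns
#'   `tx, ty, tz` (mm) and `rx, ry, rz` (degrees).
#' @export
simulate_motion_trace <- function(acq, spike_times = integer(0),
                                  spike_mm = 6, spike_deg = 0,
                                  drift_mm = 0.5, seed = 1) {
  n <- acq$n_timepoints
  if (length(spike_times) && (min(spike_times) < 1 || max(spike_times) > n))
    stop("spike times must lie within the run")
  set.seed(seed)
  smooth_drift <- function(amp) {
    w <- cumsum(stats::rnorm(n))
    w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
    w[is.na(w)] <- 0
    if (max(abs(w)) > 0) w <- w / max(abs(w)) * amp
    w
  }
  tr <- sapply(1:3, function(i) smooth_drift(drift_mm))
  ro <- sapply(1:3, function(i) smooth_drift(drift_mm / 2))
  m <- cbind(tr, ro)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (length(spike_times)) {
    spike_mm <- rep_len(spike_mm, length(spike_times))
    spike_deg <- rep_len(spike_deg, length(spike_times))
    for (i in seq_along(spike_times)) {
      m[spike_times[i], "tx"] <- m[spike_times[i], "tx"] + spike_mm[i]
      m[spike_times[i], "rx"] <- m[spike_times[i], "rx"] + spike_deg[i]
    }
  }
  m
}
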