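#' Acquisition specification for a functional run
#'
#' Describes the temporal structure of a BOLD run: repetition time, number of
#' retained time points and, for task runs, the block-design periodicity. The
#' defaults reproduce the study conditions the rest of the package assumes: a
#' 21-s alternation between two stimulus conditions, TR of 3 s, six full
#' cycles (84 time points) for task runs and 120 time points for rest runs.
#' Dummy volumes (discarded before analysis for signal stabilisation) are
#' recorded for bookkeeping only; all series handled by the package start
#' after them.
#'
#' @param type `"task"` (block design) or `"rest"`.
#' @param TR repetition time in seconds.
#' @param block_s block length in seconds (one condition epoch; a full cycle
#'   is two blocks).
#' @param n_cycles number of stimulus cycles in a task run.
#' @param n_timepoints number of retained volumes. For task runs this must
#'   equal `n_cycles * 2 * block_s / TR` and is filled in automatically when
#'   omitted.
#' @param n_dummy dummy volumes discarded at acquisition start.
#'
#' @return An object of class `acquisition_spec`.
#' @examples
#' acq <- acquisition_spec()          # 84-point task run, TR 3 s
#' rest <- acquisition_spec("rest")   # 120-point resting run
#' @export
acquisition_spec <- function(type = c("task", "rest"), TR = 3, block_s = 21,
                             n_cycles = 6, n_timepoints = NULL, n_dummy = 4) {
  type <- match.arg(type)
  stopifnot(TR > 0, block_s > 0)
  if (type == "task") {
    if (is.null(n_timepoints)) n_timepoints <- n_cycles * 2 * block_s / TR
    if (abs(n_timepoints * TR - n_cycles * 2 * block_s) > 1e-9)
      stop("task run length must equal n_cycles * 2 * block_s")
    if (abs(block_s / TR - round(block_s / TR)) > 1e-9)
      stop("block length must be a whole number of TRs")
  } else {
    if (is.null(n_timepoints)) n_timepoints <- 120
  }
  structure(list(type = type, TR = TR, block_s = block_s,
                 n_cycles = if (type == "task") n_cycles else NA_integer_,
                 n_timepoints = as.integer(round(n_timepoints)),
                 n_dummy = as.integer(n_dummy)),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> %s run: %d time points, TR %g s", x$type,
              x$n_timepoints, x$TR))
  if (x$type == "task")
    cat(sprintf(", %d cycles of %g s blocks", x$n_cycles, x$block_s))
  cat("\n")
  invisible(x)
}

#' Period of the task design in TRs
#' @param acq an [acquisition_spec()].
#' @return Number of volumes per stimulus cycle (two blocks).
#' @export
period_tr <- function(acq) {
  stopifnot(inherits(acq, "acquisition_spec"), acq$type == "task")
  as.integer(round(2 * acq$block_s / acq$TR))
}

#' Hemodynamic response function parameters
#'
#' The default is a single gamma-variate kernel with onset delay 2.5 s, shape
#' 3 and dispersion 1.25 s, a standard choice for block-design analyses. A
#' double-gamma family (positive peak minus a scaled undershoot) is available
#' for sensitivity analyses.
#'
#' @param family `"single-gamma"` or `"double-gamma"`.
#' @param onset_delay seconds before the response begins (single gamma).
#' @param shape gamma shape parameter (single gamma).
#' @param scale gamma dispersion in seconds (single gamma).
#' @param undershoot_ratio peak-to-undershoot amplitude ratio (double gamma).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(family = c("single-gamma", "double-gamma"),
                       onset_delay = 2.5, shape = 3, scale = 1.25,
                       undershoot_ratio = 6) {
  family <- match.arg(family)
  stopifnot(shape > 0, scale > 0, onset_delay >= 0, undershoot_ratio > 0)
  structure(list(family = family, onset_delay = onset_delay, shape = shape,
                 scale = scale, undershoot_ratio = undershoot_ratio),
            class = "hrf_params")
}

#' Evaluate the hemodynamic response kernel
#'
#' @param t time in seconds (vector, `t >= 0`).
#' @param hrf an [hrf_params()] object.
#' @return Kernel values; the kernel integrates to a positive value.
#' @export
eval_hrf <- function(t, hrf = hrf_params()) {
  stopifnot(inherits(hrf, "hrf_params"))
  if (hrf$family == "single-gamma") {
    u <- (t - hrf$onset_delay) / hrf$scale
    h <- ifelse(u > 0, u^(hrf$shape - 1) * exp(-u), 0)
    # a shape-1 kernel is right-continuous at onset; with a vanishing scale
    # it degenerates to a delta, leaving the boxcar unsmoothed
    h[u == 0 & hrf$shape <= 1] <- 1
  } else {
    h <- stats::dgamma(t, shape = 6, scale = 1) -
      stats::dgamma(t, shape = 16, scale = 1) / hrf$undershoot_ratio
    h[t < 0] <- 0
  }
  h
}

# Phase value assigned by convention to the canonical (standard-delay)
# hemodynamic response at the task fundamental.
.canonical_phase_deg <- 64

#' One cycle of the canonical periodic BOLD response
#'
#' Builds the steady-state response of a voxel following the standard
#' hemodynamic model: a boxcar (on during the first block of each cycle)
#' convolved circularly with the gamma HRF on a fine time grid, then sampled
#' at the TR. The returned cycle is mean-centred and scaled to unit maximum
#' absolute deviation, so a simulated region with response amplitude `a`
#' percent deviates from baseline by at most `a` percent.
#'
#' Response phase follows the package convention in which this canonical
#' response reads 64 degrees at the fundamental frequency (see
#' [sn_phase()]). Passing `phase_deg` returns the cycle delayed (circularly
#' shifted) so that its fundamental phase equals `phase_deg`; e.g.
#' `phase_deg = 64 + 180` (wrapped to -116) is the exact counterphase
#' response of a region preferring the opposite condition.
#'
#' @param acq a task [acquisition_spec()].
#' @param hrf an [hrf_params()] object.
#' @param phase_deg target fundamental phase in degrees, or `NULL` for the
#'   unshifted canonical response.
#' @param dt fine-grid resolution (s) for the convolution.
#' @return Numeric vector of length `period_tr(acq)`.
#' @export
canonical_cycle <- function(acq, hrf = hrf_params(), phase_deg = NULL,
                            dt = 0.01) {
  stopifnot(inherits(acq, "acquisition_spec"), acq$type == "task")
  cycle_s <- 2 * acq$block_s
  tf <- seq(0, cycle_s - dt, by = dt)
  box <- as.numeric(tf < acq$block_s)
  th <- seq(0, min(32, cycle_s - dt), by = dt)
  h <- eval_hrf(th, hrf)
  if (sum(h) <= 0) stop("HRF must integrate to a positive value")
  h <- h / sum(h)
  L <- length(box)
  resp <- Re(stats::fft(stats::fft(box) * stats::fft(c(h, rep(0, L - length(h)))),
                        inverse = TRUE)) / L
  if (!is.null(phase_deg)) {
    shift_s <- (phase_deg - .canonical_phase_deg) / 360 * cycle_s
    k <- as.integer(round(shift_s / dt)) %% L
    if (k > 0) resp <- c(resp[(L - k + 1):L], resp[1:(L - k)])
  }
  idx <- as.integer(round(seq(0, cycle_s - acq$TR, by = acq$TR) / dt)) + 1L
  s <- resp[idx]
  s <- s - mean(s)
  s / max(abs(s))
}

#' Full-run canonical response
#'
#' The canonical cycle of [canonical_cycle()] tiled over all cycles of a task
#' run (optionally truncated or extended to `n_timepoints`).
#'
#' @inheritParams canonical_cycle
#' @param n_timepoints series length; defaults to the full run.
#' @return Numeric vector of length `n_timepoints`.
#' @export
canonical_response <- function(acq, hrf = hrf_params(), phase_deg = NULL,
                               n_timepoints = acq$n_timepoints, dt = 0.01) {
  cyc <- canonical_cycle(acq, hrf, phase_deg, dt)
  rep_len(cyc, n_timepoints)
}

#' Wrap angles in degrees to (-180, 180]
#' @param x angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}
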