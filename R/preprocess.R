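#' Scrub a run by its rigid-motion trace
#'
#' Removes intervals contaminated by head motion exceeding 4 mm of
#' translation or 5 degrees of rotation on any rigid-body parameter
#' (absolute displacement). For task runs, removal operates on half-period
#' intervals anchored at block onsets: an interval is discarded if any of
#' its time points is supra-threshold, and the surviving intervals are
#' treated as independent shorter samples. For rest runs, single
#' supra-threshold time points are discarded. A run retaining less than half
#' of its duration is flagged unusable.
#'
#' @param trace n x 6 motion matrix (`tx, ty, tz` in mm, `rx, ry, rz` in
#'   degrees), one row per retained volume.
#' @param acq the run's [acquisition_spec()].
#' @param translation_thresh threshold on absolute translation, mm.
#' @param rotation_thresh threshold on absolute rotation, degrees.
#' @return An object of class `run_segments`: `intervals` (data frame with
#'   `start`, `end`), `offsets` (0-based position of each segment start
#'   within the stimulus cycle; `NA` for rest), `retained` (logical per time
#'   point), `retained_fraction`, and `usable`.
#' @export
scrub_motion <- function(trace, acq, translation_thresh = 4,
                         rotation_thresh = 5) {
  trace <- as.matrix(trace)
  if (nrow(trace) != acq$n_timepoints)
    stop("motion trace has ", nrow(trace), " rows but the run has ",
         acq$n_timepoints, " time points")
  bad_tp <- apply(abs(trace[, 1:3, drop = FALSE]) > translation_thresh, 1, any) |
    apply(abs(trace[, 4:6, drop = FALSE]) > rotation_thresh, 1, any)
  n <- acq$n_timepoints
  if (acq$type == "task") {
    half <- period_tr(acq) / 2
    bin <- (seq_len(n) - 1) %/% half
    bad_bin <- tapply(bad_tp, bin, any)
    retained <- as.logical(!bad_bin[as.character(bin)])
  } else {
    retained <- !bad_tp
  }
  run_segments(retained, acq)
}

#' Build run segments from a retained-time-point mask
#'
#' @param retained logical vector, `TRUE` for retained time points.
#' @param acq the run's [acquisition_spec()].
#' @return A `run_segments` object (see [scrub_motion()]).
#' @export
run_segments <- function(retained, acq) {
  n <- length(retained)
  stopifnot(n == acq$n_timepoints)
  r <- rle(retained)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  intervals <- data.frame(start = starts[keep], end = ends[keep])
  offsets <- if (acq$type == "task")
    (intervals$start - 1) %% period_tr(acq) else rep(NA_integer_,
                                                     nrow(intervals))
  frac <- sum(retained) / n
  structure(list(intervals = intervals, offsets = offsets,
                 retained = retained, retained_fraction = frac,
                 usable = frac >= 0.5),
            class = "run_segments")
}

#' @export
print.run_segments <- function(x, ...) {
  cat(sprintf("<run_segments> %d segment(s), retained fraction %.3f%s\n",
              nrow(x$intervals), x$retained_fraction,
              if (x$usable) "" else " [run flagged unusable]"))
  invisible(x)
}

#' Full-run segments (nothing scrubbed)
#' @param acq the run's [acquisition_spec()].
#' @return A `run_segments` covering the whole run.
#' @export
full_segments <- function(acq) run_segments(rep(TRUE, acq$n_timepoints), acq)

#' Mean intensity adjustment across volumes
#'
#' Rescales each volume so that its spatial mean equals the run's grand mean,
#' compensating for inter-scan intensity differences. The grand mean is
#' preserved.
#'
#' @param run a [bold_run()].
#' @return The adjusted [bold_run()].
#' @export
intensity_adjust <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  vol_means <- colMeans(Y)
  if (any(abs(vol_means) < 1e-12))
    stop("cannot adjust a volume with zero mean intensity")
  grand <- mean(vol_means)
  Y <- sweep(Y, 2, grand / vol_means, "*")
  run$data <- array(Y, d)
  run
}

#' Fourier high-pass filter
#'
#' Projects out the constant plus the sine/cosine pairs at 1..`n_cycles`
#' cycles per series (the GLM-Fourier approach). The output is orthogonal to
#' every removed regressor, and the projection is idempotent.
#'
#' @param x numeric vector (a voxel or ROI time course), or a matrix with
#'   one series per column.
#' @param n_cycles highest whole-series frequency removed.
#' @return Filtered series of the same shape.
#' @export
highpass_fourier <- function(x, n_cycles = 2) {
  if (is.matrix(x)) return(apply(x, 2, highpass_fourier, n_cycles = n_cycles))
  n <- length(x)
  if (n < 2 * n_cycles + 1)
    stop("series too short for ", n_cycles, "-cycle high-pass")
  t <- seq_len(n) - 1
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_cycles), function(k)
    cbind(sin(2 * pi * k * t / n), cos(2 * pi * k * t / n)))))
  qr.resid(qr(X), x)
}

#' Scrubbing report
#'
#' Summarises a motion trace and its scrubbing outcome in the form used for
#' audit tables: per-parameter mean, SD and maximum over the retained time
#' points, plus thresholds, removed intervals and retained fraction.
#'
#' @param trace n x 6 motion matrix.
#' @param seg `run_segments` from [scrub_motion()].
#' @param translation_thresh,rotation_thresh the thresholds applied.
#' @return A list; serialise with [write_json_file()].
#' @export
scrub_report <- function(trace, seg, translation_thresh = 4,
                         rotation_thresh = 5) {
  used <- trace[seg$retained, , drop = FALSE]
  list(
    thresholds = list(translation_mm = translation_thresh,
                      rotation_deg = rotation_thresh),
    parameter_mean = colMeans(used),
    parameter_sd = apply(used, 2, stats::sd),
    max_translation_mm = max(abs(used[, 1:3])),
    max_rotation_deg = max(abs(used[, 4:6])),
    removed_intervals = which(!seg$retained),
    retained_fraction = seg$retained_fraction,
    usable = seg$usable
  )
}
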