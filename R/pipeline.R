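#' Pipeline configuration
#'
#' Collects every threshold and model parameter the task pipeline applies,
#' with the study defaults: seed selection at p < 0.001, correlation mask at
#' alpha 0.05 over delays 0 and 3 s, ROI labelling at two-tailed alpha 0.05
#' (Z 1.96), an 81 mm^3 minimum cluster (three 3-mm voxels), FDR q < 0.05
#' for the group map, scrubbing at 4 mm / 5 degrees, a two-cycle Fourier
#' high-pass, and the single-gamma HRF.
#'
#' @param acq task [acquisition_spec()].
#' @param hrf [hrf_params()].
#' @param seed_p seed-selection two-tailed p threshold.
#' @param mask_alpha correlation-mask two-tailed alpha.
#' @param roi_alpha ROI-labelling two-tailed alpha.
#' @param cluster_mm3 minimum cluster volume, mm^3.
#' @param fdr_q group-map FDR level.
#' @param translation_thresh,rotation_thresh scrubbing thresholds (mm, deg).
#' @param delays_s correlation-mask delays, seconds.
#' @param highpass_cycles cycles removed by the high-pass filter.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(acq = acquisition_spec(), hrf = hrf_params(),
                            seed_p = 0.001, mask_alpha = 0.05,
                            roi_alpha = 0.05, cluster_mm3 = 81, fdr_q = 0.05,
                            translation_thresh = 4, rotation_thresh = 5,
                            delays_s = c(0, 3), highpass_cycles = 2) {
  for (v in c(seed_p, mask_alpha, roi_alpha, fdr_q))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  if (cluster_mm3 <= 0) stop("cluster floor must be positive")
  structure(list(acq = acq, hrf = hrf, seed_p = seed_p,
                 mask_alpha = mask_alpha, roi_alpha = roi_alpha,
                 cluster_mm3 = cluster_mm3, fdr_q = fdr_q,
                 translation_thresh = translation_thresh,
                 rotation_thresh = rotation_thresh, delays_s = delays_s,
                 highpass_cycles = highpass_cycles),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$acq <- unclass(x$acq)
  x$hrf <- unclass(x$hrf)
  write_json_file(x, path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acq <- acquisition_spec(x$acq$type, TR = x$acq$TR, block_s = x$acq$block_s,
                          n_cycles = x$acq$n_cycles,
                          n_timepoints = x$acq$n_timepoints,
                          n_dummy = x$acq$n_dummy)
  hrf <- hrf_params(x$hrf$family, onset_delay = x$hrf$onset_delay,
                    shape = x$hrf$shape, scale = x$hrf$scale,
                    undershoot_ratio = x$hrf$undershoot_ratio)
  pipeline_config(acq = acq, hrf = hrf, seed_p = x$seed_p,
                  mask_alpha = x$mask_alpha, roi_alpha = x$roi_alpha,
                  cluster_mm3 = x$cluster_mm3, fdr_q = x$fdr_q,
                  translation_thresh = x$translation_thresh,
                  rotation_thresh = x$rotation_thresh,
                  delays_s = x$delays_s,
                  highpass_cycles = x$highpass_cycles)
}

# preprocess one run: scrub -> intensity adjust -> voxelwise high-pass
.preprocess_run <- function(run, config) {
  seg <- if (is.null(run$motion)) full_segments(run$acq)
  else scrub_motion(run$motion, run$acq, config$translation_thresh,
                    config$rotation_thresh)
  if (!seg$usable)
    stop("run flagged unusable: retained fraction ",
         signif(seg$retained_fraction, 3))
  run <- intensity_adjust(run)
  list(run = run, seg = seg)
}

# voxel matrix (retained time points x voxels), high-passed per segment
.filtered_matrix <- function(run, seg, n_cycles) {
  d <- dim(run$data)
  Y <- t(matrix(run$data, prod(d[1:3]), d[4]))[seg$retained, , drop = FALSE]
  bounds <- cumsum(seg$intervals$end - seg$intervals$start + 1)
  starts <- c(1, utils::head(bounds, -1) + 1)
  for (s in seq_along(starts)) {
    rows <- starts[s]:bounds[s]
    if (length(rows) >= 2 * n_cycles + 1)
      Y[rows, ] <- highpass_fourier(Y[rows, , drop = FALSE], n_cycles)
    else Y[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                            colMeans(Y[rows, , drop = FALSE]))
  }
  Y
}

#' Run the full task pipeline on a synthetic cohort
#'
#' Executes the complete per-subject analysis in the study's order —
#' motion scrubbing, mean intensity adjustment, Fourier high-pass, V1-seed
#' selection from the flow-versus-blank GLM, lagged-correlation mask from
#' the seed signal, masked coherent-versus-random GLM, cluster extraction —
#' followed by S/N-and-phase metrics per ROI and a fixed-effects group map
#' with FDR correction over the coherent-versus-random runs.
#'
#' @param config a [pipeline_config()].
#' @param subjects list of subjects; each a list with elements `fvb` (the
#'   flow-versus-blank [bold_run()]) and `cvr` (the coherent-versus-random
#'   run), sharing one voxel grid.
#' @param seed_hint optional voxel matrix restricting seed-cluster
#'   candidates (e.g. the layout's V1 labels).
#' @return A list per the study outputs: `roi_tables` (per-subject ROI data
#'   frames), `sn_phase` (long data frame: subject, roi, hemi, sn,
#'   phase_deg, tier), `group` (the [fixed_effects_group()] result),
#'   `seeds`, `masks`, and `log` (per-subject retained fractions, mask
#'   fractions, cluster counts).
#' @export
run_task_pipeline <- function(config, subjects, seed_hint = NULL) {
  if (length(subjects) == 0) stop("empty run list")
  roi_tables <- list(); snp <- list(); seeds <- list(); masks <- list()
  cvr_runs <- list(); cvr_designs <- list(); log <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    id <- if (!is.null(names(subjects)) && nzchar(names(subjects)[si]))
      names(subjects)[si] else sprintf("S%02d", si)
    pf <- tryCatch(.preprocess_run(sub$fvb, config), error = function(e)
      stop("subject ", id, ", flow-vs-blank preprocessing: ",
           conditionMessage(e)))
    pc <- tryCatch(.preprocess_run(sub$cvr, config), error = function(e)
      stop("subject ", id, ", coherent-vs-random preprocessing: ",
           conditionMessage(e)))
    # seed GLM on the flow-vs-blank run
    des_f <- build_design(config$acq, pf$seg, config$hrf,
                          trace = sub$fvb$motion)
    Yf <- .filtered_matrix(pf$run, pf$seg, config$highpass_cycles)
    fit_f <- fit_glm(Yf, des_f)
    fit_f$zmap <- array(fit_f$zmap, dim(pf$run$data)[1:3])
    fit_f$dim <- dim(pf$run$data)[1:3]
    seed <- select_v1_seed(fit_f, config$seed_p, hint = seed_hint,
                           voxel_mm = pf$run$voxel_mm)
    # lagged-correlation mask from the seed signal, on the same run
    seed_series <- rowMeans(Yf[, .lin_index(seed$voxels,
                                            dim(pf$run$data)[1:3]),
                               drop = FALSE])
    zsc <- function(M) sweep(sweep(M, 2, colMeans(M)), 2,
                             pmax(apply(M, 2, stats::sd), 1e-12), "/")
    cmask <- lagged_correlation_mask(as.numeric(scale(seed_series)),
                                     zsc(Yf), delays_s = config$delays_s,
                                     alpha = config$mask_alpha,
                                     TR = config$acq$TR)
    # masked coherent-vs-random GLM
    des_c <- build_design(config$acq, pc$seg, config$hrf,
                          trace = sub$cvr$motion)
    Yc <- .filtered_matrix(pc$run, pc$seg, config$highpass_cycles)
    fit_c <- fit_glm(Yc, des_c)
    d3 <- dim(pc$run$data)[1:3]
    zmap <- array(fit_c$zmap, d3)
    zmap[!cmask$mask] <- 0
    rois <- threshold_and_cluster(zmap, alpha = config$roi_alpha,
                                  min_cluster_mm3 = config$cluster_mm3,
                                  voxel_mm = pc$run$voxel_mm)
    roi_tables[[id]] <- write_roi_table(rois)
    for (r in rois) {
      tc <- extract_timecourse(pc$run, r, pc$seg)
      sp <- sn_phase(highpass_fourier(tc, config$highpass_cycles),
                     config$acq, config$hrf)
      snp[[length(snp) + 1]] <- data.frame(
        subject = id, roi = r$label, hemi = r$hemisphere, sn = sp$sn,
        phase_deg = sp$phase_deg, tier = sp$tier)
    }
    seeds[[id]] <- seed
    masks[[id]] <- cmask
    cvr_runs[[id]] <- pc$run
    cvr_designs[[id]] <- des_c
    log[[id]] <- list(retained_fvb = pf$seg$retained_fraction,
                      retained_cvr = pc$seg$retained_fraction,
                      mask_fraction = cmask$union_fraction,
                      n_clusters = length(rois))
  }
  group <- fixed_effects_group(cvr_runs, cvr_designs, fdr_q = config$fdr_q,
                               min_cluster_mm3 = config$cluster_mm3)
  list(roi_tables = roi_tables,
       sn_phase = if (length(snp)) do.call(rbind, snp) else NULL,
       group = group, seeds = seeds, masks = masks, log = log)
}
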