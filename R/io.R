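#' Write a BOLD run as NIfTI-1 with a JSON sidecar
#'
#' The 4D intensity grid goes to `<path>.nii` (uncompressed NIfTI-1 via
#' RNifti) and the acquisition metadata (type, TR, condition labels, seed)
#' to `<path>.json`. The motion trace, when present, is written as a
#' six-column TSV `<path>_motion.tsv`.
#'
#' @param run a [bold_run()].
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data,
                         pixdim = c(rep(run$voxel_mm, 3), run$acq$TR))
  RNifti::writeNifti(img, paste0(path, ".nii"), compression = 0)
  meta <- list(type = run$acq$type, TR = run$acq$TR,
               block_s = run$acq$block_s, n_cycles = run$acq$n_cycles,
               n_timepoints = run$acq$n_timepoints,
               n_dummy = run$acq$n_dummy, voxel_mm = run$voxel_mm,
               condition = run$condition, seed = run$seed)
  write_json_file(meta, paste0(path, ".json"))
  if (!is.null(run$motion))
    utils::write.table(run$motion, paste0(path, "_motion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BOLD run written by [write_bold_run()]
#' @param path path without extension.
#' @return A [bold_run()].
#' @export
read_bold_run <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  acq <- if (meta$type == "task")
    acquisition_spec("task", TR = meta$TR, block_s = meta$block_s,
                     n_cycles = meta$n_cycles, n_dummy = meta$n_dummy)
  else acquisition_spec("rest", TR = meta$TR,
                        n_timepoints = meta$n_timepoints,
                        n_dummy = meta$n_dummy)
  motion_path <- paste0(path, "_motion.tsv")
  motion <- if (file.exists(motion_path))
    as.matrix(utils::read.table(motion_path, header = TRUE, sep = "\t"))
  else NULL
  cond <- meta$condition
  if (length(cond) == 0) cond <- NULL
  bold_run(array(as.numeric(img), dim = dim(img)), acq,
           voxel_mm = meta$voxel_mm, condition = cond, motion = motion,
           seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write an ROI table as TSV
#'
#' One row per ROI with the reporting convention of the study tables:
#' label, hemisphere, voxel count, centre-of-mass coordinates in mm from the
#' grid centre (chi, psi, zeta) and peak Z.
#'
#' @param rois list of `roi` objects.
#' @param path output TSV path (omit to only return the data frame).
#' @return The ROI data frame, invisibly when written.
#' @export
write_roi_table <- function(rois, path = NULL) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, hemi = r$hemisphere, n = r$n,
               chi = round(r$com_mm[1], 1), psi = round(r$com_mm[2], 1),
               zeta = round(r$com_mm[3], 1),
               Zpeak = round(r$peak_z, 2))))
  if (is.null(df))
    df <- data.frame(label = character(0), hemi = character(0),
                     n = integer(0), chi = numeric(0), psi = numeric(0),
                     zeta = numeric(0), Zpeak = numeric(0))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write a labelled matrix as TSV
#' @param m matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(roi = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a list as pretty JSON
#' @param x list to serialise.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a 3D map as NIfTI-1
#' @param map 3D numeric or logical array.
#' @param path output `.nii` path.
#' @param voxel_mm isotropic voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_mm = 3) {
  img <- RNifti::asNifti(map * 1, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path, compression = 0)
  invisible(path)
}
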