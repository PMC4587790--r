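#' ROI-by-ROI resting-state correlation matrix
#'
#' Extracts ROI-mean series over the retained time points, applies the
#' two-cycle Fourier high-pass, and computes all pairwise Pearson
#' correlations. Because of the high-pass filtering, negative correlations
#' are retained and interpretable.
#'
#' @param run a [bold_run()] (rest), or a time x ROI matrix of extracted
#'   series.
#' @param rois list of `roi` objects (or voxel matrices); names become row
#'   and column labels. Ignored for matrix input.
#' @param seg `run_segments`; defaults to the full run.
#' @param highpass_cycles cycles removed by the high-pass (0 to skip).
#' @return A `connectivity_matrix`: the labelled correlation matrix with the
#'   extracted series in attribute `"series"`.
#' @export
roi_correlation_matrix <- function(run, rois = NULL, seg = NULL,
                                   highpass_cycles = 2) {
  if (inherits(run, "bold_run")) {
    if (is.null(seg)) seg <- full_segments(run$acq)
    if (sum(seg$retained) < 10) stop("need at least 10 retained time points")
    S <- sapply(rois, function(r) extract_timecourse(run, r, seg))
    if (!is.null(names(rois))) colnames(S) <- names(rois)
  } else {
    S <- as.matrix(run)
    if (nrow(S) < 10) stop("need at least 10 retained time points")
  }
  if (highpass_cycles > 0) S <- highpass_fourier(S, highpass_cycles)
  sds <- apply(S, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("constant ROI series: correlation undefined for '",
         paste(colnames(S)[sds < 1e-12], collapse = "', '"), "'")
  M <- stats::cor(S)
  structure(M, series = S, class = c("connectivity_matrix", "matrix"))
}

#' Super-subject correlation significance
#'
#' Z-scores each subject's ROI series, concatenates the subjects into one
#' super-subject per ROI, and computes the Pearson correlation per ROI pair
#' with its p-value from the t distribution at `df = total length - 2`.
#' When all subjects contribute equal-length z-scored series, the
#' super-subject correlation equals the mean of the per-subject
#' correlations.
#'
#' @param series_list list of time x ROI matrices (all with the same ROI
#'   columns), one per subject; typically the `"series"` attribute of
#'   [roi_correlation_matrix()] results.
#' @return A list: `r` (matrix), `p` (matrix), `n` (total concatenated
#'   length).
#' @export
supersubject_significance <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  k <- ncol(series_list[[1]])
  zs <- lapply(series_list, function(S) {
    S <- as.matrix(S)
    if (ncol(S) != k) stop("all subjects must share the ROI set")
    sds <- apply(S, 2, stats::sd)
    if (any(sds < 1e-12)) stop("subject with constant ROI series")
    scale(S)
  })
  big <- do.call(rbind, zs)
  n <- nrow(big)
  r <- stats::cor(big)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- 0
  dimnames(p) <- dimnames(r)
  list(r = r, p = p, n = n)
}

#' Compare two groups of connectivity matrices cell by cell
#'
#' For each ROI pair, a two-sample two-tailed t test between the groups'
#' correlation values, Fisher-z transformed by default for variance
#' stabilisation. Cells are flagged at the two conventional tiers
#' (`p < 0.01`, `p < 0.05`).
#'
#' @param group_a,group_b lists of correlation matrices (one per subject),
#'   identical ROI order.
#' @param fisher_z transform correlations by `atanh` before testing.
#' @return A list: `t`, `p`, `tier` (character matrix: `"p<0.01"`,
#'   `"p<0.05"` or `""`), `mean_a`, `mean_b` (group-mean correlation
#'   matrices, untransformed).
#' @export
compare_group_matrices <- function(group_a, group_b, fisher_z = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 matrices per group")
  k <- nrow(group_a[[1]])
  stack <- function(g) vapply(g, function(m) as.matrix(m), matrix(0, k, k))
  A <- stack(group_a); B <- stack(group_b)
  mean_a <- apply(A, 1:2, mean); mean_b <- apply(B, 1:2, mean)
  if (fisher_z) {
    A <- atanh(pmin(pmax(A, -1 + 1e-12), 1 - 1e-12))
    B <- atanh(pmin(pmax(B, -1 + 1e-12), 1 - 1e-12))
  }
  na <- dim(A)[3]; nb <- dim(B)[3]
  ma <- apply(A, 1:2, mean); mb <- apply(B, 1:2, mean)
  va <- apply(A, 1:2, stats::var); vb <- apply(B, 1:2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tmat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tmat[!is.finite(tmat)] <- 0
  df <- na + nb - 2
  p <- 2 * stats::pt(abs(tmat), df, lower.tail = FALSE)
  diag(p) <- 1
  tier <- matrix("", k, k, dimnames = dimnames(mean_a))
  tier[p < 0.05] <- "p<0.05"
  tier[p < 0.01] <- "p<0.01"
  diag(tier) <- ""
  dimnames(tmat) <- dimnames(p) <- dimnames(mean_a) <-
    dimnames(mean_b) <- dimnames(group_a[[1]])
  list(t = tmat, p = p, df = df, tier = tier,
       mean_a = mean_a, mean_b = mean_b)
}
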