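#' Build a design matrix for the periodic GLM
#'
#' The task regressor is the boxcar for the first-condition blocks convolved
#' with the gamma HRF (the steady-state periodic convolution of
#' [canonical_response()]), sampled at the TR and restricted to the retained
#' time points. Six motion regressors (mean-centred over retained rows) are
#' included when a trace is supplied, and one constant column per segment
#' absorbs segment-wise baselines.
#'
#' @param acq a task [acquisition_spec()].
#' @param seg `run_segments` (use [full_segments()] for an unscrubbed run).
#' @param hrf an [hrf_params()].
#' @param trace optional n x 6 motion matrix aligned to the full run.
#' @return An object of class `design_matrix` with elements `X` (rows =
#'   retained time points), `task_col`, `rows` (original time-point indices)
#'   and `col_names`.
#' @export
build_design <- function(acq, seg = full_segments(acq), hrf = hrf_params(),
                         trace = NULL) {
  stopifnot(acq$type == "task", inherits(seg, "run_segments"))
  if (nrow(seg$intervals) == 0) stop("no retained segments")
  rows <- which(seg$retained)
  task_full <- canonical_response(acq, hrf)
  task <- task_full[rows]
  nseg <- nrow(seg$intervals)
  const <- matrix(0, length(rows), nseg)
  for (s in seq_len(nseg))
    const[rows >= seg$intervals$start[s] & rows <= seg$intervals$end[s], s] <- 1
  X <- cbind(task, const)
  cn <- c("task", paste0("const", seq_len(nseg)))
  if (!is.null(trace)) {
    trace <- as.matrix(trace)
    if (nrow(trace) != acq$n_timepoints)
      stop("motion trace length does not match the run")
    mo <- trace[rows, , drop = FALSE]
    mo <- sweep(mo, 2, colMeans(mo))
    keep <- apply(mo, 2, function(c) stats::sd(c) > 1e-12)
    if (any(keep)) {
      X <- cbind(X[, 1, drop = FALSE], mo[, keep, drop = FALSE],
                 X[, -1, drop = FALSE])
      cn <- c("task", paste0("motion", which(keep)), cn[-1])
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  structure(list(X = X, task_col = 1L, rows = rows, col_names = cn),
            class = "design_matrix")
}

#' Fit a voxelwise ordinary-least-squares GLM
#'
#' Fits `Y = X beta + e` independently per voxel and computes the contrast
#' t statistic `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` with
#' `df = n - rank(X)`, mapped to a Z score through the probit transform of
#' the exact t distribution (two-sided preserving: `Z` and `t` share sign
#' and tail probability).
#'
#' @param run a [bold_run()], or a matrix with one column per voxel whose
#'   rows already match the design.
#' @param design a [build_design()] result.
#' @param contrast numeric weight vector over design columns, or a single
#'   column name; defaults to the task column.
#' @return An object of class `glm_result`: `beta` (contrast effect map),
#'   `tmap`, `zmap`, `sigma2`, `df`, and the grid `dim` (for matrix input, a
#'   1-voxel-thick pseudo-grid).
#' @export
fit_glm <- function(run, design, contrast = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(run, "bold_run")) {
    d3 <- dim(run$data)[1:3]
    Y <- matrix(run$data, prod(d3), dim(run$data)[4])
    Y <- t(Y[, design$rows, drop = FALSE])
  } else {
    Y <- as.matrix(run)
    if (nrow(Y) != length(design$rows))
      stop("rows of Y must match the retained time points of the design")
    d3 <- c(ncol(Y), 1L, 1L)
  }
  X <- design$X
  p <- ncol(X)
  if (is.null(contrast)) {
    contrast <- rep(0, p); contrast[design$task_col] <- 1
  } else if (is.character(contrast)) {
    contrast <- as.numeric(design$col_names == contrast)
  }
  if (length(contrast) != p) stop("contrast length must match design columns")
  if (all(contrast == 0)) stop("contrast must not be all zeros")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is singular")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - p
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  eff <- drop(t(contrast) %*% beta)
  tmap <- eff / sqrt(sigma2 * cvar)
  tmap[sigma2 <= 0] <- 0
  zmap <- z_from_t(tmap, df)
  structure(list(beta = array(eff, d3), tmap = array(tmap, d3),
                 zmap = array(zmap, d3), sigma2 = array(sigma2, d3),
                 df = df, dim = d3), class = "glm_result")
}

#' Probit-transform t statistics to Z scores
#'
#' Maps each t value to the standard-normal deviate with the same one-sided
#' tail probability, preserving sign and two-sided p-values. Computed on the
#' log scale for stability in the far tails.
#'
#' @param t t statistics.
#' @param df residual degrees of freedom.
#' @return Z scores.
#' @export
z_from_t <- function(t, df) {
  z <- sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE,
                                        log.p = TRUE),
                              lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  z
}

#' Threshold a Z map and extract clusters
#'
#' Voxels exceeding the threshold (two-tailed `alpha` mapped to
#' `qnorm(1 - alpha/2)`, or an explicit `z_min`) are grouped into connected
#' components under 6-neighbour connectivity, separately for positive and
#' negative excursions. Components smaller than the minimum cluster volume
#' are dropped. Each surviving cluster is reported as an ROI with voxel
#' count, |Z|-weighted centre of mass in millimetres from the grid centre,
#' and peak Z.
#'
#' @param zmap 3D numeric array of Z scores.
#' @param alpha two-tailed significance level (ignored if `z_min` given).
#' @param z_min explicit |Z| threshold.
#' @param min_cluster_mm3 minimum cluster volume in cubic millimetres.
#' @param voxel_mm isotropic voxel size in millimetres.
#' @return A list of `roi` objects (possibly empty), positive clusters
#'   first, each sorted by decreasing size.
#' @export
threshold_and_cluster <- function(zmap, alpha = 0.05, z_min = NULL,
                                  min_cluster_mm3 = 81, voxel_mm = 3) {
  stopifnot(all(is.finite(zmap)))
  if (is.null(z_min)) z_min <- stats::qnorm(1 - alpha / 2)
  min_vox <- ceiling(min_cluster_mm3 / voxel_mm^3 - 1e-9)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) zmap >= z_min else zmap <= -z_min
    comps <- connected_components(mask)
    comps <- comps[vapply(comps, nrow, 1L) >= min_vox]
    if (length(comps) == 0) next
    comps <- comps[order(-vapply(comps, nrow, 1L))]
    for (i in seq_along(comps)) {
      vox <- comps[[i]]
      out[[length(out) + 1]] <- roi_from_voxels(
        vox, zmap, voxel_mm,
        label = sprintf("%s%d", if (sgn > 0) "pos" else "neg", i))
    }
  }
  out
}

#' Connected components of a 3D logical mask (6-neighbourhood)
#'
#' @param mask 3D logical array.
#' @return A list of n x 3 integer voxel-index matrices, one per component.
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  lab <- array(0L, d)
  idx <- which(mask)
  comps <- list()
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (lab[start] != 0L) next
    lab[start] <- 1L
    queue <- start
    members <- start
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      for (k in 1:6) {
        p <- co + nb[k, ]
        if (any(p < 1) || any(p > d)) next
        lin <- (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- 1L
          queue <- c(queue, lin)
          members <- c(members, lin)
        }
      }
    }
    comps[[length(comps) + 1]] <- arrayInd(members, d)
  }
  comps
}

#' Construct an ROI from a voxel set and a statistic map
#'
#' @param vox n x 3 integer voxel-index matrix.
#' @param zmap 3D statistic array used for weighting and the peak.
#' @param voxel_mm isotropic voxel size in mm.
#' @param label ROI label.
#' @param hemisphere optional hemisphere tag; inferred from the centre of
#'   mass sign on x when omitted (`"L"` for negative, `"R"` for positive,
#'   `"M"` near the midline).
#' @return An object of class `roi` with fields `label`, `hemisphere`,
#'   `voxels`, `n`, `com_mm` (mm from the grid centre) and `peak_z`.
#' @export
roi_from_voxels <- function(vox, zmap = NULL, voxel_mm = 3, label = "roi",
                            hemisphere = NULL) {
  vox <- as.matrix(vox)
  stopifnot(ncol(vox) == 3, nrow(vox) >= 1)
  d <- if (is.null(zmap)) apply(vox, 2, max) else dim(zmap)
  if (is.null(zmap)) {
    w <- rep(1, nrow(vox)); peak <- NA_real_
  } else {
    z <- zmap[vox]
    w <- abs(z)
    if (sum(w) == 0) w <- rep(1, nrow(vox))
    peak <- z[which.max(abs(z))]
  }
  ctr <- (d + 1) / 2
  com_vox <- colSums(vox * w) / sum(w)
  com_mm <- (com_vox - ctr) * voxel_mm
  if (is.null(hemisphere))
    hemisphere <- if (com_mm[1] < -voxel_mm) "L" else
      if (com_mm[1] > voxel_mm) "R" else "M"
  structure(list(label = label, hemisphere = hemisphere, voxels = vox,
                 n = nrow(vox), com_mm = com_mm, peak_z = peak),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s (%s): n=%d, com=(%.1f, %.1f, %.1f) mm, peak Z=%s\n",
              x$label, x$hemisphere, x$n, x$com_mm[1], x$com_mm[2],
              x$com_mm[3],
              if (is.na(x$peak_z)) "NA" else sprintf("%.2f", x$peak_z)))
  invisible(x)
}

#' Fixed-effects multi-subject GLM with FDR correction
#'
#' Concatenates subjects' retained time points on a common voxel grid and
#' fits a single GLM in which the task effect is shared (fixed) across
#' subjects while nuisance columns (segment constants, motion) stay
#' subject-specific. Voxelwise two-sided p-values for the task contrast are
#' corrected by Benjamini-Hochberg; voxels with `q < fdr_q` form the group
#' mask, to which the minimum cluster volume is applied.
#'
#' @param runs list of [bold_run()] objects on identical grids.
#' @param designs list of matching [build_design()] results.
#' @param fdr_q FDR level.
#' @param min_cluster_mm3 minimum cluster volume (mm^3).
#' @return A list: `zmap`, `tmap`, `df`, `p`, `q` (3D arrays), `mask`
#'   (q-thresholded plus cluster floor), and `rois`.
#' @export
fixed_effects_group <- function(runs, designs, fdr_q = 0.05,
                                min_cluster_mm3 = 81) {
  stopifnot(length(runs) >= 1, length(runs) == length(designs))
  d3 <- dim(runs[[1]]$data)[1:3]
  voxel_mm <- runs[[1]]$voxel_mm
  for (r in runs)
    if (!all(dim(r$data)[1:3] == d3)) stop("runs must share one voxel grid")
  Ys <- list(); Xs <- list()
  for (i in seq_along(runs)) {
    Y <- matrix(runs[[i]]$data, prod(d3), dim(runs[[i]]$data)[4])
    Ys[[i]] <- t(Y[, designs[[i]]$rows, drop = FALSE])
    Xs[[i]] <- designs[[i]]$X
  }
  nrows <- vapply(Ys, nrow, 1L)
  task <- unlist(lapply(seq_along(Xs), function(i)
    Xs[[i]][, designs[[i]]$task_col]))
  nuis_cols <- lapply(Xs, function(X) X[, -1, drop = FALSE])
  p_nuis <- vapply(nuis_cols, ncol, 1L)
  Xbig <- matrix(0, sum(nrows), 1 + sum(p_nuis))
  Xbig[, 1] <- task
  ro <- cumsum(c(0, nrows)); co <- cumsum(c(1, p_nuis))
  for (i in seq_along(Xs))
    Xbig[(ro[i] + 1):ro[i + 1], (co[i] + 1):co[i + 1]] <- nuis_cols[[i]]
  Ybig <- do.call(rbind, Ys)
  des <- structure(list(X = Xbig, task_col = 1L,
                        rows = seq_len(nrow(Xbig)),
                        col_names = c("task", paste0("n", seq_len(sum(p_nuis))))),
                   class = "design_matrix")
  fit <- fit_glm(Ybig, des)
  tv <- fit$tmap
  pv <- 2 * stats::pt(abs(tv), fit$df, lower.tail = FALSE)
  qv <- array(stats::p.adjust(pv, method = "BH"), d3)
  zmap <- array(fit$zmap, d3)
  mask <- array(qv < fdr_q, d3)
  min_vox <- ceiling(min_cluster_mm3 / voxel_mm^3 - 1e-9)
  comps <- connected_components(mask)
  comps <- comps[vapply(comps, nrow, 1L) >= min_vox]
  mask2 <- array(FALSE, d3)
  rois <- list()
  for (i in seq_along(comps)) {
    mask2[comps[[i]]] <- TRUE
    rois[[i]] <- roi_from_voxels(comps[[i]], zmap, voxel_mm,
                                 label = paste0("group", i))
  }
  list(zmap = zmap, tmap = array(tv, d3), df = fit$df,
       p = array(pv, d3), q = qv, mask = mask2, rois = rois)
}
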