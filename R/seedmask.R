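#' Select the bilateral V1 seed from a flow-versus-blank contrast
#'
#' Identifies the strong bilateral calcarine response: positive
#' supra-threshold voxels are clustered within each hemisphere (split at the
#' grid midline on x) and the largest cluster per hemisphere is taken. An
#' optional hint ROI restricts the candidate clusters to those overlapping
#' it (in synthetic data, the layout's V1 labels). The seed is the union of
#' the two clusters; its reported centre of mass is the average of the two
#' foci.
#'
#' @param glm_result a [fit_glm()] result for the flow-vs-blank contrast on
#'   a 3D grid.
#' @param threshold_p two-tailed voxelwise p threshold (0.001 by default).
#' @param hint optional `roi` (or n x 3 voxel matrix) that candidate
#'   clusters must intersect.
#' @param voxel_mm isotropic voxel size in mm.
#' @param min_voxels smallest candidate cluster (defaults to the three-voxel
#'   cluster floor, so isolated noise voxels never qualify as a seed).
#' @return An `roi` labelled `"V1_seed"` spanning both hemispheres.
#' @export
select_v1_seed <- function(glm_result, threshold_p = 0.001, hint = NULL,
                           voxel_mm = 3, min_voxels = 3) {
  stopifnot(inherits(glm_result, "glm_result"))
  zmap <- glm_result$zmap
  if (length(dim(zmap)) != 3) stop("seed selection needs a 3D Z map")
  z_min <- stats::qnorm(1 - threshold_p / 2)
  d <- dim(zmap)
  mid <- (d[1] + 1) / 2
  hint_vox <- if (is.null(hint)) NULL else
    if (inherits(hint, "roi")) hint$voxels else as.matrix(hint)
  pick <- function(side) {
    mask <- zmap >= z_min
    co <- which(mask, arr.ind = TRUE)
    keep <- if (side == "L") co[, 1] < mid else co[, 1] > mid
    mask[] <- FALSE
    mask[co[keep, , drop = FALSE]] <- TRUE
    comps <- connected_components(mask)
    comps <- comps[vapply(comps, nrow, 1L) >= min_voxels]
    if (!is.null(hint_vox) && length(comps)) {
      hin <- paste(hint_vox[, 1], hint_vox[, 2], hint_vox[, 3])
      comps <- comps[vapply(comps, function(v)
        any(paste(v[, 1], v[, 2], v[, 3]) %in% hin), TRUE)]
    }
    if (length(comps) == 0)
      stop("no supra-threshold calcarine cluster in the ",
           if (side == "L") "left" else "right",
           " hemisphere at p < ", threshold_p)
    comps[[which.max(vapply(comps, nrow, 1L))]]
  }
  vl <- pick("L"); vr <- pick("R")
  rl <- roi_from_voxels(vl, zmap, voxel_mm, "V1_L", "L")
  rr <- roi_from_voxels(vr, zmap, voxel_mm, "V1_R", "R")
  seed <- roi_from_voxels(rbind(vl, vr), zmap, voxel_mm, "V1_seed", "bilateral")
  seed$com_mm <- (rl$com_mm + rr$com_mm) / 2
  seed
}

#' Two-tailed critical Pearson correlation
#'
#' The |r| above which a sample correlation over `n` paired observations is
#' significant at two-tailed level `alpha` under the t distribution with
#' `n - 2` degrees of freedom: `r* = t* / sqrt(df + t*^2)`.
#'
#' @param n number of paired observations.
#' @param alpha two-tailed significance level.
#' @return Critical |r|.
#' @examples
#' critical_r(63)   # ~0.25, the mask threshold for a 63-point series
#' @export
critical_r <- function(n, alpha = 0.05) {
  df <- n - 2
  if (df < 3) stop("overlap too short: need at least 5 points")
  tstar <- stats::qt(1 - alpha / 2, df)
  tstar / sqrt(df + tstar^2)
}

#' Lagged-correlation functional mask from a seed series
#'
#' Cross-correlates the seed time course with every voxel at each
#' hemodynamic delay: for delay `d`, the Pearson correlation between
#' `seed(t)` and `voxel(t + d)` over the overlapping window. A voxel enters
#' the mask when |r| exceeds the two-tailed critical value at any delay
#' (union over delays); positive and negative correlations are both
#' retained. The default delays 0 and 3 s allow for variability in the
#' hemodynamic time constant.
#'
#' @param seed_series numeric seed time course (same sampling as the run).
#' @param run a [bold_run()] or a time x voxel matrix.
#' @param delays_s delays in seconds, each a multiple of the TR.
#' @param alpha two-tailed significance level for the critical |r|.
#' @param TR repetition time in seconds (taken from the run when it is a
#'   `bold_run`).
#' @return A list of class `correlation_mask`: `mask` (logical, voxel
#'   space), `r_maps` (one per delay), `critical_r` (per delay),
#'   `marked_fraction` (per delay) and `union_fraction`.
#' @export
lagged_correlation_mask <- function(seed_series, run, delays_s = c(0, 3),
                                    alpha = 0.05, TR = NULL) {
  if (inherits(run, "bold_run")) {
    TR <- run$acq$TR
    d3 <- dim(run$data)[1:3]
    Y <- t(matrix(run$data, prod(d3), dim(run$data)[4]))
  } else {
    if (is.null(TR)) stop("TR must be given for matrix input")
    Y <- as.matrix(run)
    d3 <- c(ncol(Y), 1L, 1L)
  }
  n <- length(seed_series)
  if (n != nrow(Y)) stop("seed series and run must share time points")
  lags <- delays_s / TR
  if (any(abs(lags - round(lags)) > 1e-9))
    stop("delays must be multiples of the TR")
  lags <- as.integer(round(lags))
  r_maps <- list(); crit <- numeric(0); frac <- numeric(0)
  mask_v <- rep(FALSE, ncol(Y))
  for (i in seq_along(lags)) {
    l <- lags[i]
    n_ov <- n - l
    if (n_ov - 2 < 3) stop("overlap too short at delay ", delays_s[i], " s")
    s <- seed_series[seq_len(n_ov)]
    V <- Y[(1 + l):n, , drop = FALSE]
    r <- suppressWarnings(as.numeric(stats::cor(s, V)))
    r[is.na(r)] <- 0
    cr <- critical_r(n_ov, alpha)
    r_maps[[i]] <- array(r, d3)
    crit[i] <- cr
    frac[i] <- mean(abs(r) > cr)
    mask_v <- mask_v | abs(r) > cr
  }
  names(r_maps) <- paste0("delay_", delays_s, "s")
  structure(list(mask = array(mask_v, d3), r_maps = r_maps,
                 critical_r = stats::setNames(crit, names(r_maps)),
                 marked_fraction = stats::setNames(frac, names(r_maps)),
                 union_fraction = mean(mask_v), delays_s = delays_s,
                 alpha = alpha),
            class = "correlation_mask")
}

#' @export
print.correlation_mask <- function(x, ...) {
  cat(sprintf("<correlation_mask> delays {%s} s, union fraction %.3f\n",
              paste(x$delays_s, collapse = ", "), x$union_fraction))
  invisible(x)
}
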