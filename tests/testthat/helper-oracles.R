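# Independent oracles used across the suite.

# Brute-force 6-neighbour flood fill over a logical 3D array, recursive
# region growing by repeated dilation (no shared code with the package).
oracle_components <- function(mask) {
  d <- dim(mask)
  remaining <- which(mask)
  comps <- list()
  while (length(remaining)) {
    seed <- remaining[1]
    comp <- seed
    repeat {
      co <- arrayInd(comp, d)
      cand <- unique(do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
        rbind(co[i, ] + c(1, 0, 0), co[i, ] - c(1, 0, 0),
              co[i, ] + c(0, 1, 0), co[i, ] - c(0, 1, 0),
              co[i, ] + c(0, 0, 1), co[i, ] - c(0, 0, 1))
      })))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
        cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
      grown <- union(comp, lin[mask[lin]])
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# Hand-computed Benjamini-Hochberg rejection set at level q.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  if (length(k) == 0) return(logical(m))
  reject <- logical(m)
  reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Closed-form OLS via explicit normal equations.
oracle_ols <- function(X, y, contrast) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  eff <- sum(contrast * beta)
  list(beta = beta, eff = eff,
       t = eff / sqrt(s2 * drop(t(contrast) %*% solve(XtX) %*% contrast)),
       df = df)
}

tiny_layout <- function(phase_deg = 64, sign = 1, amplitude_pct = 1,
                        dim = c(8, 8, 4)) {
  region_layout(dim = dim, regions = list(
    R1 = list(voxels = voxel_block(3:5, 3:5, 2:4), sign = sign,
              amplitude_pct = amplitude_pct, phase_deg = phase_deg)))
}
tiny_vox <- function() voxel_block(3:5, 3:5, 2:4)
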