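#' Intensity-based similarity costs
#'
#' Mutual information (the primary cost) and correlation ratio (the
#' fallback) between a fixed volume and a moving volume mapped through a
#' candidate transform. Both are computed from samples taken at fixed
#' voxel centres (optionally restricted to a mask), with the moving
#' intensity interpolated trilinearly at the mapped world point; samples
#' mapping outside the moving field of view are discarded. Intensity
#' ranges are clipped to the 2nd-98th percentile of each image so that
#' dropout/hyperintense tails do not waste histogram bins.
#'
#' @name costs
NULL

robust_range <- function(v, probs = c(0.02, 0.98)) {
  r <- unname(quantile(v, probs, type = 7))
  if (r[2] <= r[1]) r <- range(v)
  if (r[2] <= r[1]) r[2] <- r[1] + 1
  r
}

# Shared sampling setup: fixed-sample world coords + intensities.
# With `jitter`, sample positions are displaced by a seeded uniform
# sub-voxel offset and fixed intensities interpolated there: off-grid
# sampling prevents the classic MI interpolation artifact in which
# grid-commensurate transforms look spuriously sharp because trilinear
# interpolation smooths noise everywhere except on the grid.
cost_samples <- function(fixed, mask = NULL, jitter = FALSE, seed = 0L,
                         oversample = 1L) {
  idx <- if (is.null(mask)) {
    which(fixed$data > 0)
  } else {
    stopifnot(all(dim(mask$data) == dim(fixed$data)))
    which(mask$data)
  }
  if (length(idx) == 0L) stop("cost_samples: empty mask", call. = FALSE)
  shape <- dim(fixed$data)
  i0 <- idx - 1L
  if (jitter && oversample > 1L) i0 <- rep(i0, oversample)
  vox <- rbind(i0 %% shape[1],
               (i0 %/% shape[1]) %% shape[2],
               i0 %/% (shape[1] * shape[2]))
  if (jitter) {
    u <- with_seed(seed,
                   matrix(runif(length(i0) * 3, -0.5, 0.5), 3))
    vox <- vox + u
    vox <- pmin(pmax(vox, 0), shape - 1)
    fvals <- cpp_interp_points(as.numeric(fixed$data), shape, vox)
  } else {
    fvals <- as.numeric(fixed$data[idx])
  }
  pts <- fixed$affine[1:3, 1:3] %*% vox + fixed$affine[1:3, 4]
  list(pts = pts, fvals = fvals)
}

#' Mutual information between fixed and transformed moving volume
#'
#' `MI = H(fixed) + H(moving) - H(fixed, moving)` in bits (log base 2),
#' estimated from the joint histogram of fixed intensities and
#' interpolated moving intensities over the overlap. Intensities are
#' soft-assigned to bins with linear weights for a smooth cost surface.
#'
#' @param fixed,moving `image_volume`s.
#' @param A 4x4 affine mapping moving world to fixed world (identity by
#'   default).
#' @param bins joint-histogram bins per axis (>= 8).
#' @param mask optional [brain_mask()] on the fixed grid restricting the
#'   sampled voxels; default: fixed voxels with intensity > 0.
#' @param min_overlap minimum number of overlapping samples below which
#'   an overlap error (a diverged transform) is raised.
#' @param fixed_range,moving_range optional explicit intensity ranges
#'   `c(min, max)` for the histogram axes; default is the robust
#'   2nd-98th percentile range.
#' @return MI in bits (a single number, >= 0 up to floating error).
#' @export
mutual_information <- function(fixed, moving, A = diag(4), bins = 64L,
                               mask = NULL, min_overlap = 1000L,
                               fixed_range = NULL, moving_range = NULL) {
  s <- cost_samples(fixed, mask)
  mi_from_samples(s, moving, A, bins, min_overlap, fixed_range,
                  moving_range)$mi
}

mi_from_samples <- function(s, moving, A, bins, min_overlap,
                            frange = NULL, mrange = NULL) {
  if (bins < 8L) stop("mutual_information: bins must be >= 8", call. = FALSE)
  if (is.null(frange)) frange <- robust_range(s$fvals)
  if (is.null(mrange)) mrange <- robust_range(as.numeric(moving$data))
  M <- solve(moving$affine) %*% solve(as_affine(A))
  r <- cpp_mi(s$fvals, frange[1], frange[2], as.numeric(moving$data),
              dim(moving$data), M, s$pts, mrange[1], mrange[2],
              as.integer(bins))
  if (r$n_overlap < min_overlap)
    stop("overlap error: only ", r$n_overlap,
         " samples map inside the moving volume (needed ", min_overlap,
         "); transform has likely diverged", call. = FALSE)
  r
}

#' Mutual information of a hand-built joint histogram
#'
#' Utility exposing the MI summation itself: given a matrix of joint
#' counts (or probabilities), returns
#' `sum p(f, m) log2( p(f, m) / (p(f) p(m)) )`.
#'
#' @param counts non-negative matrix of joint counts.
#' @return MI in bits.
#' @export
mi_from_joint <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("mi_from_joint: counts must be non-negative with positive sum",
         call. = FALSE)
  p <- counts / sum(counts)
  pf <- rowSums(p)
  pm <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (pf[row(p)[nz]] * pm[col(p)[nz]])))
}

#' Correlation ratio between fixed and transformed moving volume
#'
#' `1 - within-bin variance / total variance` of moving intensities
#' binned by fixed intensity; lies in \[0, 1\] and approaches 1 when the
#' moving intensity is a function of the fixed intensity. Used as the
#' fallback registration cost when MI fails on a sub-region.
#'
#' @inheritParams mutual_information
#' @return correlation ratio in \[0, 1\].
#' @export
correlation_ratio <- function(fixed, moving, A = diag(4), bins = 32L,
                              mask = NULL, min_overlap = 1000L) {
  s <- cost_samples(fixed, mask)
  cr_from_samples(s, moving, A, bins, min_overlap)$cr
}

cr_from_samples <- function(s, moving, A, bins, min_overlap,
                            frange = NULL) {
  if (is.null(frange)) frange <- robust_range(s$fvals)
  M <- solve(moving$affine) %*% solve(as_affine(A))
  r <- cpp_cr(s$fvals, frange[1], frange[2], as.numeric(moving$data),
              dim(moving$data), M, s$pts, as.integer(bins))
  if (r$n_overlap < min_overlap)
    stop("overlap error: only ", r$n_overlap,
         " samples map inside the moving volume (needed ", min_overlap,
         "); transform has likely diverged", call. = FALSE)
  if (!is.finite(r$total_var) || r$total_var <= 0)
    stop("degenerate input: moving intensities have zero variance over ",
         "the overlap", call. = FALSE)
  r
}
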