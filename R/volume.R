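#' Image volume: a 3D intensity grid with a voxel-to-world affine
#'
#' The universal raster type of the package: a numeric 3D array plus a 4x4
#' homogeneous matrix mapping 0-based voxel indices to world coordinates
#' (right-handed RAS, millimetres). This is the NIfTI convention, so
#' volumes round-trip losslessly through [read_volume()] / [write_volume()].
#'
#' @param data numeric 3D array of intensities.
#' @param affine 4x4 voxel-to-world matrix (0-based indices, world mm).
#'   Defaults to identity spacing at the origin.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("image_volume: `data` must be a 3D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("image_volume: `affine` must be 4x4", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("image_volume: singular voxel-to-world affine", call. = FALSE)
  structure(list(data = data, affine = unname(affine)),
            class = "image_volume")
}

#' Build a volume from voxel spacing and grid shape
#'
#' Convenience constructor for axis-aligned grids. The grid is centred on
#' the world origin unless `origin` is given (world coordinates of voxel
#' (0,0,0)).
#'
#' @param data 3D array.
#' @param spacing_mm length-3 positive voxel size in mm.
#' @param origin optional world position of voxel (0,0,0); default centres
#'   the grid on the origin.
#' @return an `image_volume`.
#' @export
image_volume_from_spacing <- function(data, spacing_mm, origin = NULL) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0))
    stop("image_volume_from_spacing: spacings must be > 0", call. = FALSE)
  shp <- dim(data)
  if (is.null(origin)) origin <- -spacing_mm * (shp - 1) / 2
  aff <- diag(c(spacing_mm, 1))
  aff[1:3, 4] <- origin
  image_volume(data, aff)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ",
      paste(signif(voxel_size(x), 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Grid shape of a volume
#' @param vol an `image_volume`.
#' @return integer length-3 vector of voxels per axis.
#' @export
grid_shape <- function(vol) dim(vol$data)

#' Voxel size of a volume
#'
#' Column norms of the 3x3 block of the voxel-to-world affine, i.e. the
#' physical step per voxel index along each grid axis.
#'
#' @param vol an `image_volume`.
#' @return numeric length-3 voxel size in mm.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param vol an `image_volume`.
#' @param idx 3 x N matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return 3 x N matrix of world mm coordinates.
#' @export
vox2world <- function(vol, idx) {
  idx <- as.matrix(idx)
  if (nrow(idx) != 3L) idx <- t(idx)
  h <- rbind(idx, 1)
  (vol$affine %*% h)[1:3, , drop = FALSE]
}

#' Map world coordinates to (continuous) voxel indices
#' @param vol an `image_volume`.
#' @param pts 3 x N matrix (or length-3 vector) of world mm coordinates.
#' @return 3 x N matrix of 0-based continuous voxel indices.
#' @export
world2vox <- function(vol, pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) != 3L) pts <- t(pts)
  h <- rbind(pts, 1)
  (solve(vol$affine) %*% h)[1:3, , drop = FALSE]
}

#' Trilinear interpolation of a volume at world coordinates
#'
#' @param vol an `image_volume`.
#' @param pts 3 x N matrix of world mm points.
#' @return numeric vector of interpolated intensities; `NA` outside the
#'   field of view.
#' @export
sample_at <- function(vol, pts) {
  vx <- world2vox(vol, pts)
  cpp_interp_points(as.numeric(vol$data), dim(vol$data), vx)
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian filtering with sigma given in millimetres and
#' converted per axis to voxel units, so anisotropic grids are smoothed
#' isotropically in world space.
#'
#' @param vol an `image_volume`.
#' @param sigma_mm smoothing sigma in mm (scalar or length 3).
#' @return smoothed `image_volume` on the same grid.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3L)
  sv <- sigma_mm / voxel_size(vol)
  out <- cpp_gauss3(as.numeric(vol$data), dim(vol$data), sv)
  image_volume(array(out, dim(vol$data)), vol$affine)
}

# Dyadic downsampling for the registration pyramid: smooth at ~0.5 * new
# voxel size then take every other voxel, keeping the world affine exact.
downsample2 <- function(vol) {
  vs <- voxel_size(vol)
  sm <- smooth_volume(vol, vs)  # sigma = old voxel size ~ antialias for 2x
  idx <- lapply(dim(vol$data), function(n) seq(1L, n, by = 2L))
  d <- sm$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  image_volume(d, aff)
}

#' Resample a moving volume through an affine transform onto a grid
#'
#' For each output-grid voxel, the world point is mapped through the
#' inverse of `A` into moving space and the moving volume is
#' interpolated trilinearly; points outside the moving field of view
#' become 0. With `A` the moving-to-fixed world transform returned by
#' [register()], this produces the moving volume aligned to the fixed
#' grid.
#'
#' @param moving an `image_volume`.
#' @param A 4x4 affine transform (moving world to fixed world).
#' @param fixed_grid target grid: an `image_volume` (its grid is used)
#'   or a list with `shape` and `affine`.
#' @param fill value for out-of-field voxels.
#' @return an `image_volume` on the target grid.
#' @export
resample_volume <- function(moving, A = diag(4), fixed_grid = moving,
                            fill = 0) {
  stopifnot(inherits(moving, "image_volume"))
  A <- as_affine(A)
  if (inherits(fixed_grid, "image_volume")) {
    oshape <- dim(fixed_grid$data); oaff <- fixed_grid$affine
  } else {
    oshape <- as.integer(fixed_grid$shape)
    oaff <- as.matrix(fixed_grid$affine)
  }
  M <- solve(moving$affine) %*% solve(A) %*% oaff
  d <- cpp_resample(as.numeric(moving$data), dim(moving$data), oshape, M,
                    fill)
  image_volume(array(d, oshape), oaff)
}

#' Crop a volume to a 0-based half-open index box
#'
#' @param vol an `image_volume`.
#' @param box 2 x 3 matrix: row 1 the 0-based inclusive start, row 2 the
#'   exclusive end, per axis.
#' @return the cropped `image_volume` with a translated affine, so crop
#'   voxels keep their world coordinates.
#' @export
crop_volume <- function(vol, box) {
  box <- as.matrix(box)
  shape <- dim(vol$data)
  if (any(box[1, ] < 0) || any(box[2, ] > shape) ||
      any(box[2, ] <= box[1, ]))
    stop("crop_volume: box outside the volume or empty", call. = FALSE)
  d <- vol$data[(box[1, 1] + 1):box[2, 1],
                (box[1, 2] + 1):box[2, 2],
                (box[1, 3] + 1):box[2, 3], drop = FALSE]
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% box[1, ]
  image_volume(d, aff)
}
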