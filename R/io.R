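#' Volume, transform and report file formats
#'
#' Volumes are NIfTI-1 (`.nii` / `.nii.gz`, float32, sform set from the
#' voxel-to-world affine); landmarks are TSV; transforms are 4-line text
#' matrices (see [write_affine()]); reports and phantom truth are JSON.
#'
#' @name io
NULL

#' Read a single 3D scalar NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unsupported format: cannot read '", path,
                         "' as NIfTI (", conditionMessage(e), ")",
                         call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), d)
  } else {
    stop("unsupported format: expected a single 3D scalar volume, got dims ",
         paste(d, collapse = "x"), call. = FALSE)
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  image_volume(img2, matrix(as.numeric(aff), 4, 4))
}

#' Write a volume as NIfTI-1
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(array(as.numeric(vol$data), dim(vol$data)))
  RNifti::pixdim(img) <- voxel_size(vol)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Serialize phantom ground truth as a JSON sidecar
#'
#' Matrices are written row-major; units are mm.
#'
#' @param truth a `phantom_truth` from
#'   [apply_ground_truth_distortion()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  obj <- list(
    true_affine_rowmajor = as.numeric(t(truth$true_affine)),
    warp = truth$warp,
    rotation_center_mm = truth$rotation_center,
    landmarks_ref = as.data.frame(unclass(truth$landmarks_ref)),
    landmarks_test = as.data.frame(unclass(truth$landmarks_test)),
    degradation = unclass(truth$degradation),
    seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Gradient-magnitude edge mask of a volume
#'
#' Central-difference gradient magnitude (per mm), thresholded at the
#' given percentile of its positive values.
#'
#' @param vol an `image_volume`.
#' @param percentile threshold percentile (default 90).
#' @return logical array of edge voxels.
#' @export
edge_mask <- function(vol, percentile = 90) {
  v <- vol$data
  vs <- voxel_size(vol)
  d <- dim(v)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (v[3:d[1], , ] - v[1:(d[1] - 2), , ]) /
    (2 * vs[1])
  gy[, 2:(d[2] - 1), ] <- (v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) /
    (2 * vs[2])
  gz[, , 2:(d[3] - 1)] <- (v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) /
    (2 * vs[3])
  g <- sqrt(gx^2 + gy^2 + gz^2)
  pos <- g[g > 0]
  if (length(pos) == 0L) return(array(FALSE, d))
  thr <- unname(quantile(pos, percentile / 100, type = 7))
  g >= thr
}

norm01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / diff(r)
}

#' Edge-overlay quality-control images
#'
#' Emulates the standard visual check of registration quality: edges of
#' the registered volume (gradient-magnitude threshold at the stated
#' percentile) are drawn in red over the grayscale reference for the
#' axial, coronal and sagittal mid-slices, and written as PNG files.
#'
#' @param reference,registered `image_volume`s on the same grid.
#' @param out_prefix path prefix for the three PNGs
#'   (`<prefix>_axial.png`, etc.).
#' @param percentile edge threshold percentile.
#' @return invisibly, a list with the `files` written and the 3D edge
#'   mask used.
#' @export
edge_overlay <- function(reference, registered, out_prefix,
                         percentile = 90) {
  stopifnot(inherits(reference, "image_volume"),
            inherits(registered, "image_volume"))
  if (!all(dim(reference$data) == dim(registered$data)) ||
      max(abs(reference$affine - registered$affine)) > 1e-6)
    stop("grid error: reference and registered volumes are on different grids",
         call. = FALSE)
  em <- edge_mask(registered, percentile)
  d <- dim(reference$data)
  mids <- floor(d / 2) + 1L
  planes <- list(
    axial = list(ref = reference$data[, , mids[3]],
                 edge = em[, , mids[3]]),
    coronal = list(ref = reference$data[, mids[2], ],
                   edge = em[, mids[2], ]),
    sagittal = list(ref = reference$data[mids[1], , ],
                    edge = em[mids[1], , ]))
  files <- character(0)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    g <- norm01(p$ref)
    rgb <- array(0, c(nrow(g), ncol(g), 3))
    rgb[, , 1] <- ifelse(p$edge, 1, g)
    rgb[, , 2] <- ifelse(p$edge, 0, g)
    rgb[, , 3] <- ifelse(p$edge, 0, g)
    # transpose to image row order (rows = y descending)
    rgb_img <- aperm(rgb[, ncol(g):1, , drop = FALSE], c(2, 1, 3))
    f <- paste0(out_prefix, "_", nm, ".png")
    png::writePNG(rgb_img, f)
    files <- c(files, f)
  }
  invisible(list(files = files, edges = em))
}
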