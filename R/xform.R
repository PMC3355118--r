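#' Affine transforms and distortion metrics
#'
#' Affine transforms are plain 4x4 homogeneous matrices mapping
#' moving-space world mm to fixed-space world mm, last row (0,0,0,1).
#' [decompose_affine()] factors the 3x3 block as R * S * H (rotation,
#' positive scales, unit-upper-triangular shear) and reports the
#' distortion metrics used throughout the package: maximum scaling
#' deviation from 1, maximum skew (the tangent of the skew angle, i.e.
#' the off-diagonal shear entries), and volume change (deviation of the
#' determinant from 1).
#'
#' @name affine
NULL

#' Validate a 4x4 affine transform
#'
#' @param A 4x4 numeric matrix.
#' @return the matrix, unnamed, after validation.
#' @export
as_affine <- function(A) {
  A <- unname(as.matrix(A))
  if (!all(dim(A) == c(4L, 4L)))
    stop("affine transform must be a 4x4 matrix", call. = FALSE)
  if (max(abs(A[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("affine transform last row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(A[1:3, 1:3])) < 1e-12)
    stop("singular transform: 3x3 block has zero determinant",
         call. = FALSE)
  A[4, ] <- c(0, 0, 0, 1)
  A
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

translate_affine <- function(t) {
  A <- diag(4)
  A[1:3, 4] <- t
  A
}

shear_matrix <- function(shears) {
  H <- diag(3)
  H[1, 2] <- shears[1]  # xy
  H[1, 3] <- shears[2]  # xz
  H[2, 3] <- shears[3]  # yz
  H
}

#' Build an affine transform from parameters
#'
#' The 3x3 block is composed as `Rz %*% Ry %*% Rx %*% diag(scales) %*% H`
#' (extrinsic rotations about the fixed axes, applied x then y then z),
#' acting about `center` (world mm), followed by the translation. This is
#' the parameterization the registration optimizes and that
#' [decompose_affine()] inverts.
#'
#' @param translation_mm length-3 translation in mm.
#' @param rotation_deg length-3 rotations about x, y, z in degrees.
#' @param scales length-3 positive scale factors.
#' @param shears length-3 shear tangents (xy, xz, yz).
#' @param center world-mm point the rotation/scale/shear act about.
#' @return 4x4 affine transform.
#' @export
affine_from_params <- function(translation_mm = c(0, 0, 0),
                               rotation_deg = c(0, 0, 0),
                               scales = c(1, 1, 1),
                               shears = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  if (any(scales <= 0))
    stop("affine_from_params: scales must be positive", call. = FALSE)
  r <- rotation_deg * pi / 180
  R <- rot_z(r[3]) %*% rot_y(r[2]) %*% rot_x(r[1])
  A3 <- R %*% diag(scales, 3) %*% shear_matrix(shears)
  A <- diag(4)
  A[1:3, 1:3] <- A3
  A[1:3, 4] <- center - A3 %*% center + translation_mm
  A
}

#' Compose two affine transforms
#'
#' Returns the transform that applies `inner` first, then `outer`
#' (the matrix product `outer %*% inner`).
#'
#' @param outer,inner 4x4 affine transforms.
#' @return 4x4 affine transform.
#' @export
compose_affine <- function(outer, inner) {
  as_affine(as_affine(outer) %*% as_affine(inner))
}

#' Invert an affine transform
#' @param A 4x4 affine transform.
#' @return the inverse transform.
#' @export
invert_affine <- function(A) {
  A <- as_affine(A)
  as_affine(solve(A))
}

#' Apply an affine transform to world points
#' @param A 4x4 affine transform.
#' @param pts 3 x N matrix (or length-3 vector) of world mm points.
#' @return 3 x N matrix of mapped points.
#' @export
apply_affine <- function(A, pts) {
  A <- as_affine(A)
  pts <- as.matrix(pts)
  if (nrow(pts) != 3L) pts <- t(pts)
  (A %*% rbind(pts, 1))[1:3, , drop = FALSE]
}

#' Decompose an affine transform into distortion metrics
#'
#' Factors the 3x3 block uniquely as `R %*% S %*% H` with `R` a proper
#' rotation, `S = diag(scales)` positive, and `H` unit-upper-triangular
#' whose off-diagonal entries are the shear tangents (the tangent of the
#' skew angle). Shear values are order-dependent; this package fixes the
#' rotation-scale-shear order (applied right to left) and always reports
#' exactly the three upper-triangular tangents (xy, xz, yz). Metrics are
#' computed from the world-mm matrix, so anisotropic voxel grids cannot
#' masquerade as scaling.
#'
#' @param A 4x4 affine transform with positive 3x3 determinant.
#' @return object of class `decomposition_report`: a list with
#'   `translation_mm`, `rotation_deg` (x, y, z, same convention as
#'   [affine_from_params()]), `scales`, `shear_tangents` (xy, xz, yz),
#'   `determinant`, and the distortion metrics `max_scale_dev`
#'   (max |scale - 1|), `max_skew` (max |shear tangent|) and `volume_dev`
#'   (|determinant - 1|).
#' @export
decompose_affine <- function(A) {
  A <- as_affine(A)
  A3 <- A[1:3, 1:3]
  d <- det(A3)
  if (d <= 0)
    stop("reflection: 3x3 block has non-positive determinant (",
         signif(d, 6), "); not a proper transform", call. = FALSE)
  qrd <- qr(A3)
  Q <- qr.Q(qrd)
  Ru <- qr.R(qrd)
  sgn <- sign(diag(Ru))
  sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn, 3)
  Ru <- diag(sgn, 3) %*% Ru
  scales <- diag(Ru)
  H <- Ru / scales  # rows scaled: H[i,] = Ru[i,]/scales[i], unit diagonal
  # Euler angles of R = Rz Ry Rx
  ry <- asin(max(-1, min(1, -Q[3, 1])))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  rep_ <- list(
    translation_mm = as.numeric(A[1:3, 4]),
    rotation_deg = c(rx, ry, rz) * 180 / pi,
    scales = as.numeric(scales),
    shear_tangents = c(xy = H[1, 2], xz = H[1, 3], yz = H[2, 3]),
    determinant = d,
    max_scale_dev = max(abs(scales - 1)),
    max_skew = max(abs(c(H[1, 2], H[1, 3], H[2, 3]))),
    volume_dev = abs(d - 1)
  )
  class(rep_) <- "decomposition_report"
  rep_
}

#' Rebuild the affine transform from a decomposition report
#' @param report a `decomposition_report`.
#' @return 4x4 affine transform equal (to numerical precision) to the
#'   decomposed matrix.
#' @export
recompose_affine <- function(report) {
  r <- report$rotation_deg * pi / 180
  R <- rot_z(r[3]) %*% rot_y(r[2]) %*% rot_x(r[1])
  A3 <- R %*% diag(report$scales, 3) %*% shear_matrix(report$shear_tangents)
  A <- diag(4)
  A[1:3, 1:3] <- A3
  A[1:3, 4] <- report$translation_mm
  A
}

#' @export
print.decomposition_report <- function(x, ...) {
  cat("<decomposition_report>\n")
  cat("  translation (mm): ", paste(signif(x$translation_mm, 5),
                                    collapse = ", "), "\n")
  cat("  rotation (deg):   ", paste(signif(x$rotation_deg, 5),
                                    collapse = ", "), "\n")
  cat("  scales:           ", paste(signif(x$scales, 6),
                                    collapse = ", "), "\n")
  cat("  shear tangents:   ", paste(signif(x$shear_tangents, 6),
                                    collapse = ", "), "\n")
  cat("  determinant:      ", signif(x$determinant, 8), "\n")
  cat("  max scale dev:    ", signif(x$max_scale_dev, 6), "\n")
  cat("  max skew:         ", signif(x$max_skew, 6), "\n")
  cat("  volume dev:       ", signif(x$volume_dev, 6), "\n")
  invisible(x)
}

#' Write / read a 4x4 transform as a text matrix file
#'
#' Plain whitespace-separated 4-line matrix (FLIRT-style layout), with a
#' leading comment line documenting that entries are in the world-mm
#' convention (moving world to fixed world), not FLIRT's scaled-voxel
#' convention. Comment lines start with `#` and are skipped on read.
#'
#' @param A 4x4 affine transform.
#' @param path file path.
#' @return `read_affine` returns the 4x4 matrix; `write_affine` returns
#'   `path` invisibly.
#' @export
write_affine <- function(A, path) {
  A <- as_affine(A)
  lines <- c("# warpgauge affine transform: world-mm (moving -> fixed)",
             apply(A, 1, function(r) paste(formatC(r, format = "g",
                                                   digits = 17),
                                           collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4L)
    stop("transform file must contain exactly 4 matrix rows: ", path,
         call. = FALSE)
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l),
                                                        "\\s+")[[1]]))
  if (any(vapply(vals, length, 1L) != 4L) || anyNA(unlist(vals)))
    stop("malformed transform file: ", path, call. = FALSE)
  as_affine(do.call(rbind, vals))
}

# FLIRT-style scaled-voxel matrices: coordinates are diag(voxelsize) *
# voxel index, with the x axis flipped for grids stored with a positive
# world-affine determinant. These helpers convert between that convention
# and this package's world-mm matrices, given both image geometries.
flirt_scaler <- function(vol) {
  vs <- voxel_size(vol)
  S <- diag(c(vs, 1))
  if (det(vol$affine[1:3, 1:3]) > 0) {
    Fm <- diag(4)
    Fm[1, 1] <- -1
    Fm[1, 4] <- (dim(vol$data)[1] - 1) * vs[1]
    S <- Fm %*% S
  }
  S
}

#' Convert between world-mm and FLIRT-style scaled-voxel transforms
#'
#' @param A 4x4 transform (world-mm for `world_to_flirt`, scaled-voxel for
#'   `flirt_to_world`).
#' @param fixed,moving the `image_volume`s defining both grids.
#' @return the converted 4x4 matrix.
#' @export
world_to_flirt <- function(A, fixed, moving) {
  Sf <- flirt_scaler(fixed)
  Sm <- flirt_scaler(moving)
  Sf %*% solve(fixed$affine) %*% as_affine(A) %*% moving$affine %*% solve(Sm)
}

#' @rdname world_to_flirt
#' @export
flirt_to_world <- function(A, fixed, moving) {
  Sf <- flirt_scaler(fixed)
  Sm <- flirt_scaler(moving)
  as_affine(fixed$affine %*% solve(Sf) %*% A %*% Sm %*%
              solve(moving$affine))
}
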