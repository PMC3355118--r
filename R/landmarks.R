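#' Named anatomical landmarks in world coordinates
#'
#' A landmark set is an ordered data frame of uniquely named 3D world-mm
#' points. In the distortion-analysis workflow landmarks are placed
#' independently on both acquisitions and held out of the (landmark-free)
#' registration; mapping the test-image landmarks through the recovered
#' transform and measuring Euclidean distances to their reference
#' counterparts gives the target registration error.
#'
#' @param name character vector of unique landmark names.
#' @param positions N x 3 matrix (or data frame) of world-mm coordinates.
#' @return object of class `landmark_set` (a data frame with columns
#'   `name`, `x`, `y`, `z`).
#' @export
landmark_set <- function(name, positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("landmark_set: positions must be N x 3", call. = FALSE)
  if (length(name) != nrow(positions))
    stop("landmark_set: one name per position required", call. = FALSE)
  if (anyDuplicated(name))
    stop("landmark_set: names must be unique", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("landmark_set: positions must be finite", call. = FALSE)
  out <- data.frame(name = as.character(name),
                    x = positions[, 1], y = positions[, 2],
                    z = positions[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("landmark_set", "data.frame")
  out
}

landmark_matrix <- function(lm) t(as.matrix(lm[, c("x", "y", "z")]))

#' Apply an affine transform to a landmark set
#'
#' @param A 4x4 affine transform (moving world to fixed world).
#' @param lm a [landmark_set()].
#' @return the transformed `landmark_set`, names preserved.
#' @export
transform_points <- function(A, lm) {
  stopifnot(inherits(lm, "landmark_set"))
  mapped <- apply_affine(A, landmark_matrix(lm))
  landmark_set(lm$name, t(mapped))
}

#' Landmark distance statistics (target registration error summary)
#'
#' Pairs landmarks by name and computes 3D Euclidean distances plus a
#' boxplot summary: quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7), whiskers at the most extreme datum within
#' 1.5 * IQR of the box, values beyond flagged as outliers. Landmarks
#' present in only one set (e.g. unidentifiable due to signal loss) are
#' dropped pairwise with a warning. Distances are also expressed in
#' voxel-equivalent units against a reference voxel size, since
#' registration error is conventionally judged against the voxel.
#'
#' @param ref,test [landmark_set()]s to pair by name (`test` typically
#'   already transformed into reference space).
#' @param ref_voxel_mm optional reference voxel size (length 3) for
#'   voxel-equivalent distances.
#' @param whisker_mult IQR multiplier for the whisker fence (1.5 by
#'   convention).
#' @return object of class `distance_stats`: per-landmark distances,
#'   `mean`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers` (named distances), `dropped` (unmatched names), and, if a
#'   voxel size was given, `voxel_equivalent` (distances / voxel
#'   diagonal) and `per_axis_voxel` (per-axis |error| / per-axis voxel
#'   size).
#' @export
landmark_distances <- function(ref, test, ref_voxel_mm = NULL,
                               whisker_mult = 1.5) {
  stopifnot(inherits(ref, "landmark_set"), inherits(test, "landmark_set"))
  common <- intersect(ref$name, test$name)
  if (length(common) == 0L)
    stop("landmark_distances: no landmark names in common", call. = FALSE)
  dropped <- setdiff(union(ref$name, test$name), common)
  if (length(dropped))
    warning("landmark_distances: dropping unmatched landmarks: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  r <- as.matrix(ref[match(common, ref$name), c("x", "y", "z")])
  t_ <- as.matrix(test[match(common, test$name), c("x", "y", "z")])
  delta <- t_ - r
  d <- sqrt(rowSums(delta^2))
  names(d) <- common
  q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - whisker_mult * iqr
  hi_fence <- q[3] + whisker_mult * iqr
  inl <- d >= lo_fence & d <= hi_fence
  out <- list(
    distances = d,
    mean = mean(d),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = if (any(inl)) min(d[inl]) else NA_real_,
    whisker_high = if (any(inl)) max(d[inl]) else NA_real_,
    outliers = d[!inl],
    dropped = dropped
  )
  if (!is.null(ref_voxel_mm)) {
    ref_voxel_mm <- rep_len(as.numeric(ref_voxel_mm), 3L)
    out$voxel_equivalent <- d / sqrt(sum(ref_voxel_mm^2))
    pa <- sweep(abs(delta), 2, ref_voxel_mm, "/")
    colnames(pa) <- c("x", "y", "z")
    rownames(pa) <- common
    out$per_axis_voxel <- pa
  }
  class(out) <- "distance_stats"
  out
}

#' @export
print.distance_stats <- function(x, ...) {
  cat("<distance_stats> n =", length(x$distances), "\n")
  cat("  mean ", signif(x$mean, 4), " mm, median ", signif(x$median, 4),
      " mm, Q1 ", signif(x$q1, 4), ", Q3 ", signif(x$q3, 4), "\n", sep = "")
  if (length(x$outliers))
    cat("  outliers:", paste(names(x$outliers), signif(x$outliers, 4),
                             collapse = "; "), "\n")
  invisible(x)
}

#' Read / write landmark sets as TSV
#'
#' Format: one landmark per line, `name<TAB>x<TAB>y<TAB>z` in world mm,
#' with a `#`-prefixed header line.
#'
#' @param lm a [landmark_set()].
#' @param path file path.
#' @return `read_landmarks` returns a `landmark_set`; `write_landmarks`
#'   returns `path` invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  lines <- c("# name\tx\ty\tz (world mm)",
             sprintf("%s\t%.10g\t%.10g\t%.10g", lm$name, lm$x, lm$y, lm$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 4L))
    stop("malformed landmark TSV: ", path, call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  landmark_set(nm, pos)
}
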