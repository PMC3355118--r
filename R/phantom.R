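#' Digital head phantom with known ground-truth distortion
#'
#' The phantom stands in for the paired patient scans: a smooth
#' "reference" volume emulating a 1 mm-isotropic T1-like whole-head
#' acquisition (at reduced grid scale), and a "test" volume derived from
#' it through a known affine transform, an optional localized nonlinear
#' warp with signal dropout near a simulated air cavity, a multiplicative
#' polynomial bias field, and Rician noise. Because every degradation is
#' parameterized and recorded, each stage of the distortion-analysis
#' pipeline can be validated by parameter recovery.
#'
#' @name phantom
NULL

# evaluate expr with a temporary RNG state seeded by `seed`;
# seed = NULL uses (and advances) the current RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Phantom geometry specification
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 8).
#' @param voxel_size_mm positive length-3 (or scalar) voxel spacing.
#' @param ellipsoids list of ellipsoids, each a list with `center` (world
#'   mm), `semiaxes` (mm, > 0), `rotation_deg` (length-3 Euler angles),
#'   `intensity` (additive, may be negative for hypointense structures as
#'   long as the summed image stays >= 0) and optional `name`. The first
#'   ellipsoid is the brain-analog envelope.
#' @param cavity_center_mm world-mm location of the simulated air cavity
#'   (site of susceptibility warp / dropout in the test image).
#' @param texture_amplitude relative amplitude of the smooth deterministic
#'   intensity texture multiplying the rasterized structures. Real tissue
#'   is not piecewise-constant: without low-frequency contrast variation,
#'   intensity-based costs on synthetic images develop lattice artifacts
#'   and lose local gradient information. Set to 0 for analytically flat
#'   structures.
#' @param seed integer RNG seed recorded with the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, ellipsoids,
                         cavity_center_mm = c(0, 0, 0),
                         texture_amplitude = 0, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(grid_shape < 8L))
    stop("invalid phantom spec: every grid axis needs >= 8 voxels",
         call. = FALSE)
  if (any(voxel_size_mm <= 0))
    stop("invalid phantom spec: spacings must be > 0", call. = FALSE)
  if (length(ellipsoids) < 1L)
    stop("invalid phantom spec: need at least one ellipsoid", call. = FALSE)
  for (e in ellipsoids) {
    if (any(e$semiaxes <= 0))
      stop("invalid phantom spec: semi-axes must be > 0", call. = FALSE)
  }
  if (texture_amplitude < 0 || texture_amplitude >= 1)
    stop("invalid phantom spec: texture_amplitude must be in [0, 1)",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 ellipsoids = ellipsoids,
                 cavity_center_mm = as.numeric(cavity_center_mm),
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default head phantom specification
#'
#' A brain-analog envelope with nine asymmetrically placed internal
#' structures (ventricle analogues, thalamic/midbrain blocks, cortical
#' markers), on a grid spanning a 160 mm field of view. The default
#' 64-voxel grid keeps simulated registrations fast; increase `n` for a
#' finer raster of the same world-space geometry.
#'
#' @param n voxels per axis (isotropic grid).
#' @param texture_amplitude smooth tissue-texture amplitude (see
#'   [phantom_spec()]); the default 0.15 gives mild within-structure
#'   contrast variation comparable to real T1 tissue heterogeneity.
#' @param seed recorded RNG seed.
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(n = 64L, texture_amplitude = 0.15,
                                 seed = 1L) {
  ell <- list(
    list(name = "brain",      center = c(0, 0, 0),      semiaxes = c(60, 70, 55), rotation_deg = c(0, 0, 0),   intensity = 100),
    list(name = "vent_l",     center = c(-12, 8, 8),    semiaxes = c(8, 20, 10),  rotation_deg = c(0, 0, 15),  intensity = -60),
    list(name = "vent_r",     center = c(12, 8, 8),     semiaxes = c(8, 20, 10),  rotation_deg = c(0, 0, -15), intensity = -60),
    list(name = "thalamus",   center = c(0, -8, 0),     semiaxes = c(18, 14, 10), rotation_deg = c(0, 0, 0),   intensity = 40),
    list(name = "midbrain",   center = c(0, -18, -18),  semiaxes = c(12, 12, 14), rotation_deg = c(0, 0, 0),   intensity = 60),
    list(name = "frontal",    center = c(0, 45, 10),    semiaxes = c(14, 10, 10), rotation_deg = c(0, 0, 0),   intensity = 50),
    list(name = "occipital",  center = c(0, -48, 5),    semiaxes = c(11, 9, 9),   rotation_deg = c(0, 0, 0),   intensity = -30),
    list(name = "temporal_l", center = c(-35, 0, -15),  semiaxes = c(10, 16, 10), rotation_deg = c(0, 0, 20),  intensity = 45),
    list(name = "cerebellum", center = c(0, -32, -30),  semiaxes = c(20, 15, 12), rotation_deg = c(0, 0, 0),   intensity = 30),
    list(name = "marker",     center = c(25, 25, 20),   semiaxes = c(7, 7, 7),    rotation_deg = c(0, 0, 0),   intensity = 70),
    # cortical-analog blobs: real cortex has structure everywhere, and a
    # registration phantom with large uniform areas would be both
    # unrealistic and locally under-determined
    list(name = "post_sup",   center = c(0, -45, 35),   semiaxes = c(10, 9, 8),   rotation_deg = c(0, 0, 0),   intensity = 45),
    list(name = "sup_l",      center = c(-20, 15, 38),  semiaxes = c(8, 8, 7),    rotation_deg = c(0, 10, 0),  intensity = 55),
    list(name = "sup_r",      center = c(20, 15, 38),   semiaxes = c(8, 8, 7),    rotation_deg = c(0, -10, 0), intensity = -35),
    list(name = "ant_mid",    center = c(25, 40, 0),    semiaxes = c(8, 8, 8),    rotation_deg = c(0, 0, 0),   intensity = 50),
    list(name = "ant_inf",    center = c(15, 42, -30),  semiaxes = c(8, 7, 7),    rotation_deg = c(0, 0, 0),   intensity = 40)
  )
  phantom_spec(grid_shape = rep(as.integer(n), 3L),
               voxel_size_mm = rep(160 / n, 3L),
               ellipsoids = ell,
               cavity_center_mm = c(0, 38, -42),
               texture_amplitude = texture_amplitude,
               seed = seed)
}

# world coordinates (3 x Nvox) of every voxel centre of a grid
grid_world_coords <- function(shape, affine) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ii <- rep.int(0:(nx - 1), ny * nz)
  jj <- rep.int(rep(0:(ny - 1), each = nx), nz)
  kk <- rep(0:(nz - 1), each = nx * ny)
  affine[1:3, 1:3] %*% rbind(ii, jj, kk) + affine[1:3, 4]
}

# ellipsoid membership of world points (3 x N): quadratic form <= 1
ellipsoid_inside <- function(e, pts) {
  r <- (e$rotation_deg %||% c(0, 0, 0)) * pi / 180
  R <- rot_z(r[3]) %*% rot_y(r[2]) %*% rot_x(r[1])
  local <- t(R) %*% (pts - e$center)
  q <- colSums((local / e$semiaxes)^2)
  q <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the analytic phantom intensity field at world points
#'
#' The summed ellipsoid intensities (clamped at 0) times the smooth
#' texture factor, evaluated exactly: sampling this field on a grid and
#' sampling it at mapped points are both interpolation-free, so
#' reference and distorted volumes share identical sharpness.
#'
#' @param spec a [phantom_spec()].
#' @param pts 3 x N matrix of world mm points.
#' @return numeric intensity vector of length N.
#' @export
rasterize_field <- function(spec, pts) {
  v <- numeric(ncol(pts))
  for (e in spec$ellipsoids)
    v <- v + e$intensity * ellipsoid_inside(e, pts)
  v[v < 0] <- 0
  ta <- spec$texture_amplitude %||% 0
  if (ta > 0) {
    # fixed-phase low-frequency cosines (wavelengths 40-80 mm): smooth
    # world-space tissue-contrast variation, identical for any grid
    # rasterizing the same geometry
    g <- cos(2 * pi * pts[1, ] / 67 + 0.7) *
      cos(2 * pi * pts[2, ] / 53 - 0.4) +
      cos(2 * pi * (pts[1, ] + pts[3, ]) / 79 + 1.3) +
      cos(2 * pi * (pts[2, ] - pts[3, ]) / 43 - 2.1)
    v <- v * (1 + ta * g / 3)
  }
  v
}

#' Generate the reference phantom volume and its analytic landmarks
#'
#' Rasterizes the summed ellipsoid intensities on the specified grid
#' (hard analytic membership per voxel centre) and returns the analytic
#' landmark set: the centres of all internal ellipsoids, padded with
#' interior pole points of the envelope if fewer than seven structures
#' are defined. All landmarks lie strictly inside the brain-analog.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an `image_volume`) and `landmarks`
#'   (a [landmark_set()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  aff <- diag(c(spec$voxel_size_mm, 1))
  aff[1:3, 4] <- -spec$voxel_size_mm * (shape - 1) / 2
  pts <- grid_world_coords(shape, aff)
  vol <- image_volume(array(rasterize_field(spec, pts), shape), aff)

  internal <- spec$ellipsoids[-1]
  nm <- vapply(seq_along(internal),
               function(i) internal[[i]]$name %||% paste0("lm", i), "")
  pos <- if (length(internal))
    t(vapply(internal, function(e) as.numeric(e$center), numeric(3)))
  else matrix(numeric(0), 0, 3)
  if (length(internal) < 7L) {
    env <- spec$ellipsoids[[1]]
    poles <- rbind(c(0, 0, 0), diag(env$semiaxes * 0.6),
                   -diag(env$semiaxes * 0.6))
    poles <- sweep(poles, 2, as.numeric(env$center), "+")
    need <- min(7L - length(internal), nrow(poles))
    pos <- rbind(pos, poles[seq_len(max(need, 0)), , drop = FALSE])
    nm <- c(nm, paste0("pole", seq_len(max(need, 0))))
  }
  lm <- landmark_set(nm, pos)
  list(volume = vol, landmarks = lm)
}

#' Distortion specification for the simulated test acquisition
#'
#' Models the two distortion sources of high-field imaging: system-level
#' affine distortion (gradient nonlinearity approximated to first order
#' as scaling and shear plus a rigid repositioning) and a
#' subject-dependent susceptibility effect near an air cavity (localized
#' Gaussian-bump displacement with co-located signal dropout), plus a
#' smooth multiplicative bias field and Rician noise.
#'
#' @param translation_mm,rotation_deg,scales,shears the 12 affine
#'   parameters (see [affine_from_params()]); scales must lie in
#'   (0.5, 2), |shears| < 0.5.
#' @param warp_amplitude_mm peak local displacement of the susceptibility
#'   warp (0 disables it).
#' @param warp_sigma_mm Gaussian radius (> 0) of the warp, also used as
#'   the radius of the dropout sphere.
#' @param warp_direction unit-normalized direction of the displacement.
#' @param dropout_strength fractional signal loss at the cavity centre,
#'   in \[0, 1\].
#' @param dropout_order super-Gaussian order of the dropout profile,
#'   `1 - strength * exp(-(r^2 / 2 sigma^2)^order)`. Order 1 is a plain
#'   Gaussian shoulder; higher orders give the flat-core, sharp-edged
#'   signal void seen around real air cavities.
#' @param bias_order polynomial order of the log bias field (0 disables).
#' @param bias_amplitude maximum magnitude of the log field.
#' @param noise_sigma Rician sigma in intensity units (0 disables).
#' @return object of class `distortion_spec`.
#' @export
distortion_spec <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            scales = c(1, 1, 1),
                            shears = c(0, 0, 0),
                            warp_amplitude_mm = 0,
                            warp_sigma_mm = 15,
                            warp_direction = c(0, 0, 1),
                            dropout_strength = 0,
                            dropout_order = 1L,
                            bias_order = 0L,
                            bias_amplitude = 0,
                            noise_sigma = 0) {
  if (any(scales <= 0.5 | scales >= 2))
    stop("invalid distortion spec: scales must lie in (0.5, 2)",
         call. = FALSE)
  if (any(abs(shears) >= 0.5))
    stop("invalid distortion spec: |shear| must be < 0.5", call. = FALSE)
  if (warp_sigma_mm <= 0)
    stop("invalid distortion spec: warp_sigma_mm must be > 0", call. = FALSE)
  if (dropout_strength < 0 || dropout_strength > 1)
    stop("invalid distortion spec: dropout_strength must be in [0, 1]",
         call. = FALSE)
  if (dropout_order < 1)
    stop("invalid distortion spec: dropout_order must be >= 1",
         call. = FALSE)
  wd <- as.numeric(warp_direction)
  if (sum(wd^2) == 0) wd <- c(0, 0, 1)
  wd <- wd / sqrt(sum(wd^2))
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 scales = as.numeric(scales),
                 shears = as.numeric(shears),
                 warp_amplitude_mm = warp_amplitude_mm,
                 warp_sigma_mm = warp_sigma_mm,
                 warp_direction = wd,
                 dropout_strength = dropout_strength,
                 dropout_order = as.integer(dropout_order),
                 bias_order = as.integer(bias_order),
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma),
            class = "distortion_spec")
}

#' Distortion presets emulating the two 7 T system variants
#'
#' Two illustrative presets: `"PS"` (passively shielded analogue, smaller
#' scale/shear corrections) and `"AS"` (actively shielded analogue with
#' higher-performing but less uniform gradients: ~1% scales and shears
#' near 0.01). Values are representative magnitudes, not measurements.
#'
#' @param name `"PS"` or `"AS"`.
#' @param noise_sigma Rician sigma; the default (5 against a brain-analog
#'   base intensity of 100) corresponds to SNR ~ 20.
#' @return a [distortion_spec()].
#' @export
distortion_preset <- function(name = c("PS", "AS"), noise_sigma = 5) {
  name <- match.arg(name)
  rigid <- list(translation_mm = c(2, -1.5, 1),
                rotation_deg = c(1.5, -1, 2))
  if (name == "PS") {
    distortion_spec(translation_mm = rigid$translation_mm,
                    rotation_deg = rigid$rotation_deg,
                    scales = c(1.003, 0.998, 1.004),
                    shears = c(0.003, 0.002, -0.004),
                    bias_order = 2L, bias_amplitude = 0.1,
                    noise_sigma = noise_sigma)
  } else {
    distortion_spec(translation_mm = rigid$translation_mm,
                    rotation_deg = rigid$rotation_deg,
                    scales = c(1.010, 0.994, 1.012),
                    shears = c(0.008, -0.006, 0.010),
                    bias_order = 2L, bias_amplitude = 0.1,
                    noise_sigma = noise_sigma)
  }
}

# Gaussian-bump displacement (3 x N) at world points
warp_displacement <- function(dspec, pts, center) {
  if (dspec$warp_amplitude_mm == 0)
    return(matrix(0, 3, ncol(pts)))
  r2 <- colSums((pts - center)^2)
  g <- dspec$warp_amplitude_mm * exp(-r2 / (2 * dspec$warp_sigma_mm^2))
  dspec$warp_direction %o% g
}

# ground-truth mapping m: test world -> reference world
truth_map <- function(A, dspec, cavity) {
  force(A); force(dspec); force(cavity)
  function(pts) {
    pts <- as.matrix(pts)
    if (nrow(pts) != 3L) pts <- t(pts)
    apply_affine(A, pts + warp_displacement(dspec, pts, cavity))
  }
}

# invert the truth map at reference points q by fixed-point iteration:
# y = A^{-1} q - d(y); contraction because |grad d| < 1.
truth_map_inverse <- function(A, dspec, cavity, q, tol = 1e-12,
                              maxit = 300L) {
  q <- as.matrix(q)
  if (nrow(q) != 3L) q <- t(q)
  base <- apply_affine(invert_affine(A), q)
  y <- base
  for (it in seq_len(maxit)) {
    ynew <- base - warp_displacement(dspec, y, cavity)
    if (max(abs(ynew - y)) < tol) return(ynew)
    y <- ynew
  }
  y
}

#' Apply a known distortion to a phantom, producing the test acquisition
#'
#' Builds the simulated "7 T" test volume from the reference phantom: the
#' output grid is sampled through the ground-truth mapping
#' `m(y) = A(y + d(y))` (affine `A` composed with the localized
#' susceptibility displacement `d`, acting in test space), so that a
#' moving-to-fixed registration of the result against the reference must
#' recover exactly `A`. The resampled image is then multiplied by a
#' polynomial bias field, attenuated by a Gaussian dropout sphere at the
#' cavity, and Rician-corrupted. Test-space landmarks are obtained by
#' inverting `m` at the reference landmarks to machine precision, so
#' landmark pairs satisfy the recorded mapping exactly (before any
#' jitter).
#'
#' @param vol reference `image_volume`.
#' @param landmarks reference [landmark_set()] (analytic points).
#' @param dspec a [distortion_spec()].
#' @param cavity_center_mm world-mm cavity location (warp + dropout
#'   centre); defaults to the origin-adjacent default of
#'   [default_phantom_spec()].
#' @param out_grid optional output grid: an `image_volume` to copy the
#'   grid from, or a list with `shape` and `affine`. Default: same grid
#'   as `vol`.
#' @param seed integer seed for bias-field coefficients and noise.
#' @param rotation_center world-mm centre the affine parameters act
#'   about (default origin, the centre of the default phantom grid).
#' @param spec optional [phantom_spec()]: when given, the distorted
#'   image is rasterized analytically from the spec's intensity field at
#'   the mapped points instead of interpolating `vol`, so the test
#'   volume carries no resampling blur relative to the reference (an
#'   asymmetry real scanner pairs do not have).
#' @return list with `volume` (the degraded test `image_volume`) and
#'   `truth` (a `phantom_truth`: the applied affine, warp description,
#'   paired landmark sets and degradation parameters).
#' @export
apply_ground_truth_distortion <- function(vol, landmarks, dspec,
                                          cavity_center_mm = c(0, 38, -42),
                                          out_grid = NULL, seed = 1L,
                                          rotation_center = c(0, 0, 0),
                                          spec = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(dspec, "distortion_spec"))
  if (is.null(out_grid)) {
    oshape <- dim(vol$data); oaff <- vol$affine
  } else if (inherits(out_grid, "image_volume")) {
    oshape <- dim(out_grid$data); oaff <- out_grid$affine
  } else {
    oshape <- as.integer(out_grid$shape); oaff <- as.matrix(out_grid$affine)
  }
  if (any(sqrt(colSums(oaff[1:3, 1:3]^2)) <= 0))
    stop("invalid output grid: spacings must be > 0", call. = FALSE)
  # non-invertibility guard: peak displacement gradient of the Gaussian
  # bump is amplitude * exp(-1/2) / sigma
  grad_max <- abs(dspec$warp_amplitude_mm) * exp(-0.5) / dspec$warp_sigma_mm
  if (grad_max >= 1)
    stop("invalid distortion spec: warp is non-invertible ",
         "(max displacement gradient ", signif(grad_max, 3), " >= 1)",
         call. = FALSE)

  A <- affine_from_params(dspec$translation_mm, dspec$rotation_deg,
                          dspec$scales, dspec$shears,
                          center = rotation_center)
  m <- truth_map(A, dspec, cavity_center_mm)

  opts <- grid_world_coords(oshape, oaff)           # test-space world
  refw <- m(opts)                                   # mapped into ref space
  if (is.null(spec)) {
    refv <- world2vox(vol, refw)
    v <- cpp_interp_points(as.numeric(vol$data), dim(vol$data), refv)
    v[is.na(v)] <- 0
  } else {
    v <- rasterize_field(spec, refw)
  }

  with_seed(seed, {
    if (dspec$bias_order > 0L && dspec$bias_amplitude > 0) {
      # random polynomial in grid-normalized coords, scaled to amplitude
      ext <- apply(opts, 1, range)
      u <- (opts - colMeans(ext)) / pmax(ext[2, ] - ext[1, ], 1e-9) * 2
      pows <- expand.grid(px = 0:dspec$bias_order, py = 0:dspec$bias_order,
                          pz = 0:dspec$bias_order)
      pows <- pows[rowSums(pows) >= 1 &
                     rowSums(pows) <= dspec$bias_order, , drop = FALSE]
      cf <- rnorm(nrow(pows))
      fld <- numeric(ncol(opts))
      for (t in seq_len(nrow(pows)))
        fld <- fld + cf[t] * u[1, ]^pows$px[t] * u[2, ]^pows$py[t] *
          u[3, ]^pows$pz[t]
      fld <- fld / max(abs(fld)) * dspec$bias_amplitude
      v <- v * exp(fld)
    }
    if (dspec$dropout_strength > 0) {
      r2 <- colSums((opts - cavity_center_mm)^2)
      u <- r2 / (2 * dspec$warp_sigma_mm^2)
      v <- v * (1 - dspec$dropout_strength *
                  exp(-u^(dspec$dropout_order %||% 1L)))
    }
    if (dspec$noise_sigma > 0) {
      n <- length(v)
      v <- sqrt((v + rnorm(n, 0, dspec$noise_sigma))^2 +
                  rnorm(n, 0, dspec$noise_sigma)^2)
    }
  })

  out <- image_volume(array(v, oshape), oaff)
  lm_test <- landmarks
  lm_test[, c("x", "y", "z")] <-
    t(truth_map_inverse(A, dspec, cavity_center_mm,
                        t(as.matrix(landmarks[, c("x", "y", "z")]))))
  truth <- structure(list(
    true_affine = A,
    warp = list(amplitude_mm = dspec$warp_amplitude_mm,
                sigma_mm = dspec$warp_sigma_mm,
                direction = dspec$warp_direction,
                center_mm = as.numeric(cavity_center_mm)),
    landmarks_ref = landmarks,
    landmarks_test = lm_test,
    degradation = dspec,
    rotation_center = as.numeric(rotation_center),
    seed = as.integer(seed)), class = "phantom_truth")
  list(volume = out, truth = truth)
}

#' Extract an anisotropic axial slab from a volume
#'
#' Emulates a thin 2D-acquired slab (e.g. an axial T2 slab through the
#' midbrain): the output grid covers only `slab_thickness_mm` around
#' `slab_center_mm` along the slice axis, at `slice_mm` slice spacing and
#' `inplane_mm` in-plane spacing (requiring `slice_mm >= inplane_mm`),
#' resampled from the parent so that slab voxels map to the same world
#' locations.
#'
#' @param vol parent `image_volume` (assumed axis-aligned RAS grid).
#' @param slab_center_mm world-mm centre of the slab.
#' @param slab_thickness_mm slab extent along z.
#' @param inplane_mm in-plane voxel size.
#' @param slice_mm slice thickness (z spacing).
#' @return an `image_volume` with `slab_thickness_mm / slice_mm` slices.
#' @export
make_slab <- function(vol, slab_center_mm = c(0, 0, 0),
                      slab_thickness_mm = 40, inplane_mm = 1,
                      slice_mm = 2) {
  stopifnot(inherits(vol, "image_volume"))
  if (slice_mm < inplane_mm)
    stop("make_slab: slice_mm must be >= inplane_mm (anisotropic slab)",
         call. = FALSE)
  shape <- dim(vol$data)
  lo <- vox2world(vol, c(0, 0, 0))
  hi <- vox2world(vol, shape - 1)
  zmin <- slab_center_mm[3] - slab_thickness_mm / 2
  zmax <- slab_center_mm[3] + slab_thickness_mm / 2
  if (zmin < min(lo[3], hi[3]) - 1e-9 || zmax > max(lo[3], hi[3]) + 1e-9)
    stop("make_slab: slab extends outside the parent volume", call. = FALSE)
  nsl <- max(1L, as.integer(round(slab_thickness_mm / slice_mm)))
  nx <- as.integer(floor((hi[1] - lo[1]) / inplane_mm)) + 1L
  ny <- as.integer(floor((hi[2] - lo[2]) / inplane_mm)) + 1L
  oaff <- diag(c(inplane_mm, inplane_mm, slice_mm, 1))
  oaff[1:3, 4] <- c(lo[1], lo[2], zmin + slice_mm / 2)
  # identity world mapping: output voxel -> world -> parent voxel
  M <- solve(vol$affine) %*% oaff
  d <- cpp_resample(as.numeric(vol$data), shape,
                    c(nx, ny, nsl), M, 0)
  image_volume(array(d, c(nx, ny, nsl)), oaff)
}

#' Jitter landmark positions with isotropic Gaussian error
#'
#' Emulates manual landmark-marking error (the repeat-marking experiments
#' of the landmark method put it near 0.5 mm): each landmark is displaced
#' by an independent isotropic Gaussian with the given sigma per axis.
#'
#' @param lm a [landmark_set()].
#' @param sigma_mm marking-error sigma (>= 0) in mm.
#' @param seed integer RNG seed.
#' @return a jittered `landmark_set` with names preserved.
#' @export
jitter_landmarks <- function(lm, sigma_mm, seed = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  if (sigma_mm < 0)
    stop("jitter_landmarks: sigma_mm must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(lm)
  n <- nrow(lm)
  with_seed(seed, {
    lm[, c("x", "y", "z")] <- as.matrix(lm[, c("x", "y", "z")]) +
      matrix(rnorm(3 * n, 0, sigma_mm), n, 3)
  })
  lm
}
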