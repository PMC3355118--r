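test_that("rasterization matches a brute-force per-voxel membership oracle", {
  spec <- phantom_spec(
    grid_shape = c(16, 16, 16), voxel_size_mm = c(4, 4, 4),
    ellipsoids = list(
      list(name = "env", center = c(0, 0, 0), semiaxes = c(24, 20, 26),
           rotation_deg = c(0, 0, 0), intensity = 10),
      list(name = "blob", center = c(6, -4, 2), semiaxes = c(8, 10, 6),
           rotation_deg = c(10, -5, 25), intensity = 5)))
  got <- generate_phantom(spec)$volume

  # independent oracle: triple loop, explicit rotation matrices
  rotm <- function(deg) {
    r <- deg * pi / 180
    Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0,
                   0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0,
                   sin(r[2]), 0, cos(r[2])), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]),
                   0, -sin(r[1]), cos(r[1])), 3, 3)
    Rz %*% Ry %*% Rx
  }
  want <- array(0, c(16, 16, 16))
  for (i in 0:15) for (j in 0:15) for (k in 0:15) {
    w <- got$affine[1:3, 1:3] %*% c(i, j, k) + got$affine[1:3, 4]
    v <- 0
    for (e in spec$ellipsoids) {
      l <- t(rotm(e$rotation_deg)) %*% (w - e$center)
      if (sum((l / e$semiaxes)^2) <= 1) v <- v + e$intensity
    }
    want[i + 1, j + 1, k + 1] <- v
  }
  expect_identical(got$data, want)
  expect_identical(sum(got$data > 0), sum(want > 0))
})

test_that("phantom generation is deterministic and satisfies spec examples", {
  spec <- phantom_spec(
    grid_shape = c(17, 17, 17), voxel_size_mm = c(2, 2, 2),
    ellipsoids = list(list(center = c(0, 0, 0), semiaxes = c(10, 10, 10),
                           rotation_deg = c(0, 0, 0), intensity = 1)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  # single centred unit ellipsoid: centre voxel 1, corner voxel 0
  expect_equal(a$volume$data[9, 9, 9], 1)
  expect_equal(a$volume$data[1, 1, 1], 0)
  # >= 7 landmarks, all strictly inside the envelope
  expect_gte(nrow(a$landmarks), 7)
  q <- rowSums((as.matrix(a$landmarks[, c("x", "y", "z")]) / 10)^2)
  expect_true(all(q < 1))
  expect_error(phantom_spec(c(4, 16, 16), 1, spec$ellipsoids),
               "invalid")
})

test_that("default phantom landmarks lie strictly inside the brain-analog", {
  ph <- fix_phantom(24)
  env <- default_phantom_spec(24)$ellipsoids[[1]]
  q <- rowSums(sweep(as.matrix(ph$landmarks[, c("x", "y", "z")]), 2,
                     env$center, "-")^2 / rep(env$semiaxes^2,
                                              each = nrow(ph$landmarks)))
  expect_true(all(q < 1))
  expect_gte(nrow(ph$landmarks), 7)
})

test_that("identity distortion returns the input volume", {
  ph <- fix_phantom(24)
  out <- apply_ground_truth_distortion(ph$volume, ph$landmarks,
                                       distortion_spec(), seed = 1)
  expect_equal(out$volume$data, ph$volume$data, tolerance = 1e-12)
  expect_equal(out$truth$landmarks_test, ph$landmarks)
})

test_that("pure translation shifts the centre of mass by the stated amount", {
  ph <- fix_phantom(32)
  smooth <- smooth_volume(ph$volume, 5)
  tr <- c(3, -2, 1.5)
  out <- apply_ground_truth_distortion(smooth, ph$landmarks,
                                       distortion_spec(translation_mm = tr),
                                       seed = 1)
  com <- function(vol) {
    s <- warpgauge:::cost_samples(vol)
    as.numeric(s$pts %*% s$fvals / sum(s$fvals))
  }
  shift <- com(smooth) - com(out$volume)
  expect_lt(max(abs(shift - tr)), 0.1)
})

test_that("full-strength dropout suppresses signal at the cavity", {
  ph <- fix_phantom(32)
  cav <- c(0, 0, 0)  # deep inside the brain-analog so base signal is high
  clean <- apply_ground_truth_distortion(ph$volume, ph$landmarks,
                                         distortion_spec(), seed = 1)
  dropped <- apply_ground_truth_distortion(
    ph$volume, ph$landmarks,
    distortion_spec(dropout_strength = 1, warp_sigma_mm = 15),
    cavity_center_mm = cav, seed = 1)
  v0 <- sample_at(clean$volume, cav)
  v1 <- sample_at(dropped$volume, cav)
  expect_gt(v0, 0)
  expect_lt(v1, 0.05 * v0)
})

test_that("ground-truth landmark pairs satisfy the recorded mapping", {
  ph <- fix_phantom(16)
  ds <- distortion_spec(translation_mm = c(2, -1, 3),
                        rotation_deg = c(2, 1, -3),
                        scales = c(1.01, 0.99, 1.005),
                        shears = c(0.01, -0.005, 0.008),
                        warp_amplitude_mm = 2, warp_sigma_mm = 12)
  out <- apply_ground_truth_distortion(ph$volume, ph$landmarks, ds,
                                       cavity_center_mm = c(0, 20, -10),
                                       seed = 2)
  m <- warpgauge:::truth_map(out$truth$true_affine, ds, c(0, 20, -10))
  mapped <- m(t(as.matrix(out$truth$landmarks_test[, c("x", "y", "z")])))
  err <- max(abs(mapped -
                   t(as.matrix(out$truth$landmarks_ref[, c("x", "y", "z")]))))
  expect_lt(err, 1e-9)
})

test_that("distortion output is seed-reproducible and seed-sensitive", {
  ph <- fix_phantom(16)
  ds <- distortion_spec(noise_sigma = 5, bias_order = 2L,
                        bias_amplitude = 0.1)
  a <- apply_ground_truth_distortion(ph$volume, ph$landmarks, ds, seed = 4)
  b <- apply_ground_truth_distortion(ph$volume, ph$landmarks, ds, seed = 4)
  c_ <- apply_ground_truth_distortion(ph$volume, ph$landmarks, ds, seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("background Rician noise is Rayleigh with the stated sigma", {
  sigma <- 4
  zero <- image_volume_from_spacing(array(0, c(47, 47, 47)), c(1, 1, 1))
  lm <- landmark_set("c", rbind(c(0, 0, 0)))
  out <- apply_ground_truth_distortion(zero, lm,
                                       distortion_spec(noise_sigma = sigma),
                                       seed = 11)
  x <- as.numeric(out$volume$data)
  expect_gt(length(x), 1e5)
  ks <- stats::ks.test(x, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
  # Rayleigh mode equals sigma: check via the distribution mean
  expect_equal(mean(x), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("warp displacement is negligible beyond four sigma", {
  ds <- distortion_spec(warp_amplitude_mm = 3, warp_sigma_mm = 10)
  far <- rbind(c(41, 0, 0), c(0, -45, 0), c(30, 30, 30))
  d <- warpgauge:::warp_displacement(ds, t(far), c(0, 0, 0))
  expect_lt(max(sqrt(colSums(d^2))), 0.02 * 3)
  # non-invertible warp rejected
  expect_error(
    apply_ground_truth_distortion(
      fix_phantom(16)$volume, landmark_set("a", rbind(c(0, 0, 0))),
      distortion_spec(warp_amplitude_mm = 30, warp_sigma_mm = 10)),
    "non-invertible")
})

test_that("anisotropic slab has the stated slices and aligned geometry", {
  ph <- fix_phantom(32)
  slab <- make_slab(ph$volume, slab_center_mm = c(0, 0, 0),
                    slab_thickness_mm = 40, inplane_mm = 2, slice_mm = 2)
  expect_equal(dim(slab$data)[3], 20L)
  expect_equal(voxel_size(slab), c(2, 2, 2))
  aniso <- make_slab(ph$volume, c(0, 0, 0), 40, inplane_mm = 1,
                     slice_mm = 2)
  expect_equal(voxel_size(aniso), c(1, 1, 2))
  expect_equal(dim(aniso$data)[3], 20L)
  # voxel (i, j, 0) world coordinates follow the documented layout:
  # parent in-plane origin + i * inplane, first slice centred at
  # slab_bottom + slice/2
  p0 <- vox2world(ph$volume, c(0, 0, 0))
  expect_equal(as.numeric(vox2world(aniso, c(3, 5, 0))),
               c(p0[1] + 3, p0[2] + 5, -20 + 1))
  expect_error(make_slab(ph$volume, c(0, 0, 60), 40, 1, 2),
               "outside")
  expect_error(make_slab(ph$volume, c(0, 0, 0), 40, 2, 1), "slice_mm")
})

test_that("slab intensities match a direct crop of the parent", {
  ph <- fix_phantom(32)
  vs <- voxel_size(ph$volume)  # 5 mm isotropic at n = 32
  slab <- make_slab(ph$volume, slab_center_mm = c(0, 0, 0),
                    slab_thickness_mm = 8 * vs[3], inplane_mm = vs[1],
                    slice_mm = vs[3])
  # grid-aligned slab: voxels coincide with a parent sub-block
  k0 <- 12  # parent z index of the first slab slice (0-based)
  sub <- ph$volume$data[, , (k0 + 1):(k0 + 8)]
  expect_equal(dim(slab$data), dim(sub))
  expect_equal(mean(slab$data), mean(sub), tolerance = 1e-6)
})

test_that("landmark jitter is exact at sigma zero and matches its Monte Carlo scale", {
  lm <- landmark_set(paste0("l", 1:1000), matrix(rnorm(3000, sd = 40),
                                                 1000, 3))
  expect_identical(jitter_landmarks(lm, 0, seed = 1), lm)
  j1 <- jitter_landmarks(lm, 0.5, seed = 1)
  j2 <- jitter_landmarks(lm, 0.5, seed = 2)
  expect_identical(jitter_landmarks(lm, 0.5, seed = 1), j1)
  expect_false(identical(j1, j2))
  expect_identical(j1$name, lm$name)
  # Monte-Carlo oracle for the mean displacement length of an isotropic
  # 3D Gaussian with sigma 0.5
  set.seed(99)
  oracle <- mean(sqrt(rowSums(matrix(rnorm(3e5, 0, 0.5), 1e5, 3)^2)))
  obs <- mean(sqrt(rowSums((as.matrix(j1[, c("x", "y", "z")]) -
                              as.matrix(lm[, c("x", "y", "z")]))^2)))
  expect_equal(obs, oracle, tolerance = 0.05)
})
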