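# Registration recovery tests run on a 48-voxel (3.33 mm) phantom: large
# enough for sub-voxel accuracy, small enough to keep the suite fast.

test_that("registering a volume to itself recovers the identity", {
  ph <- fix_phantom(32)
  b <- extract_brain(ph$volume)
  res <- suppressWarnings(
    register(b$masked, b$masked, registration_config(dof = 6L),
             fixed_mask = b$mask))
  d <- decompose_affine(res$transform)
  expect_lt(max(abs(d$translation_mm)), 0.1)
  expect_lt(max(abs(d$rotation_deg)), 0.1)
  # cost monotonicity against the (identity) initialization
  expect_gte(res$cost, res$diagnostics$init_cost - 1e-9)
})

test_that("a known rigid displacement is recovered to sub-voxel accuracy", {
  pair <- fix_pair(48, distortion_spec(translation_mm = c(3, -2, 1.5),
                                       rotation_deg = c(0, 0, 4),
                                       noise_sigma = 5))
  res <- suppressWarnings(
    register(pair$fixed, pair$moving, registration_config(dof = 6L),
             fixed_mask = pair$fixed_mask))
  got <- decompose_affine(res$transform)
  want <- decompose_affine(pair$truth$true_affine)
  expect_lt(max(abs(got$translation_mm - want$translation_mm)), 0.3)
  expect_lt(max(abs(got$rotation_deg - want$rotation_deg)), 0.3)
  expect_gte(res$cost, res$diagnostics$init_cost)
})

test_that("12-DOF registration recovers small scales and shears", {
  # noise-free pair in the regime of interest: ~1% scales, 0.01 shears
  pair <- fix_pair(48, distortion_spec(translation_mm = c(2, -1.5, 1),
                                       rotation_deg = c(1.5, -1, 2),
                                       scales = c(1.01, 0.99, 1.0),
                                       shears = c(0.01, 0, 0)))
  res <- suppressWarnings(
    register(pair$fixed, pair$moving, registration_config(dof = 12L),
             fixed_mask = pair$fixed_mask))
  got <- decompose_affine(res$transform)
  want <- decompose_affine(pair$truth$true_affine)
  expect_lt(max(abs(got$scales - want$scales)), 0.005)
  expect_lt(max(abs(got$shear_tangents - want$shear_tangents)), 0.005)
})

test_that("forward and reverse registrations compose to the identity", {
  pair <- fix_pair(48, distortion_spec(translation_mm = c(3, -2, 1.5),
                                       rotation_deg = c(0, 0, 4)))
  cfg <- registration_config(dof = 6L)
  fwd <- suppressWarnings(register(pair$fixed, pair$moving, cfg,
                                   fixed_mask = pair$fixed_mask))
  rev <- suppressWarnings(register(pair$moving, pair$fixed, cfg,
                                   fixed_mask = pair$moving_mask))
  round_trip <- decompose_affine(compose_affine(fwd$transform,
                                                rev$transform))
  expect_lt(max(abs(round_trip$translation_mm)), 1)
  expect_lt(max(abs(round_trip$rotation_deg)), 1)
})

test_that("with rigid-only truth, 6 DOF matches 12 DOF to within the noise floor", {
  pair <- fix_pair(48, distortion_spec(translation_mm = c(2, -1, 1.5),
                                       rotation_deg = c(1, 2, -1),
                                       noise_sigma = 5))
  lm_err <- function(res) {
    mapped <- transform_points(res$transform, pair$truth$landmarks_test)
    landmark_distances(pair$truth$landmarks_ref, mapped)$mean
  }
  r6 <- suppressWarnings(
    register(pair$fixed, pair$moving, registration_config(dof = 6L),
             fixed_mask = pair$fixed_mask))
  r12 <- suppressWarnings(
    register(pair$fixed, pair$moving, registration_config(dof = 12L),
             fixed_mask = pair$fixed_mask))
  vs <- voxel_size(pair$ref)[1]
  # rigid truth: the extra 6 DOF must not be needed
  expect_lt(abs(lm_err(r6) - lm_err(r12)), 0.3 * vs)
  expect_lt(lm_err(r6), vs)
})

test_that("an explicit initialization is honoured and never made worse", {
  pair <- fix_pair(32, distortion_spec(translation_mm = c(3, -2, 1.5),
                                       rotation_deg = c(0, 0, 3)))
  init <- pair$truth$true_affine  # start at the right answer
  res <- suppressWarnings(
    register(pair$fixed, pair$moving,
             registration_config(dof = 6L, pyramid_levels = 2L),
             init = init, fixed_mask = pair$fixed_mask))
  expect_gte(res$cost, res$diagnostics$init_cost - 1e-9)
  got <- decompose_affine(res$transform)
  want <- decompose_affine(init)
  expect_lt(max(abs(got$translation_mm - want$translation_mm)), 1)
})
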