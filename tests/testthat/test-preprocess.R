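test_that("brain extraction recovers the analytic support of the phantom", {
  ph <- fix_phantom(32)
  got <- extract_brain(ph$volume)
  env <- default_phantom_spec(32)$ellipsoids[[1]]
  pts <- warpgauge:::grid_world_coords(dim(ph$volume$data),
                                       ph$volume$affine)
  truth <- array(warpgauge:::ellipsoid_inside(env, pts),
                 dim(ph$volume$data))
  inter <- sum(got$mask$data & truth)
  dice <- 2 * inter / (sum(got$mask$data) + sum(truth))
  expect_gte(dice, 0.95)
  # masking contract: zero outside the mask, untouched inside
  expect_true(all(got$masked$data[!got$mask$data] == 0))
  expect_equal(got$masked$data[got$mask$data],
               ph$volume$data[got$mask$data])
})

test_that("a detached shell component is removed by the largest-component rule", {
  spec <- phantom_spec(
    grid_shape = c(32, 32, 32), voxel_size_mm = c(5, 5, 5),
    ellipsoids = list(
      list(name = "brain", center = c(0, 0, 0), semiaxes = c(45, 45, 45),
           rotation_deg = c(0, 0, 0), intensity = 100),
      list(name = "skull_bit", center = c(0, 0, 70),
           semiaxes = c(10, 10, 6), rotation_deg = c(0, 0, 0),
           intensity = 120)))
  ph <- generate_phantom(spec)
  got <- extract_brain(ph$volume)
  # the detached blob sits near the top of the grid; none of it survives
  shell_idx <- which(ph$volume$data > 0 &
                       warpgauge:::grid_world_coords(
                         dim(ph$volume$data), ph$volume$affine)[3, ] > 55)
  expect_true(all(!got$mask$data[shell_idx]))
})

test_that("extraction is invariant to global intensity scaling", {
  ph <- fix_phantom(24)
  m1 <- extract_brain(ph$volume)$mask$data
  scaled <- ph$volume
  scaled$data <- scaled$data * 37.5
  m2 <- extract_brain(scaled)$mask$data
  expect_identical(m1, m2)
})

test_that("bias correction leaves a uniform volume unchanged and preserves the mask mean", {
  d <- array(0, c(24, 24, 24))
  d[5:20, 5:20, 5:20] <- 50
  vol <- image_volume_from_spacing(d, c(4, 4, 4))
  out <- correct_bias(vol)
  expect_equal(out$data, vol$data, tolerance = 1e-10)

  ph <- fix_phantom(24)
  mask <- extract_brain(ph$volume)$mask
  biased <- ph$volume
  pts <- warpgauge:::grid_world_coords(dim(ph$volume$data),
                                       ph$volume$affine)
  ramp <- array(0.3 * pts[1, ] / max(abs(pts[1, ])), dim(ph$volume$data))
  biased$data <- ph$volume$data * exp(ramp)
  fixed <- correct_bias(biased, mask = mask)
  m <- mask$data
  expect_lt(abs(mean(fixed$data[m]) - mean(biased$data[m])) /
              mean(biased$data[m]), 0.001)
})

test_that("bias correction strongly reduces a multiplicative ramp", {
  # uniform ellipsoid times exp(linear ramp, amplitude 0.3)
  spec <- phantom_spec(
    grid_shape = c(32, 32, 32), voxel_size_mm = c(5, 5, 5),
    ellipsoids = list(list(center = c(0, 0, 0), semiaxes = c(60, 60, 60),
                           rotation_deg = c(0, 0, 0), intensity = 100)))
  ph <- generate_phantom(spec)
  mask <- extract_brain(ph$volume)$mask
  pts <- warpgauge:::grid_world_coords(dim(ph$volume$data),
                                       ph$volume$affine)
  ramp <- array(0.3 * pts[1, ] / max(abs(pts[1, ])), dim(ph$volume$data))
  biased <- ph$volume
  biased$data <- biased$data * exp(ramp)
  fixed <- correct_bias(biased, mask = mask)
  m <- mask$data
  cv <- function(x) sd(x) / mean(x)
  expect_gte(cv(biased$data[m]) / cv(fixed$data[m]), 5)
})

test_that("bias correction is idempotent to within one percent", {
  ph <- fix_phantom(24)
  mask <- extract_brain(ph$volume)$mask
  once <- correct_bias(ph$volume, mask = mask)
  twice <- correct_bias(once, mask = mask)
  m <- mask$data
  # intensity-level change on re-run, relative to the mean signal; the
  # worst single voxel sits on a structure boundary so the bulk measure
  # is the meaningful one
  rel <- abs(twice$data[m] - once$data[m]) / mean(once$data[m])
  expect_lt(mean(rel), 0.01)
  expect_lt(max(rel), 0.05)
})

test_that("degenerate inputs raise no-signal errors", {
  zero <- image_volume_from_spacing(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_error(extract_brain(zero), "no-signal")
  expect_error(correct_bias(zero), "no-signal")
  neg <- image_volume_from_spacing(array(-1, c(16, 16, 16)), c(2, 2, 2))
  expect_error(correct_bias(neg), ">= 0")
})
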