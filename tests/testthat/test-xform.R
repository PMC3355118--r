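test_that("decomposition of analytic matrices matches closed forms", {
  # identity
  d <- decompose_affine(diag(4))
  expect_equal(d$scales, c(1, 1, 1))
  expect_equal(unname(d$shear_tangents), c(0, 0, 0))
  expect_equal(d$determinant, 1)
  expect_equal(d$max_scale_dev, 0)
  expect_equal(d$max_skew, 0)
  expect_equal(d$volume_dev, 0)

  # pure diagonal scaling
  d <- decompose_affine(diag(c(1.01, 0.99, 1.0, 1)))
  expect_equal(d$scales, c(1.01, 0.99, 1.0))
  expect_equal(d$max_scale_dev, 0.01)
  expect_equal(d$determinant, 1.01 * 0.99)
  expect_equal(d$volume_dev, abs(1.01 * 0.99 - 1))

  # unit-upper-triangular shear: (x, y) entry 0.01
  A <- diag(4)
  A[1, 2] <- 0.01
  d <- decompose_affine(A)
  expect_equal(d$scales, c(1, 1, 1))
  expect_equal(d$max_skew, 0.01)
  expect_equal(unname(d$shear_tangents["xy"]), 0.01)
  expect_equal(d$determinant, 1)
})

test_that("random proper affines recompose exactly and metrics match determinant", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    A <- random_proper_affine()
    d <- decompose_affine(A)
    worst <- max(worst, max_abs(recompose_affine(d), A))
    # brute-force determinant of the 3x3 block
    M <- A[1:3, 1:3]
    det_bf <- M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
      M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
      M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
    expect_equal(d$volume_dev, abs(det_bf - 1), tolerance = 1e-9)
    expect_equal(prod(d$scales), d$determinant, tolerance = 1e-12)
    expect_true(all(d$scales > 0))
  }
  expect_lt(worst, 1e-10)
})

test_that("scale and skew metrics are invariant under left rotation", {
  set.seed(7)
  for (i in 1:20) {
    A <- random_proper_affine()
    R <- affine_from_params(rotation_deg = rnorm(3, sd = 40))
    d1 <- decompose_affine(A)
    d2 <- decompose_affine(compose_affine(R, A))
    expect_equal(d1$scales, d2$scales, tolerance = 1e-9)
    expect_equal(d1$shear_tangents, d2$shear_tangents, tolerance = 1e-9)
  }
})

test_that("reflections are rejected", {
  A <- diag(c(-1, 1, 1, 1))
  expect_error(decompose_affine(A), "reflection")
})

test_that("compose and invert behave like matrix algebra on points", {
  set.seed(2)
  A0 <- random_proper_affine()
  expect_equal(compose_affine(diag(4), A0), A0)
  t1 <- affine_from_params(c(1, 2, 3))
  t2 <- affine_from_params(c(-4, 0.5, 2))
  expect_equal(compose_affine(t1, t2)[1:3, 4], c(-3, 2.5, 5))
  expect_equal(invert_affine(t1)[1:3, 4], c(-1, -2, -3))

  set.seed(11)
  for (i in 1:25) {
    A <- random_proper_affine()
    B <- random_proper_affine()
    p <- rnorm(3, sd = 20)
    expect_equal(apply_affine(compose_affine(B, A), p),
                 apply_affine(B, apply_affine(A, p)), tolerance = 1e-9)
    expect_lt(max_abs(compose_affine(A, invert_affine(A)), diag(4)), 1e-10)
  }
})

test_that("affine parameterization round-trips through decomposition", {
  set.seed(3)
  for (i in 1:25) {
    tr <- rnorm(3, sd = 5)
    ro <- rnorm(3, sd = 20)
    sc <- exp(rnorm(3, sd = 0.05))
    sh <- rnorm(3, sd = 0.05)
    A <- affine_from_params(tr, ro, sc, sh)
    d <- decompose_affine(A)
    expect_equal(d$translation_mm, tr, tolerance = 1e-9)
    expect_equal(d$rotation_deg, ro, tolerance = 1e-9)
    expect_equal(d$scales, sc, tolerance = 1e-9)
    expect_equal(unname(d$shear_tangents), sh, tolerance = 1e-9)
  }
})

test_that("transform text files and FLIRT-style conversion round-trip", {
  set.seed(5)
  A <- random_proper_affine()
  f <- tempfile(fileext = ".mat")
  on.exit(unlink(f))
  write_affine(A, f)
  expect_lt(max_abs(read_affine(f), A), 1e-12)
  expect_error(read_affine(textConnectionPath <- {
    bad <- tempfile(); writeLines(c("1 2 3", "4 5 6"), bad); bad
  }), "4 matrix rows")
  unlink(textConnectionPath)

  fixed <- image_volume_from_spacing(array(0, c(10, 12, 14)), c(1, 1.5, 2))
  moving <- image_volume_from_spacing(array(0, c(8, 8, 8)), c(2.5, 2.5, 2.5))
  Af <- world_to_flirt(A, fixed, moving)
  expect_lt(max_abs(flirt_to_world(Af, fixed, moving), A), 1e-9)
})
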