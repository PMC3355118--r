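make_mask <- function(shape, lo, hi, spacing = c(2, 2, 2)) {
  m <- array(FALSE, shape)
  m[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- TRUE
  brain_mask(m, {
    a <- diag(c(spacing, 1)); a[1:3, 4] <- -spacing * (shape - 1) / 2; a
  })
}

test_that("parcellation splits the bounding box into exact thirds", {
  # AP axis spanning 0-based indices 0..89 -> thirds [0,30) [30,60) [60,90)
  mask <- make_mask(c(12, 90, 12), c(0, 0, 0), c(12, 90, 12))
  grid <- parcel(mask, "3slab")
  expect_length(grid$regions, 3L)
  ap <- t(vapply(grid$regions, function(r) r$box[, 2], numeric(2)))
  expect_equal(sort(ap[, 1]), c(0, 30, 60))
  expect_equal(sort(ap[, 2]), c(30, 60, 90))
  # posterior = smallest world y
  post <- grid$regions[[which(vapply(grid$regions, `[[`, "", "label") ==
                                "posterior")]]
  expect_equal(unname(post$box[, 2]), c(0, 30))
})

test_that("schemes produce the expected labels", {
  mask <- make_mask(c(30, 30, 30), c(2, 3, 4), c(28, 27, 26))
  g9 <- parcel(mask, "3x3")
  expect_length(g9$regions, 9L)
  labs <- vapply(g9$regions, `[[`, "", "label")
  expect_setequal(labs, c("posterior-superior", "mid-superior",
                          "antero-superior", "posterior-middle", "middle",
                          "antero-middle", "posterior-inferior",
                          "mid-inferior", "antero-inferior"))
  g3 <- parcel(mask, "3slab")
  expect_setequal(vapply(g3$regions, `[[`, "", "label"),
                  c("posterior", "middle", "anterior"))
})

test_that("regions tile the bounding box exactly, with no overlap or gap", {
  set.seed(21)
  for (i in 1:20) {
    lo <- sample(0:5, 3, replace = TRUE)
    hi <- lo + sample(5:25, 3, replace = TRUE)
    shape <- hi + sample(0:4, 3, replace = TRUE)
    mask <- make_mask(shape, lo, hi)
    for (scheme in c("3x3", "3slab")) {
      grid <- parcel(mask, scheme)
      cover <- array(0L, shape)
      for (r in grid$regions) {
        b <- r$box
        cover[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
              (b[1, 3] + 1):b[2, 3]] <-
          cover[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                (b[1, 3] + 1):b[2, 3]] + 1L
      }
      bbox <- array(0L, shape)
      bbox[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- 1L
      expect_identical(cover, bbox)
    }
  }
})

test_that("too-thin masks raise a parcellation error", {
  mask <- make_mask(c(20, 20, 20), c(0, 8, 0), c(20, 10, 20))
  expect_error(parcel(mask, "3slab"), "parcellation error")
})

test_that("signal-loss detection matches a direct counting oracle", {
  ph <- fix_phantom(32)
  bf <- extract_brain(ph$volume)
  grid <- parcel(bf$mask, "3x3")
  region <- grid$regions[[5]]
  for (frac in c(0.05, 0.1, 0.3)) {
    got <- detect_signal_loss(ph$volume, region, bf$mask,
                              intensity_frac = frac)
    # direct computation
    b <- region$box
    sub <- ph$volume$data[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                          (b[1, 3] + 1):b[2, 3]]
    msub <- bf$mask$data[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                         (b[1, 3] + 1):b[2, 3]]
    robmax <- unname(quantile(ph$volume$data[bf$mask$data], 0.98,
                              type = 7))
    want_frac <- mean(sub[msub] > frac * robmax)
    expect_equal(got$fraction, want_frac)
    expect_identical(got$excluded, want_frac < 0.5)
  }
  # an intact central region of the clean phantom is never excluded
  expect_false(detect_signal_loss(ph$volume, region, bf$mask)$excluded)
})

test_that("regional summary equals brute-force aggregation", {
  mk <- function(label, skew, scale, vol) {
    structure(list(label = label, excluded = FALSE,
                   report = list(max_skew = skew, max_scale_dev = scale,
                                 volume_dev = vol)),
              class = "regional_result")
  }
  res <- list(mk("middle", 0.00, 0.001, 0.002),
              mk("middle", 0.02, 0.003, 0.004),
              mk("antero-middle", 0.01, 0.005, 0.006),
              structure(list(label = "mid-inferior", excluded = TRUE,
                             reason = "signal loss"),
                        class = "regional_result"))
  s <- regional_summary(res)
  expect_equal(nrow(s), 2L)
  mid <- s[s$label == "middle", ]
  expect_equal(mid$mean_max_skew, 0.01)
  expect_equal(mid$max_max_skew, 0.02)
  expect_equal(mid$n, 2L)
  expect_false("mid-inferior" %in% s$label)
  # single result: summary equals that result's metrics
  s1 <- regional_summary(res[3])
  expect_equal(s1$mean_max_skew, 0.01)
  expect_equal(s1$max_volume_dev, 0.006)
  expect_error(regional_summary(res[4]), "empty summary")
})
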