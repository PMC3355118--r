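# Shared fixture builders: everything is generated in code at test time.

# small reference phantom + landmarks (n voxels per axis, 160 mm FOV)
fix_phantom <- function(n = 32L) {
  generate_phantom(default_phantom_spec(n))
}

# distorted pair under a given distortion spec; returns fixed/moving
# brain-extracted volumes plus masks and ground truth. The test image is
# rasterized analytically (spec passed through) so both images share the
# same sharpness, as two real acquisitions would.
fix_pair <- function(n = 32L, dspec, seed = 7L,
                     cavity = c(0, 38, -42)) {
  spec <- default_phantom_spec(n)
  ph <- generate_phantom(spec)
  out <- apply_ground_truth_distortion(ph$volume, ph$landmarks, dspec,
                                       cavity_center_mm = cavity,
                                       seed = seed, spec = spec)
  bf <- extract_brain(ph$volume)
  bm <- extract_brain(out$volume)
  list(ref = ph$volume, test = out$volume, landmarks = ph$landmarks,
       truth = out$truth, fixed = bf$masked, fixed_mask = bf$mask,
       moving = bm$masked, moving_mask = bm$mask)
}

# a random proper affine (positive-determinant 3x3 block + translation)
random_proper_affine <- function() {
  repeat {
    M <- matrix(rnorm(9, sd = 0.5), 3, 3) + diag(3)
    if (det(M) > 0.05) break
  }
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- rnorm(3, sd = 10)
  A
}

# maximum absolute difference of two matrices/vectors
max_abs <- function(a, b) max(abs(a - b))
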