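#' Staged affine registration by mutual information
#'
#' From-scratch implementation of the staged schedule used for
#' cross-field-strength co-registration: a coarse rotational grid search
#' (default +/- 30 degrees at 3-degree steps, translation initialized by
#' centre-of-mass alignment) at the coarsest level of a Gaussian
#' pyramid, derivative-free 6-DOF refinement through the pyramid, and,
#' for 12 DOF, release of scales and shears at the finest levels.
#' Rotations are parameterized about the fixed-volume centre, and the
#' returned matrix is a world-to-world (moving -> fixed) transform.
#'
#' @name register
NULL

#' Registration configuration
#'
#' @param dof degrees of freedom: 6 (rigid) or 12 (full affine).
#' @param pyramid_levels number of dyadic pyramid levels (>= 1).
#' @param coarse_search_range_deg half-range of the rotational grid
#'   search per axis, degrees.
#' @param coarse_search_step_deg angular resolution of the coarse search.
#' @param histogram_bins joint-histogram bins (>= 8).
#' @param cost `"mi"` (mutual information, default) or `"cr"`
#'   (correlation ratio).
#' @param convergence_tol cost change (bits) below which refinement
#'   restarts stop.
#' @param max_iterations simplex iteration cap per stage.
#' @param seed integer seed for any randomized fallback initializations.
#' @return object of class `registration_config`.
#' @export
registration_config <- function(dof = 12L, pyramid_levels = 3L,
                                coarse_search_range_deg = 30,
                                coarse_search_step_deg = 3,
                                histogram_bins = 64L,
                                cost = c("mi", "cr"),
                                convergence_tol = 1e-5,
                                max_iterations = 500L,
                                seed = NULL) {
  cost <- match.arg(cost)
  if (!dof %in% c(6L, 12L)) stop("dof must be 6 or 12", call. = FALSE)
  if (coarse_search_step_deg <= 0) stop("search step must be > 0",
                                        call. = FALSE)
  if (histogram_bins < 8L) stop("histogram_bins must be >= 8",
                                call. = FALSE)
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1",
                                call. = FALSE)
  structure(list(dof = as.integer(dof),
                 pyramid_levels = as.integer(pyramid_levels),
                 coarse_search_range_deg = coarse_search_range_deg,
                 coarse_search_step_deg = coarse_search_step_deg,
                 histogram_bins = as.integer(histogram_bins),
                 cost = cost,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 seed = seed),
            class = "registration_config")
}

# 12-vector of parameters (t, r, s, h) -> affine about `center`
par_to_affine <- function(par, center) {
  affine_from_params(par[1:3], par[4:6], par[7:9], par[10:12], center)
}

# inverse of par_to_affine for a proper affine
params_from_affine <- function(A, center) {
  A <- as_affine(A)
  dec <- decompose_affine(A)
  A3 <- A[1:3, 1:3]
  t <- A[1:3, 4] - center + A3 %*% center
  c(as.numeric(t), dec$rotation_deg, dec$scales,
    as.numeric(dec$shear_tangents))
}

# pyramid of cost-ready levels; level 1 is finest (lightly smoothed)
build_pyramid <- function(vol, levels) {
  out <- vector("list", levels)
  out[[1]] <- smooth_volume(vol, 0.5 * voxel_size(vol))
  cur <- vol
  for (k in seq_len(levels - 1L)) {
    cur <- downsample2(cur)
    out[[k + 1L]] <- cur
  }
  out
}

mask_pyramid <- function(mask_arr, affine, levels) {
  mv <- image_volume(array(as.numeric(mask_arr), dim(mask_arr)), affine)
  out <- vector("list", levels)
  out[[1]] <- mask_arr
  cur <- mv
  for (k in seq_len(levels - 1L)) {
    cur <- downsample2(cur)
    out[[k + 1L]] <- cur$data > 0.35
  }
  out
}

com_world <- function(vol) {
  s <- cost_samples(vol)
  w <- pmax(s$fvals, 0)
  as.numeric(s$pts %*% w / sum(w))
}

#' Register a moving volume to a fixed volume
#'
#' @param fixed,moving `image_volume`s; brain-extracted (background-zero)
#'   input is recommended so the default mask (`fixed > 0`) restricts the
#'   cost to brain tissue.
#' @param config a [registration_config()].
#' @param init optional 4x4 initial transform (moving world to fixed
#'   world); when supplied, the coarse rotational search is skipped.
#' @param fixed_mask optional [brain_mask()] restricting cost samples.
#' @param param_bounds optional named list bounding the search around the
#'   initialization: `translation_mm`, `rotation_deg`, `scale_dev`,
#'   `shear` (each a scalar half-width). Used by regional registration
#'   to curb robustness loss on small sub-volumes.
#' @return list with `transform` (4x4 affine), `cost` (final cost at the
#'   finest level) and `diagnostics` (per-stage trace, convergence flag,
#'   initial cost).
#' @export
register <- function(fixed, moving, config = registration_config(),
                     init = NULL, fixed_mask = NULL, param_bounds = NULL) {
  stopifnot(inherits(fixed, "image_volume"),
            inherits(moving, "image_volume"),
            inherits(config, "registration_config"))
  L <- config$pyramid_levels
  fpyr <- build_pyramid(fixed, L)
  mpyr <- build_pyramid(moving, L)
  mask_arr <- if (is.null(fixed_mask)) fixed$data > 0 else fixed_mask$data
  mkpyr <- mask_pyramid(mask_arr, fixed$affine, L)

  center <- as.numeric(vox2world(fixed, (dim(fixed$data) - 1) / 2))
  jseed <- (config$seed %||% 1234L)
  levels_samples <- lapply(seq_len(L), function(k) {
    m <- mkpyr[[k]]
    if (!any(m)) m <- fpyr[[k]]$data > 0
    nmask <- sum(m)
    s <- cost_samples(fpyr[[k]],
                      brain_mask(array(m, dim(fpyr[[k]]$data)),
                                 fpyr[[k]]$affine),
                      jitter = TRUE, seed = jseed + k,
                      oversample = min(8L, max(1L, ceiling(2e4 / nmask))))
    s$frange <- robust_range(s$fvals)
    s$mrange <- robust_range(as.numeric(mpyr[[k]]$data))
    s
  })

  cost_at <- function(A, k, bins = config$histogram_bins,
                      cost = config$cost) {
    s <- levels_samples[[k]]
    mo <- max(50L, round(0.2 * ncol(s$pts)))
    if (cost == "mi")
      mi_from_samples(s, mpyr[[k]], A, bins, mo, s$frange, s$mrange)$mi
    else
      cr_from_samples(s, mpyr[[k]], A, bins, mo, s$frange)$cr
  }

  # generic validity bounds plus optional user bounds around init params
  lower <- c(rep(-500, 3), rep(-180, 3), rep(0.5, 3), rep(-0.5, 3))
  upper <- c(rep(500, 3), rep(180, 3), rep(2, 3), rep(0.5, 3))
  bound_center <- NULL
  bound_halfwidth <- NULL

  neg_cost_fn <- function(k, active) {
    s <- levels_samples[[k]]
    function(par_active, par_full) {
      par <- par_full
      par[active] <- par_active
      if (any(par < lower) || any(par > upper))
        return(1e3 + sum(pmax(lower - par, 0) + pmax(par - upper, 0)))
      if (!is.null(bound_halfwidth)) {
        ex <- abs(par - bound_center) - bound_halfwidth
        if (any(ex > 0)) return(1e3 + sum(pmax(ex, 0)))
      }
      A <- par_to_affine(par, center)
      v <- tryCatch(cost_at(A, k), error = function(e) NA_real_)
      if (!is.finite(v)) return(1e3)
      -v
    }
  }

  stages <- list()
  n_stage <- 0L
  run_nm <- function(par, k, active, stage, parscale) {
    fn <- neg_cost_fn(k, active)
    res <- optim(par[active], fn, par_full = par, method = "Nelder-Mead",
                 control = list(maxit = config$max_iterations,
                                reltol = 1e-10,
                                parscale = parscale[active]))
    par[active] <- res$par
    n_stage <<- n_stage + 1L
    stages[[n_stage]] <<- data.frame(stage = stage, level = k,
                                     cost = -res$value,
                                     evals = res$counts[["function"]],
                                     converged = res$convergence == 0L)
    list(par = par, cost = -res$value)
  }

  ps <- c(rep(2, 6), rep(0.02, 6))
  act6 <- 1:6
  act12 <- 1:12

  if (is.null(init)) {
    # coarse rotational grid search at the coarsest level, translation
    # from centre-of-mass alignment per rotation candidate
    rng <- config$coarse_search_range_deg
    stp <- config$coarse_search_step_deg
    angs <- seq(-rng, rng, by = stp)
    cand <- as.matrix(expand.grid(rx = angs, ry = angs, rz = angs))
    comf <- com_world(fpyr[[L]])
    comm <- com_world(mpyr[[L]])
    vals <- numeric(nrow(cand))
    pars <- matrix(0, nrow(cand), 12)
    for (q in seq_len(nrow(cand))) {
      r <- cand[q, ]
      R3 <- rot_z(r[3] * pi / 180) %*% rot_y(r[2] * pi / 180) %*%
        rot_x(r[1] * pi / 180)
      t <- comf - center - R3 %*% (comm - center)
      par <- c(as.numeric(t), r, 1, 1, 1, 0, 0, 0)
      A <- par_to_affine(par, center)
      vals[q] <- tryCatch(cost_at(A, L), error = function(e) NA_real_)
      pars[q, ] <- par
    }
    if (all(is.na(vals)))
      stop("overlap error: no coarse-search candidate produced overlap",
           call. = FALSE)
    keep <- head(order(-vals), 5L)
    best <- NULL
    for (q in keep) {
      r <- run_nm(pars[q, ], L, act6, "coarse-6dof", ps * 2)
      if (is.null(best) || r$cost > best$cost) best <- r
    }
    par <- best$par
  } else {
    par <- params_from_affine(init, center)
    if (config$dof == 6L) par[7:12] <- c(1, 1, 1, 0, 0, 0)
  }

  if (!is.null(param_bounds)) {
    hw <- c(rep(param_bounds$translation_mm %||% Inf, 3),
            rep(param_bounds$rotation_deg %||% Inf, 3),
            rep(param_bounds$scale_dev %||% Inf, 3),
            rep(param_bounds$shear %||% Inf, 3))
    bound_center <- par
    bound_halfwidth <- hw
  }

  # 6-DOF refinement down the pyramid
  for (k in rev(seq_len(L))) {
    r <- run_nm(par, k, act6, "refine-6dof", ps)
    par <- r$par
  }
  final_cost <- r$cost

  if (config$dof == 12L) {
    for (k in rev(seq_len(min(2L, L)))) {
      r <- run_nm(par, k, act12, "refine-12dof", ps)
      par <- r$par
    }
    final_cost <- r$cost
  }

  # polish restarts at the finest level until the gain falls below tol
  active <- if (config$dof == 12L) act12 else act6
  polish_converged <- FALSE
  for (rep_i in 1:3) {
    r <- run_nm(par, 1L, active, "polish", ps * 0.25)
    gain <- r$cost - final_cost
    par <- r$par
    final_cost <- r$cost
    if (gain < config$convergence_tol) {
      polish_converged <- TRUE
      break
    }
  }

  A_final <- par_to_affine(par, center)
  init_cost <- tryCatch(
    cost_at(if (is.null(init)) diag(4) else as_affine(init), 1L),
    error = function(e) NA_real_)
  # never return a transform worse than the initialization
  if (is.finite(init_cost) && final_cost < init_cost) {
    A_final <- if (is.null(init)) diag(4) else as_affine(init)
    final_cost <- init_cost
  }
  diag_df <- do.call(rbind, stages)
  converged <- polish_converged
  if (!converged)
    warning("registration: cost still improving when the restart cap ",
            "was reached; best-so-far transform returned", call. = FALSE)
  list(transform = A_final, cost = final_cost,
       diagnostics = list(stages = diag_df, converged = converged,
                          init_cost = init_cost,
                          parameters = par, center = center))
}
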