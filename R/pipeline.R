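#' Pipeline configuration and end-to-end orchestration
#'
#' [run_pipeline()] executes the full distortion-analysis workflow on
#' one volume pair: bias correction, brain extraction, staged global
#' registration (6-DOF then 12-DOF internally), landmark assessment,
#' transform decomposition, regional piecewise registration, and
#' edge-overlay QC, writing a self-contained JSON report. Every number
#' in the report is produced by an exported module function; the
#' orchestrator only sequences them.
#'
#' @name pipeline
NULL

#' Build a validated pipeline configuration
#'
#' @param fixed,moving input volumes: `image_volume`s or NIfTI paths.
#' @param out_dir output directory (created if missing).
#' @param landmarks_fixed,landmarks_moving optional [landmark_set()]s or
#'   TSV paths (world mm, each set in its own image space).
#' @param registration a [registration_config()].
#' @param scheme regional parcellation scheme (`"3x3"` or `"3slab"`),
#'   or `"none"` to skip the regional stage.
#' @param bias_correct,brain_extract preprocessing toggles.
#' @param supplied_transform optional 4x4 matrix or transform-file path;
#'   when given, registration is skipped and assessment stages consume
#'   this transform.
#' @param overlays write edge-overlay QC PNGs.
#' @param seed integer seed echoed to every seeded operation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixed, moving, out_dir,
                            landmarks_fixed = NULL,
                            landmarks_moving = NULL,
                            registration = registration_config(),
                            scheme = c("3x3", "3slab", "none"),
                            bias_correct = TRUE, brain_extract = TRUE,
                            supplied_transform = NULL, overlays = TRUE,
                            seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(registration, "registration_config"))
  structure(list(fixed = fixed, moving = moving, out_dir = out_dir,
                 landmarks_fixed = landmarks_fixed,
                 landmarks_moving = landmarks_moving,
                 registration = registration, scheme = scheme,
                 bias_correct = isTRUE(bias_correct),
                 brain_extract = isTRUE(brain_extract),
                 supplied_transform = supplied_transform,
                 overlays = isTRUE(overlays), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so configuration typos fail loudly.
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()] (the `registration` key holds the arguments of
#'   [registration_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "registration")
  unknown <- setdiff(names(y), c(allowed, "registration"))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$registration)) {
    runknown <- setdiff(names(y$registration),
                        names(formals(registration_config)))
    if (length(runknown))
      stop("unknown registration keys: ",
           paste(runknown, collapse = ", "), call. = FALSE)
    y$registration <- do.call(registration_config, y$registration)
  }
  do.call(pipeline_config, y)
}

config_echo <- function(config) {
  e <- unclass(config)
  e$fixed <- if (is.character(e$fixed)) e$fixed else "<in-memory volume>"
  e$moving <- if (is.character(e$moving)) e$moving else "<in-memory volume>"
  for (k in c("landmarks_fixed", "landmarks_moving"))
    if (!is.null(e[[k]]) && !is.character(e[[k]]))
      e[[k]] <- "<in-memory landmarks>"
  if (!is.null(e$supplied_transform) && !is.character(e$supplied_transform))
    e$supplied_transform <- as.numeric(t(as_affine(e$supplied_transform)))
  e$registration <- unclass(e$registration)
  e
}

load_vol <- function(x) if (inherits(x, "image_volume")) x else
  read_volume(x)
load_lm <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "landmark_set")) x else read_landmarks(x)
}

#' Run the full distortion-analysis pipeline
#'
#' Stages run in order: bias correction, brain extraction, global
#' registration (or consumption of a supplied transform), landmark
#' assessment, transform decomposition, regional registration, QC
#' overlays. Stage errors are recorded in the report and dependent
#' stages are skipped; a partial report is still written.
#'
#' @param config a [pipeline_config()].
#' @param verbose log one START/END line per stage.
#' @return object of class `run_report` (also written as
#'   `report.json` in `out_dir`, alongside `global_xfm.mat`,
#'   `regional.csv` and QC PNGs).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(software = paste0("warpgauge ",
                                   as.character(utils::packageVersion("warpgauge"))),
                 config = config_echo(config), errors = list(),
                 stages = character(0))
  say <- function(...) if (verbose) message("[warpgauge] ", ...)
  stage <- function(name, expr) {
    say("START ", name)
    out <- tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      say("ERROR ", name, ": ", conditionMessage(e))
      NULL
    })
    report$stages <<- c(report$stages, name)
    say("END ", name)
    out
  }

  fixed <- stage("load-fixed", load_vol(config$fixed))
  moving <- stage("load-moving", load_vol(config$moving))
  if (is.null(fixed) || is.null(moving)) {
    report$ok <- FALSE
    class(report) <- "run_report"
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(report)
  }

  if (config$bias_correct) {
    fixed <- stage("bias-correct-fixed", correct_bias(fixed)) %||% fixed
    moving <- stage("bias-correct-moving", correct_bias(moving)) %||% moving
  }
  fmask <- NULL
  if (config$brain_extract) {
    bf <- stage("brain-extract-fixed", extract_brain(fixed))
    bm <- stage("brain-extract-moving", extract_brain(moving))
    if (!is.null(bf)) { fixed <- bf$masked; fmask <- bf$mask }
    if (!is.null(bm)) moving <- bm$masked
  }

  global <- NULL
  if (!is.null(config$supplied_transform)) {
    global <- stage("load-transform", {
      if (is.character(config$supplied_transform))
        read_affine(config$supplied_transform)
      else as_affine(config$supplied_transform)
    })
    report$registration <- list(supplied = TRUE)
  } else {
    reg <- stage("global-registration",
                 register(fixed, moving, config$registration,
                          fixed_mask = fmask))
    if (!is.null(reg)) {
      global <- reg$transform
      report$registration <- list(supplied = FALSE, cost = reg$cost,
                                  converged = reg$diagnostics$converged)
    }
  }

  if (!is.null(global)) {
    write_affine(global, file.path(config$out_dir, "global_xfm.mat"))
    report$global_transform <- as.numeric(t(global))
    dec <- stage("decompose", decompose_affine(global))
    if (!is.null(dec)) report$decomposition <- unclass(dec)

    lf <- load_lm(config$landmarks_fixed)
    lmv <- load_lm(config$landmarks_moving)
    if (!is.null(lf) && !is.null(lmv)) {
      ds <- stage("landmark-assessment",
                  landmark_distances(lf, transform_points(global, lmv),
                                     ref_voxel_mm = voxel_size(fixed)))
      if (!is.null(ds)) report$landmarks <- distance_stats_to_json(ds)
    }

    if (config$scheme != "none" && !is.null(fmask)) {
      rg <- stage("regional-registration", {
        grid <- parcel(fmask, config$scheme)
        register_regions(fixed, moving, global, grid,
                         config$registration, fixed_mask = fmask)
      })
      if (!is.null(rg)) {
        report$regional <- lapply(rg, regional_result_to_json)
        summ <- tryCatch(regional_summary(rg), error = function(e) NULL)
        if (!is.null(summ))
          utils::write.csv(summ, file.path(config$out_dir, "regional.csv"),
                           row.names = FALSE)
      }
    }

    if (config$overlays) {
      qc <- stage("qc-overlays", {
        aligned <- resample_volume(moving, global, fixed)
        edge_overlay(fixed, aligned,
                     file.path(config$out_dir, "overlay"))
      })
      if (!is.null(qc)) report$qc_images <- qc$files
    }
  }

  report$ok <- length(report$errors) == 0L
  class(report) <- "run_report"
  jsonlite::write_json(report_to_json(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

distance_stats_to_json <- function(ds) {
  out <- unclass(ds)
  out$distances <- as.list(out$distances)
  out$outliers <- as.list(out$outliers)
  if (!is.null(out$per_axis_voxel))
    out$per_axis_voxel <- as.data.frame(out$per_axis_voxel)
  out
}

regional_result_to_json <- function(r) {
  if (isTRUE(r$excluded))
    return(list(label = r$label, excluded = TRUE, reason = r$reason))
  list(label = r$label, excluded = FALSE,
       local_rowmajor = as.numeric(t(r$local)),
       total_rowmajor = as.numeric(t(r$total)),
       report = unclass(r$report), improved = r$improved,
       cost_global_in_region = r$cost_global_in_region,
       cost_total_in_region = r$cost_total_in_region,
       strategy = r$strategy)
}

report_to_json <- function(report) {
  r <- unclass(report)
  if (!is.null(r$decomposition))
    r$decomposition <- lapply(r$decomposition, as.numeric)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", if (isTRUE(x$ok)) "ok" else "with errors", "\n")
  if (!is.null(x$decomposition)) {
    cat("  global max_scale_dev ", signif(x$decomposition$max_scale_dev, 4),
        ", max_skew ", signif(x$decomposition$max_skew, 4),
        ", volume_dev ", signif(x$decomposition$volume_dev, 4), "\n",
        sep = "")
  }
  if (!is.null(x$landmarks))
    cat("  landmark mean distance ", signif(x$landmarks$mean, 4), " mm\n",
        sep = "")
  if (length(x$errors))
    cat("  errors in:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
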