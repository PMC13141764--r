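#' Geometry pipeline configuration
#'
#' Bundles the tunable parameters of the boundary-shape measurement pipeline.
#'
#' @param angular_window Degrees of accepted outward-normal directions around
#'   the medial hint (default 90).
#' @param resample_n Points for equal-arc-length resampling before FD
#'   rasterization and curvature estimation (default 501).
#' @param scales Box sizes in px for [box_counting_fd()]; `NULL` = dyadic
#'   default.
#' @param offsets Grid phases averaged in the FD estimate (default 4).
#' @param fd_seed Seed for the FD grid phases (default 1).
#' @param smoothing Spline smoothing parameter for [estimate_curvature()]
#'   (`NULL` = default rule).
#' @param n_samples Curvature evaluation points (default 200).
#' @returns A named list of class `boundary_config`.
#' @export
boundary_config <- function(angular_window = 90, resample_n = 501,
                            scales = NULL, offsets = 4, fd_seed = 1L,
                            smoothing = NULL, n_samples = 200) {
  structure(
    list(
      angular_window = angular_window, resample_n = resample_n,
      scales = scales, offsets = offsets, fd_seed = fd_seed,
      smoothing = smoothing, n_samples = n_samples
    ),
    class = "boundary_config"
  )
}

#' Measure the boundary shape of one tumor mask
#'
#' Runs the full single-tumor geometry pipeline: extract the medial boundary
#' arc, resample it at equal arc length, estimate the box-counting fractal
#' dimension and classify the boundary as linear (L) or curved (C). The five
#' curvature descriptors (total, maximum and average curvature, curvature
#' variation, tortuosity) are computed only for curved boundaries; for linear
#' boundaries they are reported as `NA`, matching a workflow in which the
#' curvature suite is run only on curved shapes.
#'
#' @param mask A [mask_slice()].
#' @param config A [boundary_config()].
#' @returns A one-row `geometry_report` tibble with columns `fd`,
#'   `fd_replicates` (list column), `shape_label`, `total_curvature`,
#'   `max_curvature`, `average_curvature`, `curvature_variation`,
#'   `tortuosity`; the extracted arc and the config are attached as
#'   attributes.
#' @export
measure_boundary <- function(mask, config = boundary_config()) {
  stopifnot(inherits(mask, "mask_slice"))
  arc <- with_stage("extract", extract_medial_boundary(mask, config$angular_window))
  arc <- with_stage("resample", resample_arclength(arc, config$resample_n))
  fd_out <- with_stage("fd", box_counting_fd(
    arc,
    scales = config$scales, offsets = config$offsets,
    spacing = min(mask$spacing), resample_n = config$resample_n,
    seed = config$fd_seed
  ))
  label <- classify_shape(fd_out$fd)
  if (label == "C") {
    prof <- with_stage("curvature", estimate_curvature(
      arc,
      smoothing = config$smoothing, n_samples = config$n_samples
    ))
    tc <- total_curvature(prof)
    mc <- max_curvature(prof)
    ac <- average_curvature(prof)
    cvr <- curvature_variation(prof)
    tort <- tortuosity(arc)
  } else {
    tc <- mc <- ac <- cvr <- tort <- NA_real_
  }
  out <- tibble(
    fd = fd_out$fd,
    fd_replicates = list(fd_out$replicates),
    shape_label = label,
    total_curvature = tc,
    max_curvature = mc,
    average_curvature = ac,
    curvature_variation = cvr,
    tortuosity = tort
  )
  structure(out,
    class = c("geometry_report", class(out)),
    arc = arc, config = config
  )
}

# Re-raise errors with the pipeline stage prepended, keeping the condition
# class (so callers can still match on the error code).
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("[stage ", stage, "] ", conditionMessage(e)),
      class = class(e)[1], parent = e
    )
  })
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf(
    "<geometry_report: FD %.4f -> %s boundary>\n", x$fd,
    if (x$shape_label == "L") "linear (L)" else "curved (C)"
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.geometry_report <- function(x, ...) {
  tibble(
    descriptor = c(
      "fd", "total_curvature", "max_curvature", "average_curvature",
      "curvature_variation", "tortuosity"
    ),
    value = c(
      x$fd, x$total_curvature, x$max_curvature, x$average_curvature,
      x$curvature_variation, x$tortuosity
    ),
    unit = c("unitless", "radians", "1/mm", "1/mm", "1/mm^2", "unitless")
  )
}
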