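#' Read a single-slice binary mask from a NIfTI volume or image array
#'
#' Accepts a NIfTI file (2D, or 3D with `slice_index`), or an R matrix.
#' Pixel spacing is read from the NIfTI header and can be overridden.
#' Non-binary data are refused unless an explicit `threshold` is given
#' (foreground = value >= threshold).
#'
#' @param path File path to a NIfTI image, or a numeric matrix.
#' @param slice_index 1-based axial slice to extract from a 3D volume.
#' @param spacing Optional length-2 override of the (row, col) pixel size in
#'   mm.
#' @param medial_hint Medial direction passed to [mask_slice()].
#' @param threshold Optional binarization threshold for non-binary data.
#' @returns A [mask_slice()].
#' @export
read_mask <- function(path, slice_index = NULL, spacing = NULL,
                      medial_hint = c(1, 0), threshold = NULL) {
  if (is.matrix(path)) {
    img <- path
    hdr_spacing <- c(1, 1)
  } else {
    if (!file.exists(path)) gs_abort("missing-file", paste0("No such file: ", path))
    vol <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(vol)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3) {
      if (is.null(slice_index)) gs_abort("missing-slice", "3D volume needs `slice_index`.")
      if (slice_index < 1 || slice_index > dim(arr)[3]) {
        gs_abort("slice-out-of-range", sprintf(
          "slice_index %d outside 1..%d.", slice_index, dim(arr)[3]
        ))
      }
      img <- arr[, , slice_index]
      hdr_spacing <- pd[1:2]
    } else if (length(dim(arr)) == 2) {
      img <- arr
      hdr_spacing <- pd[1:2]
    } else {
      gs_abort("bad-image", "Expected a 2D or 3D image.")
    }
  }
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1))) {
    if (is.null(threshold)) {
      gs_abort("non-binary", "Image is not binary; pass an explicit `threshold`.")
    }
    img <- (img >= threshold) * 1
  }
  mask_slice(as.matrix(img),
    spacing = spacing %||% hdr_spacing,
    medial_hint = medial_hint
  )
}

#' Write / read a geometry report as JSON
#'
#' Reports are serialized with sorted keys and pretty printing so reruns
#' diff cleanly.
#'
#' @param report A `geometry_report` from [measure_boundary()].
#' @param path Output file.
#' @returns `path`, invisibly (writer); a one-row tibble (reader).
#' @export
write_geometry_report <- function(report, path) {
  cfg <- attr(report, "config")
  payload <- list(
    fd = report$fd,
    fd_replicates = report$fd_replicates[[1]],
    shape_label = report$shape_label,
    total_curvature = report$total_curvature,
    max_curvature = report$max_curvature,
    average_curvature = report$average_curvature,
    curvature_variation = report$curvature_variation,
    tortuosity = report$tortuosity,
    config = cfg[!vapply(cfg, is.null, logical(1))]
  )
  payload <- payload[order(names(payload))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_report
#' @export
read_geometry_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(
    fd = x$fd, fd_replicates = list(x$fd_replicates), shape_label = x$shape_label,
    total_curvature = x$total_curvature %||% NA_real_,
    max_curvature = x$max_curvature %||% NA_real_,
    average_curvature = x$average_curvature %||% NA_real_,
    curvature_variation = x$curvature_variation %||% NA_real_,
    tortuosity = x$tortuosity %||% NA_real_
  )
}

#' Run the full boundary-to-prognosis workflow on a cohort
#'
#' Composes the pipeline stages: optional per-patient geometry measurement
#' from masks (labels merged into the cohort by `id`), the univariate
#' association table, the subgroup risk models (the published Risk_L score
#' on linear-boundary patients, Risk_C on curved), points-scale threshold
#' search, and internal validation (bootstrap optimism-corrected C and
#' k-fold cross-validated C / ICI / E50).
#'
#' @param cohort Cohort tibble (see [make_cohort()] for the layout).
#' @param masks Optional named list of [mask_slice()] objects; names are
#'   patient ids.
#' @param config [boundary_config()] for the geometry stage.
#' @param B Bootstrap replicates for validation (default 200).
#' @param k Cross-validation folds (default 5).
#' @param horizon Calibration horizon in months (default 36).
#' @param seed Seed for all resampling stages.
#' @param out_dir Optional directory; when given, the association table and
#'   per-subgroup summaries are written as CSV/JSON named with the config
#'   hash.
#' @returns List with `geometry`, `cohort`, `association`, `models` (one
#'   entry per subgroup with scores, threshold, validation and cv reports),
#'   and `manifest`.
#' @export
run_pipeline <- function(cohort, masks = NULL, config = boundary_config(),
                         B = 200, k = 5, horizon = 36, seed = 1L,
                         out_dir = NULL) {
  cohort <- tibble::as_tibble(cohort)
  geometry <- NULL
  if (!is.null(masks)) {
    geometry <- purrr::imap_dfr(masks, function(m, id) {
      dplyr::mutate(measure_boundary(m, config), id = id, .before = 1)
    })
    cohort <- dplyr::rows_update(cohort,
      dplyr::select(geometry, "id", "shape_label"),
      by = "id", unmatched = "ignore"
    )
  }
  association <- associate_shape(cohort)
  models <- list(L = risk_model_L(), C = risk_model_C())
  fitted <- purrr::imap(models, function(model, lab) {
    sub <- dplyr::filter(cohort, .data$shape_label == lab)
    if (nrow(sub) < 20 || sum(sub$event) < 5) {
      return(list(skipped = TRUE, n = nrow(sub)))
    }
    coded <- code_covariates(sub, model)
    scored <- risk_points(risk_score(sub, model), model)
    thr <- threshold_search(scored, scored$points)
    dat <- dplyr::bind_cols(
      dplyr::select(sub, "pfs_months", "event"),
      coded
    )
    list(
      model = model,
      scores = dplyr::select(scored, "id", "risk_score", "points"),
      threshold = thr,
      validation = bootstrap_validate(dat, names(model$coefficients), B = B, seed = seed),
      cv = crossvalidate(dat, names(model$coefficients),
        k = k,
        horizon = min(horizon, max(dat$pfs_months) * 0.9), seed = seed
      )
    )
  })
  manifest <- list(
    n = nrow(cohort),
    n_by_shape = as.list(table(cohort$shape_label)),
    n_masks = length(masks),
    seed = seed, B = B, k = k, horizon = horizon,
    config_hash = rlang::hash(list(config, B, k, horizon, seed))
  )
  out <- list(
    geometry = geometry, cohort = cohort, association = association,
    models = fitted, manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- substr(manifest$config_hash, 1, 8)
    utils::write.csv(association,
      file.path(out_dir, paste0("association-", tag, ".csv")),
      row.names = FALSE
    )
    summary <- purrr::map(fitted, function(f) {
      if (isTRUE(f$skipped)) {
        return(list(skipped = TRUE, n = f$n))
      }
      list(
        model = f$model$name,
        coefficients = as.list(f$model$coefficients),
        threshold = f$threshold,
        corrected_c = f$validation$corrected_c,
        cv_mean_c = f$cv$mean_c, ici = f$cv$ici, e50 = f$cv$e50
      )
    })
    jsonlite::write_json(
      c(list(manifest = manifest), summary),
      file.path(out_dir, paste0("models-", tag, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  out
}
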