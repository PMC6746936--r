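# End-to-end per-patient analysis and cohort driver.
#
# femur_fe() is the package's central fitting function: it takes one
# patient's image bundle and returns a classed object holding the
# calibration line, plate model, impact force, FE solution and Risk of
# Fracture field, with print/summary/plot methods. run_pipeline() maps it
# over a cohort and adds the percentile classification and HSA ranking.

#' Estimate the femoral neck width from the segmentation
#'
#' Brute-force minimum-width scan: neck-ROI pixels are projected onto the
#' ROI's principal axis, grouped into one-pixel axial bins, and the minimum
#' perpendicular extent over the central bins is returned. Used as a
#' fallback when no HSA neck width is available.
#'
#' @param femur_mask logical matrix
#' @param neck_roi logical matrix selecting the neck ROI
#' @param spacing_mm pixel spacing
#' @return neck width in mm
#' @export
neck_width_from_mask <- function(femur_mask, neck_roi, spacing_mm) {
  sel <- femur_mask & neck_roi
  if (!any(sel)) stop("empty neck ROI")
  ax <- principal_axis(sel, spacing_mm)
  idx <- which(sel, arr.ind = TRUE)
  cc <- pixel_centers(dim(sel), spacing_mm)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  t_ax <- pts %*% ax
  perp <- pts %*% c(-ax[2], ax[1])
  bin <- round((t_ax - min(t_ax)) / spacing_mm)
  w <- tapply(perp, bin, function(p) max(p) - min(p) + spacing_mm)
  inner <- w[seq_along(w) > 1 & seq_along(w) < length(w)]
  if (!length(inner)) inner <- w
  min(inner)
}

as_patient_bundle <- function(phantom, id, metadata_row) {
  structure(list(image = phantom$image, femur_mask = phantom$femur_mask,
                 roi = phantom$roi, regions = phantom$regions,
                 roi_means = phantom$truth$roi_mean_bmd,
                 metadata = list(patient_id = id,
                                 spacing_mm = phantom$image$spacing_mm,
                                 height_m = metadata_row$height_m,
                                 weight_kg = metadata_row$weight_kg,
                                 tscore = metadata_row$tscore)),
            class = "patient_bundle")
}

#' Fit the DXA finite-element fracture-risk model for one patient
#'
#' Runs the full chain: per-ROI gray-to-BMD calibration averaged into one
#' patient line, pixel-wise BMD map, plate thickness from the neck width,
#' pixel-aligned plane-stress mesh with binned density-derived moduli,
#' spring-mass-damper impact force, sideways-fall solve, and the per-element
#' Risk of Fracture with its patient-wise maximum RF^ outside the head and
#' trochanteric regions.
#'
#' @param bundle a `patient_bundle` ([read_patient()]) with non-NULL
#'   `regions`
#' @param config a [pipeline_config()]
#' @param hsa_row optional named vector/1-row data.frame with the patient's
#'   HSA values; `NN_W` supplies the neck width (otherwise estimated from
#'   the mask via [neck_width_from_mask()])
#' @return object of class `femur_fe`
#' @export
femur_fe <- function(bundle, config = pipeline_config(), hsa_row = NULL) {
  stopifnot(inherits(bundle, "patient_bundle"))
  if (is.null(bundle$regions))
    stop("bundle lacks a 'regions' label image (required for boundary conditions)")
  img <- bundle$image
  spacing <- img$spacing_mm

  roi_ids <- c(neck = 1L, trochanter = 2L, intertrochanter = 3L)
  lines <- lapply(names(roi_ids), function(nm) {
    calibrate_single_roi(
      img,
      roi_measurement(nm, bundle$roi == roi_ids[[nm]],
                      bundle$roi_means[[nm]]),
      fraction_f = config$calibration$fraction_f)
  })
  line <- combine_rois(lines)
  bmd <- apply_calibration(img, line, bundle$femur_mask)

  neck_w <- if (!is.null(hsa_row) && "NN_W" %in% names(hsa_row))
    as.numeric(hsa_row[["NN_W"]])
  else neck_width_from_mask(bundle$femur_mask, bundle$roi == 1L, spacing)
  thickness <- plate_thickness(neck_w, config$thickness$method)

  mesh <- build_mesh(bundle$femur_mask, spacing,
                     config$mesh$element_size_mm, thickness)
  mat <- material_field(mesh, bmd, n_bins = config$material$n_bins,
                        ash_fraction = config$material$ash_fraction,
                        nu = config$material$nu,
                        e_min = config$material$e_min)

  imp <- impact_parameters(
    body_height_H = bundle$metadata$height_m,
    body_mass_M = bundle$metadata$weight_kg,
    effective_mass_fraction = config$impact$effective_mass_fraction,
    fall_height_fraction = config$impact$fall_height_fraction,
    contact_stiffness_k = config$impact$contact_stiffness_k,
    damping_ratio_zeta = config$impact$damping_ratio_zeta,
    gravity_g = config$impact$gravity_g)
  f_imp <- impact_force(imp)
  load <- load_case(f_imp, config$bc$force_angle_deg,
                    config$bc$head_spring_total, config$bc$arc_fraction)

  sol <- assemble_and_solve(mesh, mat, load, bundle$regions)

  crit <- fracture_criterion(config$risk$tensile_limit_et,
                             config$risk$compressive_limit_ec,
                             config$risk$prevailing_rule)
  rf <- element_rf(sol$principal[, 1], sol$principal[, 2], crit)
  rf_hat <- extract_rf_hat(rf, sol$elem_region)

  fext <- sol$f_ext_total
  rtot <- sol$reactions$springs + sol$reactions$hinge
  eq_res <- sqrt(sum((fext + rtot)^2)) / sqrt(sum(fext^2))

  structure(list(patient_id = bundle$metadata$patient_id,
                 calibration = line, bmd_map = bmd,
                 neck_width_mm = neck_w, thickness_mm = thickness,
                 mesh = mesh, materials = mat,
                 impact_force_N = f_imp, load = load, solution = sol,
                 criterion = crit, rf = rf, rf_hat = rf_hat,
                 equilibrium_residual = eq_res,
                 tscore = bundle$metadata$tscore,
                 config = config),
            class = "femur_fe")
}

#' @export
print.femur_fe <- function(x, ...) {
  cat(sprintf("femur_fe model%s\n",
              if (!is.null(x$patient_id)) paste0(" [", x$patient_id, "]") else ""))
  cat(sprintf("  calibration: aBMD = %.4g + %.4g * gray (f = %.2f)\n",
              x$calibration$intercept, x$calibration$slope,
              x$calibration$fraction))
  cat(sprintf("  plate thickness: %.2f mm (neck width %.1f mm)\n",
              x$thickness_mm, x$neck_width_mm))
  cat(sprintf("  impact force: %.0f N; mesh: %d elements (%.3g mm)\n",
              x$impact_force_N, nrow(x$mesh$elems), x$mesh$elem_size_mm))
  cat(sprintf("  RF^ = %.4f (%s), equilibrium residual %.1e\n",
              x$rf_hat$value, x$rf_hat$location_label,
              x$equilibrium_residual))
  invisible(x)
}

#' @export
summary.femur_fe <- function(object, ...) {
  print(object)
  cat(sprintf("  E range: %.3g - %.3g MPa in %d bins (%d distinct)\n",
              min(object$materials$e), max(object$materials$e),
              object$materials$n_bins, length(unique(object$materials$e))))
  cat(sprintf("  principal strains: e1 max %.3e, e3 min %.3e\n",
              max(object$solution$principal[, 1]),
              min(object$solution$principal[, 2])))
  cat(sprintf("  RF quantiles: median %.3f, P90 %.3f, max %.3f\n",
              stats::median(object$rf),
              stats::quantile(object$rf, 0.9, names = FALSE), max(object$rf)))
  invisible(object)
}

#' Plot the Risk-of-Fracture field of a fitted patient model
#'
#' Rasterises the per-element RF back onto the image grid. By default only
#' values above the model's own 90th RF percentile are shown (the usual
#' contour-map convention); lower values are drawn as background.
#'
#' @param x a `femur_fe` object
#' @param floor_quantile RF display floor as a quantile of the patient's RF
#'   (default 0.90; use 0 to show everything)
#' @param ... passed to [graphics::image()]
#' @export
plot.femur_fe <- function(x, floor_quantile = 0.90, ...) {
  mesh <- x$mesh
  img <- matrix(NA_real_, mesh$dim_img[1], mesh$dim_img[2])
  rf_show <- x$rf
  if (floor_quantile > 0) {
    fl <- stats::quantile(rf_show, floor_quantile, names = FALSE)
    rf_show[rf_show < fl] <- NA_real_
  }
  img[mesh$elem_pixel] <- rf_show
  graphics::image(t(img[nrow(img):1, ]), useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = sprintf("RF field%s (RF^ = %.3f)",
                                 if (!is.null(x$patient_id))
                                   paste0(" ", x$patient_id) else "",
                                 x$rf_hat$value), ...)
  invisible(x)
}

#' Run the cohort pipeline
#'
#' Fits [femur_fe()] for every patient, pools the per-element RF of the
#' whole cohort for the percentile thresholds, classifies patients
#' (RF^ > 99.9th percentile or RF^ >= 1), ranks the HSA variables against
#' RF^, and optionally writes per-patient JSON reports, the cohort CSV, the
#' ranking CSV and legacy-VTK field exports. A failing patient is skipped
#' with a warning; the cohort run continues.
#'
#' @param input a cohort directory path (layout of [write_cohort()]) or a
#'   `femur_cohort` object from [generate_cohort()]
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for reports and exports
#' @return object of class `cohort_result`: `table` (per-patient data.frame),
#'   `classification` ([cohort_classify()] result), `ranking`
#'   (`hsa_ranking` or NULL), `fits` (list of `femur_fe`), `config`
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  if (is.character(input)) {
    pdirs <- sort(list.dirs(input, recursive = FALSE))
    if (!length(pdirs)) stop(sprintf("no patient directories under '%s'", input))
    bundles <- lapply(pdirs, read_patient)
    names(bundles) <- basename(pdirs)
    hsa_path <- file.path(input, "hsa.csv")
    hsa <- if (file.exists(hsa_path))
      utils::read.csv(hsa_path, check.names = FALSE) else NULL
  } else if (inherits(input, "femur_cohort")) {
    ids <- names(input$patients)
    bundles <- lapply(seq_along(ids), function(i)
      as_patient_bundle(input$patients[[i]], ids[i], input$metadata[i, ]))
    names(bundles) <- ids
    hsa <- input$hsa
  } else stop("input must be a cohort directory or a femur_cohort object")

  fits <- list()
  for (id in names(bundles)) {
    row <- if (!is.null(hsa)) hsa[hsa$patient_id == id, , drop = FALSE] else NULL
    if (!is.null(row) && nrow(row) != 1L) row <- NULL
    fit <- tryCatch(femur_fe(bundles[[id]], config, hsa_row = row),
                    error = function(e) {
                      warning(sprintf("patient %s failed: %s; skipped",
                                      id, conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) fits[[id]] <- fit
  }
  if (!length(fits)) stop("no patient could be processed")

  pooled <- unlist(lapply(fits, `[[`, "rf"), use.names = FALSE)
  rf_hats <- vapply(fits, function(f) f$rf_hat$value, numeric(1))
  cls <- cohort_classify(pooled, rf_hats)

  table <- data.frame(
    patient_id = names(fits),
    rf_hat = rf_hats,
    location = vapply(fits, function(f) f$rf_hat$location_label, character(1)),
    tscore = vapply(fits, function(f)
      if (is.null(f$tscore)) NA_real_ else f$tscore, numeric(1)),
    impact_force_N = vapply(fits, `[[`, numeric(1), "impact_force_N"),
    at_risk = cls$at_risk,
    row.names = NULL)

  ranking <- NULL
  if (!is.null(hsa) && nrow(table) >= 3L) {
    dat <- merge(table[, c("patient_id", "rf_hat")], hsa, by = "patient_id")
    dat$patient_id <- NULL
    ranking <- tryCatch(
      rank_hsa(rf_hat ~ ., dat, vif_threshold = config$stats$vif_threshold,
               aicc = config$stats$aicc),
      error = function(e) {
        warning("HSA ranking failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }

  res <- structure(list(table = table, classification = cls,
                        ranking = ranking, fits = fits, config = config),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_result(res, out_dir)
  res
}

write_cohort_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$fits)) {
    f <- res$fits[[id]]
    rep <- list(
      patient_id = id,
      calibration = list(intercept_g_cm2 = f$calibration$intercept,
                         slope_g_cm2_per_gray = f$calibration$slope,
                         fraction = f$calibration$fraction),
      neck_width_mm = f$neck_width_mm,
      plate_thickness_mm = f$thickness_mm,
      impact_force_N = f$impact_force_N,
      n_elements = nrow(f$mesh$elems),
      rf_hat = f$rf_hat$value,
      rf_hat_location = f$rf_hat$location_label,
      equilibrium_residual = f$equilibrium_residual,
      at_risk = unname(res$classification$at_risk[id]))
    write_json_file(rep, file.path(out_dir, paste0(id, "_report.json")))
    if (isTRUE(f$config$output$write_vtk)) {
      write_vtk(f$mesh, file.path(out_dir, paste0(id, "_fields.vtk")),
                cell_data = list(E_MPa = f$materials$e,
                                 rho_app = f$materials$rho_app,
                                 bin_id = as.numeric(f$materials$bin_id),
                                 RF = f$rf))
    }
  }
  utils::write.csv(res$table, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_json_file(list(thresholds = as.list(res$classification$thresholds),
                       n_at_risk = res$classification$n_at_risk,
                       n_patients = length(res$classification$at_risk)),
                  file.path(out_dir, "cohort_summary.json"))
  if (!is.null(res$ranking))
    utils::write.csv(res$ranking$ranking$variables,
                     file.path(out_dir, "ranking.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort pipeline result: %d patients\n", nrow(x$table)))
  print(x$classification)
  if (!is.null(x$ranking)) {
    cat("top HSA variables by cumulative Akaike weight:\n")
    print(utils::head(x$ranking$ranking$variables, 5), row.names = FALSE)
  }
  invisible(x)
}
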