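# Readers and writers for the pipeline's on-disk layout.
#
# Cohort directory layout (all plain formats):
#   <dir>/hsa.csv            patient_id + 20 HSA columns
#   <dir>/patients.csv       patient_id, height_m, weight_kg, tscore
#   <dir>/truth.json         phantom ground truth (synthesis lines, drivers)
#   <dir>/<patient_id>/
#     image.tif              16-bit grayscale DXA-like image
#     femur_mask.tif         binary segmentation
#     roi_labels.tif         0 none, 1 neck, 2 trochanter, 3 intertrochanter
#     regions.tif            1 head, 2 neck, 3 trochanter, 4 intertroch, 5 shaft
#     meta.json              patient_id, spacing_mm, height_m, weight_kg, tscore
#     roi_means.json         mean areal BMD per ROI (g/cm^2)

GRAY_MAX <- 65535

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a phantom cohort to disk in the pipeline input layout
#'
#' @param cohort a `femur_cohort` from [generate_cohort()]
#' @param dir output directory (created if missing)
#' @param write_images write the per-patient TIFF images and masks
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, write_images = TRUE) {
  stopifnot(inherits(cohort, "femur_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$hsa, file.path(dir, "hsa.csv"), row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  truth_out <- list(
    patients = lapply(cohort$truth$patients, function(tr) list(
      gray_to_bmd_line = tr$gray_to_bmd_line,
      roi_mean_bmd = as.list(tr$roi_mean_bmd),
      hsa_row = as.list(tr$hsa_row),
      params = unclass(tr$params))),
    drivers = cohort$truth$drivers,
    rf_hat_true = cohort$truth$rf_hat_true)
  names(truth_out$patients) <- names(cohort$patients)
  write_json_file(truth_out, file.path(dir, "truth.json"))
  if (write_images) {
    ids <- names(cohort$patients)
    for (i in seq_along(ids)) {
      pdir <- file.path(dir, ids[i])
      dir.create(pdir, showWarnings = FALSE)
      ph <- cohort$patients[[i]]
      md <- cohort$metadata[i, ]
      write_patient(ph, pdir, id = ids[i], height_m = md$height_m,
                    weight_kg = md$weight_kg, tscore = md$tscore)
    }
  }
  invisible(dir)
}

#' Write one phantom patient directory
#'
#' @param phantom a `femur_phantom`
#' @param dir patient directory
#' @param id patient identifier
#' @param height_m,weight_kg,tscore patient metadata
#' @return `dir`, invisibly
#' @export
write_patient <- function(phantom, dir, id, height_m, weight_kg, tscore) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- pmin(phantom$image$pixels / GRAY_MAX, 1)
  tiff::writeTIFF(pix, file.path(dir, "image.tif"), bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(phantom$femur_mask * 1, file.path(dir, "femur_mask.tif"),
                  bits.per.sample = 8L, compression = "none")
  tiff::writeTIFF(phantom$roi / 255, file.path(dir, "roi_labels.tif"),
                  bits.per.sample = 8L, compression = "none")
  tiff::writeTIFF(phantom$regions / 255, file.path(dir, "regions.tif"),
                  bits.per.sample = 8L, compression = "none")
  write_json_file(list(patient_id = id,
                       spacing_mm = phantom$image$spacing_mm,
                       height_m = height_m, weight_kg = weight_kg,
                       tscore = tscore),
                  file.path(dir, "meta.json"))
  write_json_file(as.list(phantom$truth$roi_mean_bmd),
                  file.path(dir, "roi_means.json"))
  invisible(dir)
}

read_label_tiff <- function(path, max_val = 255) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * max_val)), nrow(m), ncol(m))
}

#' Read a patient directory into a validated bundle
#'
#' @param dir patient directory following the documented layout
#' @return object of class `patient_bundle`: `image` ([gray_image]),
#'   `femur_mask`, `roi`, `regions` (or NULL), `roi_means` (named numeric),
#'   `metadata` (list)
#' @export
read_patient <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("patient directory '%s' does not exist", dir))
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing file '%s' in %s", f, dir))
    p
  }
  img_path <- file.path(dir, "image.tif")
  if (!file.exists(img_path)) img_path <- file.path(dir, "image.png")
  if (!file.exists(img_path))
    stop(sprintf("missing file 'image.tif' (or 'image.png') in %s", dir))

  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop(sprintf(paste0("missing 'meta.json' in %s: pixel spacing is ",
                        "required (provide spacing_mm)"), dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$spacing_mm))
    stop(sprintf("meta.json in %s lacks 'spacing_mm'", dir))
  if (!is.null(meta$patient_id) && meta$patient_id != basename(dir))
    stop(sprintf("inconsistent ids: directory '%s' vs meta.json '%s'",
                 basename(dir), meta$patient_id))

  if (grepl("\\.png$", img_path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the 'png' package")
    m <- png::readPNG(img_path)
  } else {
    m <- tiff::readTIFF(img_path)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  img <- gray_image(round(m * GRAY_MAX), meta$spacing_mm)

  mask <- read_label_tiff(need("femur_mask.tif"), 255) > 127
  roi <- read_label_tiff(need("roi_labels.tif"))
  regions_path <- file.path(dir, "regions.tif")
  regions <- if (file.exists(regions_path)) read_label_tiff(regions_path) else NULL

  rm_path <- need("roi_means.json")
  roi_means <- unlist(jsonlite::read_json(rm_path, simplifyVector = TRUE))
  missing_roi <- setdiff(c("neck", "trochanter", "intertrochanter"),
                         names(roi_means))
  if (length(missing_roi))
    stop(sprintf("roi_means.json in %s lacks ROI(s): %s", dir,
                 paste(missing_roi, collapse = ", ")))

  structure(list(image = img, femur_mask = mask, roi = roi, regions = regions,
                 roi_means = roi_means, metadata = as.list(meta)),
            class = "patient_bundle")
}

#' Export a mesh with cell data as a legacy-VTK unstructured grid
#'
#' ASCII legacy VTK (readable by ParaView and friends); quadrilateral cells,
#' z = 0, one SCALARS block per entry of `cell_data`.
#'
#' @param mesh a `planar_mesh`
#' @param path output file path (conventionally `.vtk`)
#' @param cell_data named list of per-element numeric vectors
#' @return `path`, invisibly
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  np <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "femrisk planar mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", np)), con)
  writeLines(sprintf("%.6f %.6f 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  e0 <- mesh$elems - 1L
  writeLines(sprintf("4 %d %d %d %d", e0[, 1], e0[, 2], e0[, 3], e0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (length(v) != ne) stop(sprintf("cell_data '%s' has wrong length", nm))
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.8g", v), con)
    }
  }
  invisible(path)
}
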