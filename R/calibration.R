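# Gray-level -> areal-BMD calibration. DXA software reports mean areal BMD
# only inside three regions of interest (neck, trochanter, intertrochanter);
# a per-pixel BMD map is recovered by postulating a linear relation between
# pixel gray level and BMD. Per ROI, the intercept is set to a fraction f of
# the ROI mean BMD (the assumed minimum BMD in the region) and the slope is
# fixed by requiring the mean non-zero gray of the ROI to map exactly onto
# the reported mean BMD; the three per-ROI lines are then averaged into one
# patient-specific relation.

#' Gray-level image with physical pixel spacing
#'
#' @param pixels numeric matrix of non-negative gray values; background must
#'   be encoded as exactly 0
#' @param spacing_mm pixel spacing in mm (> 0)
#' @return object of class `gray_image`
#' @export
gray_image <- function(pixels, spacing_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(pixels < 0, na.rm = TRUE)) stop("gray values must be >= 0")
  stopifnot_scalar_num(spacing_mm, "spacing_mm", positive = TRUE)
  structure(list(pixels = pixels, spacing_mm = spacing_mm),
            class = "gray_image")
}

#' Per-ROI DXA measurement
#'
#' @param name one of `"neck"`, `"trochanter"`, `"intertrochanter"` (or
#'   `"whole"` for a single-region calibration)
#' @param mask logical matrix selecting the ROI pixels
#' @param mean_abmd mean areal BMD of the ROI in g/cm^2 (> 0)
#' @return object of class `roi_measurement`
#' @export
roi_measurement <- function(name, mask, mean_abmd) {
  name <- match.arg(name, c("neck", "trochanter", "intertrochanter", "whole"))
  if (!is.logical(mask) || !any(mask)) stop("ROI mask must select >= 1 pixel")
  stopifnot_scalar_num(mean_abmd, "mean_abmd", positive = TRUE)
  structure(list(name = name, mask = mask, mean_abmd = mean_abmd),
            class = "roi_measurement")
}

new_calibration_line <- function(intercept, slope, fraction) {
  structure(list(intercept = intercept, slope = slope, fraction = fraction),
            class = "calibration_line")
}

#' Calibrate the gray-to-BMD line on a single ROI
#'
#' The line is anchored at two points: gray 0 maps to `fraction_f` times the
#' ROI mean BMD (the assumed minimum), and the mean of the non-zero gray
#' values in the ROI maps exactly to the reported mean BMD.
#'
#' @param image a [gray_image()]
#' @param roi a [roi_measurement()]
#' @param fraction_f minimum-BMD fraction in `[0, 1)`; 0.20 is the default
#'   (the trial fraction that validates best against 3D reference models),
#'   with 0.10-0.30 the usual trial range
#' @return a `calibration_line` with fields `intercept` (g/cm^2), `slope`
#'   (g/cm^2 per gray unit) and `fraction`
#' @export
calibrate_single_roi <- function(image, roi, fraction_f = 0.20) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "roi_measurement"))
  if (fraction_f < 0 || fraction_f >= 1) stop("fraction_f must lie in [0, 1)")
  if (!identical(dim(roi$mask), dim(image$pixels)))
    stop("ROI mask and image dimensions differ")
  g <- image$pixels[roi$mask]
  g <- g[g > 0]
  if (!length(g)) stop("all ROI gray values are zero: slope undefined")
  g_bar <- mean(g)
  intercept <- fraction_f * roi$mean_abmd
  slope <- roi$mean_abmd * (1 - fraction_f) / g_bar
  new_calibration_line(intercept, slope, fraction_f)
}

#' Average per-ROI calibration lines into one patient-specific relation
#'
#' @param lines list of three `calibration_line` objects fitted with the same
#'   minimum-BMD fraction
#' @return a `calibration_line` with the arithmetic-mean intercept and slope
#' @export
combine_rois <- function(lines) {
  if (!is.list(lines) || length(lines) != 3L ||
      !all(vapply(lines, inherits, logical(1), "calibration_line")))
    stop("combine_rois expects a list of exactly three calibration lines")
  f <- vapply(lines, `[[`, numeric(1), "fraction")
  if (max(f) - min(f) > 1e-12)
    stop("calibration lines use different minimum-BMD fractions")
  new_calibration_line(mean(vapply(lines, `[[`, numeric(1), "intercept")),
                       mean(vapply(lines, `[[`, numeric(1), "slope")),
                       f[1])
}

#' Apply a calibration line pixel-wise to obtain an areal-BMD map
#'
#' @param image a [gray_image()]
#' @param line a `calibration_line`
#' @param femur_mask logical matrix selecting foreground (bone) pixels
#' @return object of class `bmd_map`: list with `abmd` (matrix, g/cm^2 on the
#'   foreground, `NA` on background, clamped below at 0) and `spacing_mm`
#' @export
apply_calibration <- function(image, line, femur_mask) {
  stopifnot(inherits(image, "gray_image"), inherits(line, "calibration_line"))
  if (!is.logical(femur_mask) || !identical(dim(femur_mask), dim(image$pixels)))
    stop("femur_mask must be a logical matrix matching the image")
  a <- matrix(NA_real_, nrow(image$pixels), ncol(image$pixels))
  a[femur_mask] <- pmax(line$intercept + line$slope * image$pixels[femur_mask], 0)
  structure(list(abmd = a, spacing_mm = image$spacing_mm), class = "bmd_map")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(paste0("gray-to-BMD calibration line (f = %.2f):\n",
                     "  aBMD [g/cm^2] = %.6g + %.6g * gray\n"),
              x$fraction, x$intercept, x$slope))
  invisible(x)
}
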