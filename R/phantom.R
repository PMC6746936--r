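# Synthetic femur phantom: parametric proximal-femur silhouettes with a known
# per-pixel areal-BMD ground truth, DXA-like gray images, ROI label masks, HSA
# geometry tables and patient metadata. Every downstream stage of the package
# is testable against the truth bundle emitted here.

#' Femur shape parameters for the phantom generator
#'
#' The silhouette is a union of primitives: a vertical shaft rectangle, an
#' inclined neck corridor (capsule), a femoral-head disc and a greater
#' trochanter bulge. All lengths in mm; the image frame has the head up and
#' the medial side on the left.
#'
#' @param neck_shaft_angle_deg angle between neck and shaft axes, degrees
#'   (90-160; typical adult values 120-135)
#' @param neck_width_mm femoral neck width (capsule diameter)
#' @param hip_axis_length_mm distance along the neck axis from the lateral
#'   trochanteric surface to the far edge of the head
#' @param head_radius_mm femoral head radius
#' @param shaft_width_mm shaft (diaphysis) width
#' @param image_spacing_mm pixel spacing of the synthesized image
#' @return an object of class `femur_shape_params`
#' @export
femur_shape_params <- function(neck_shaft_angle_deg = 125,
                               neck_width_mm = 33,
                               hip_axis_length_mm = 105,
                               head_radius_mm = 24,
                               shaft_width_mm = 30,
                               image_spacing_mm = 0.5) {
  stopifnot_scalar_num(neck_shaft_angle_deg, "neck_shaft_angle_deg")
  if (neck_shaft_angle_deg < 90 || neck_shaft_angle_deg > 160)
    stop("neck_shaft_angle_deg must lie in [90, 160]")
  for (nm in c("neck_width_mm", "hip_axis_length_mm", "head_radius_mm",
               "shaft_width_mm", "image_spacing_mm"))
    stopifnot_scalar_num(get(nm), nm, positive = TRUE)
  if (neck_width_mm >= 2 * head_radius_mm)
    stop(sprintf(paste0("degenerate geometry: neck_width_mm (%g) must be ",
                        "smaller than the head diameter (%g)"),
                 neck_width_mm, 2 * head_radius_mm))
  p <- list(neck_shaft_angle_deg = neck_shaft_angle_deg,
            neck_width_mm = neck_width_mm,
            hip_axis_length_mm = hip_axis_length_mm,
            head_radius_mm = head_radius_mm,
            shaft_width_mm = shaft_width_mm,
            image_spacing_mm = image_spacing_mm)
  class(p) <- "femur_shape_params"
  invisible(phantom_geometry(p))   # rejects infeasible layouts at construction
  p
}

# Geometric layout shared by rasterisation and HSA derivation. All in y-up mm
# with the canvas left edge at x = 0 and the distal shaft cut at y = 0.
phantom_geometry <- function(params) {
  nsa <- params$neck_shaft_angle_deg
  nw <- params$neck_width_mm
  hal <- params$hip_axis_length_mm
  hr <- params$head_radius_mm
  sw <- params$shaft_width_mm
  phi <- (nsa - 90) * pi / 180
  d <- c(-cos(phi), sin(phi))              # neck axis, base -> head
  y_nb <- 40                               # neck-base height above distal cut
  x_c <- 0                                 # shaft axis (translated later)
  x_R <- x_c + sw / 2                      # lateral shaft edge
  s_lat <- (sw / 2) / cos(phi)             # P0 -> lateral edge along -d
  L <- hal - hr - s_lat                    # neck-axis length base -> head center
  if (L <= hr)
    stop(sprintf(paste0("degenerate geometry: hip_axis_length_mm (%g) too ",
                        "short for head radius and shaft width"), hal))
  P0 <- c(x_c, y_nb)
  C <- P0 + L * d
  r_gt <- 0.55 * sw
  gt_c <- c(x_R - 0.3 * r_gt, y_nb + 0.45 * sw)
  y_top <- gt_c[2]                         # shaft rectangle top (GT continues)
  margin <- 4
  x_min <- min(C[1] - hr, x_c - sw / 2) - margin
  x_max <- max(x_R + r_gt * 0.8, C[1] + hr) + margin
  y_max <- max(C[2] + hr, gt_c[2] + r_gt) + margin
  shift <- -x_min
  list(phi = phi, d = d, L = L, y_nb = y_nb,
       P0 = P0 + c(shift, 0), C = C + c(shift, 0),
       x_c = x_c + shift, x_R = x_R + shift,
       gt_c = gt_c + c(shift, 0), r_gt = r_gt, y_top = y_top,
       width = x_max - x_min, height = y_max)
}

#' Generate a synthetic DXA-like femur image with known ground truth
#'
#' Rasterises the parametric silhouette, lays a smooth regional areal-BMD
#' field over it, and synthesizes gray levels through an exact affine
#' gray-to-BMD relation (recorded in the truth bundle) plus optional additive
#' Gaussian noise truncated at zero. Background pixels are exactly 0.
#'
#' @param params a [femur_shape_params()] object
#' @param bmd_profile `"regional"` (default), `"uniform"`, or a
#'   `function(x, y, region)` returning areal BMD in g/cm^2
#' @param bmd_level overall areal-BMD scale in g/cm^2 (regional weights
#'   multiply it)
#' @param noise_sd standard deviation of additive Gaussian gray noise
#'   (gray units; truncated at 0)
#' @param seed optional integer seed for the noise
#' @param gray_intercept_fraction fraction of the femur-mean BMD used as the
#'   synthesis line intercept (the gray value 0 maps to this BMD)
#' @param notch_depth_mm if positive, a semicircular notch of this depth is
#'   machined into the superior mid-neck edge (stress concentrator for
#'   placement checks)
#' @param cortical_factors named multipliers (`nn`, `it`, `fs`) on the
#'   regional cortical thickness entering the HSA section quantities;
#'   independent per-patient variation of cortical geometry
#' @param shape_factors named multipliers (`nn`, `it`, `fs`) on the regional
#'   cross-sectional moment of inertia (section shape variation not captured
#'   by width and cortical thickness)
#' @param it_width_factor multiplier on the intertrochanteric width
#'   (independent trochanteric flare variation)
#' @return a list of class `femur_phantom` with elements `image`
#'   ([gray_image]), `femur_mask` (logical matrix), `roi` (integer matrix:
#'   0 none, 1 neck, 2 trochanter, 3 intertrochanter), `regions` (integer
#'   matrix: 1 head, 2 neck, 3 trochanter, 4 intertrochanter, 5 shaft) and
#'   `truth` (true BMD map, ROI means, HSA row, synthesis line, params)
#' @export
generate_femur_image <- function(params,
                                 bmd_profile = "regional",
                                 bmd_level = 0.85,
                                 noise_sd = 0,
                                 seed = NULL,
                                 gray_intercept_fraction = 0.20,
                                 notch_depth_mm = 0,
                                 cortical_factors = c(nn = 1, it = 1, fs = 1),
                                 shape_factors = c(nn = 1, it = 1, fs = 1),
                                 it_width_factor = 1) {
  stopifnot(inherits(params, "femur_shape_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gray_intercept_fraction < 0 || gray_intercept_fraction >= 1)
    stop("gray_intercept_fraction must lie in [0, 1)")
  g <- phantom_geometry(params)
  sp <- params$image_spacing_mm
  nc <- ceiling(g$width / sp)
  nr <- ceiling(g$height / sp)
  cc <- pixel_centers(c(nr, nc), sp)
  X <- matrix(cc$x, nr, nc, byrow = TRUE)
  Y <- matrix(cc$y, nr, nc)

  in_shaft <- X >= g$x_c - params$shaft_width_mm / 2 &
    X <= g$x_R & Y >= 0 & Y <= g$y_top
  # distance to the neck axis segment P0 -> C
  px <- X - g$P0[1]; py <- Y - g$P0[2]
  t_ax <- pmin(pmax(px * g$d[1] + py * g$d[2], 0), g$L)
  dist2 <- (px - t_ax * g$d[1])^2 + (py - t_ax * g$d[2])^2
  in_neck <- dist2 <= (params$neck_width_mm / 2)^2
  in_head <- (X - g$C[1])^2 + (Y - g$C[2])^2 <= params$head_radius_mm^2
  in_gt <- (X - g$gt_c[1])^2 + (Y - g$gt_c[2])^2 <= g$r_gt^2
  mask <- in_shaft | in_neck | in_head | in_gt

  if (notch_depth_mm > 0) {
    n_sup <- c(sin(g$phi), cos(g$phi))     # superior neck edge normal
    mid <- g$P0 + 0.5 * g$L * g$d + (params$neck_width_mm / 2) * n_sup
    notch <- (X - mid[1])^2 + (Y - mid[2])^2 <= notch_depth_mm^2
    mask <- mask & !notch
  }

  # disjoint anatomical regions, priority head > neck > trochanter > intertroch;
  # the proximal 30% of the neck corridor belongs to the intertrochanteric zone.
  # The trochanteric region carries a 2.5 mm margin beyond the bulge so that
  # the re-entrant junction corners (where the load-patch boundary conditions
  # pollute the solution) fall inside the excluded zone.
  in_gt_margin <- (X - g$gt_c[1])^2 + (Y - g$gt_c[2])^2 <= (g$r_gt + 2.5)^2
  regions <- matrix(0L, nr, nc)
  regions[mask & in_head] <- 1L
  regions[mask & in_neck & t_ax >= 0.3 * g$L & regions == 0L] <- 2L
  regions[mask & in_gt_margin & regions == 0L] <- 3L
  it_band <- (Y >= g$y_nb - 0.4 * params$shaft_width_mm & Y <= g$y_top) | in_neck
  regions[mask & it_band & regions == 0L] <- 4L
  regions[mask & regions == 0L] <- 5L

  # DXA-style ROI labels: mid-neck band, greater trochanter, intertroch band
  roi <- matrix(0L, nr, nc)
  roi[mask & in_neck & !in_head & t_ax >= 0.35 * g$L & t_ax <= 0.70 * g$L] <- 1L
  roi[mask & regions == 3L] <- 2L
  roi[mask & regions == 4L] <- 3L

  region_w <- c(1.05, 0.95, 0.85, 1.05, 1.25)  # head neck troch intertroch shaft
  a <- matrix(NA_real_, nr, nc)
  fg <- which(mask)
  if (identical(bmd_profile, "regional")) {
    a[fg] <- bmd_level * region_w[regions[fg]] *
      (1 - 0.08 * Y[fg] / g$height) *
      (1 + 0.05 * sin(X[fg] / 7) * sin(Y[fg] / 9))
  } else if (identical(bmd_profile, "uniform")) {
    a[fg] <- bmd_level
  } else if (is.function(bmd_profile)) {
    a[fg] <- bmd_profile(X[fg], Y[fg], regions[fg])
    if (any(!is.finite(a[fg])) || any(a[fg] <= 0))
      stop("bmd_profile function must return finite positive BMD values")
  } else stop("bmd_profile must be 'regional', 'uniform' or a function")

  # exact affine synthesis line: gray = (aBMD - intercept) / slope
  b_int <- gray_intercept_fraction * mean(a[fg])
  if (min(a[fg]) <= b_int)
    stop("BMD profile too flat/low for the requested intercept fraction")
  m_slope <- (max(a[fg]) - b_int) / 45000
  pix <- matrix(0, nr, nc)
  pix[fg] <- (a[fg] - b_int) / m_slope
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pix[fg] <- pmax(pix[fg] + stats::rnorm(length(fg), 0, noise_sd), 0)
  }

  roi_names <- c("neck", "trochanter", "intertrochanter")
  roi_mean <- vapply(1:3, function(k) mean(a[roi == k]), numeric(1))
  names(roi_mean) <- roi_names

  out <- list(
    image = gray_image(pix, sp),
    femur_mask = mask,
    roi = roi,
    regions = regions,
    truth = list(
      true_bmd_map = a,
      roi_mean_bmd = roi_mean,
      hsa_row = phantom_hsa_row(params, g, mask, regions, a, sp,
                                cortical_factors, shape_factors,
                                it_width_factor),
      gray_to_bmd_line = list(intercept = b_int, slope = m_slope,
                              fraction = gray_intercept_fraction),
      params = params
    )
  )
  class(out) <- "femur_phantom"
  out
}

# Synthetic HSA row: NSA and HAL come from the shape parameters; the narrow
# neck (NN), intertrochanteric (IT) and femoral-shaft (FS) cross-section
# quantities use an annulus model with three quasi-independent latents per
# region, mirroring how the real estimates are derived from partly
# independent features of the mass profile: the width, a cortical thickness
# (weakly tied to regional BMD, with an independent per-region factor), and
# a section shape factor entering the second moment. ED, CSA and SM are pure
# derived quantities of those latents, as in the measured tables, where
# collinearity screening typically discards them. CSMI in mm^4, CSA in mm^2,
# widths in mm.
phantom_hsa_row <- function(params, g, mask, regions, a, sp,
                            cortical_factors = c(nn = 1, it = 1, fs = 1),
                            shape_factors = c(nn = 1, it = 1, fs = 1),
                            it_width_factor = 1) {
  # intertrochanteric width along the region bisector: scales with the shaft
  # and the trochanteric bulge (1.25 x shaft width for this silhouette, with
  # independent flare variation), not with the neck inclination
  it_w <- 1.25 * params$shaft_width_mm * it_width_factor

  section <- function(w, abmd, cf, qf) {
    t_c <- min(1.65 * sqrt(abmd / 0.85) * cf, 0.45 * w)
    ed <- w - 2 * t_c
    csmi <- pi / 64 * (w^4 - ed^4) * qf
    c(W = w, BR = (w / 2) / t_c, ED = ed,
      CSA = pi / 4 * (w^2 - ed^2), CSMI = csmi, SM = csmi / (w / 2))
  }
  nn <- section(params$neck_width_mm, mean(a[regions == 2L]),
                cortical_factors[["nn"]], shape_factors[["nn"]])
  it <- section(it_w, mean(a[regions == 4L]),
                cortical_factors[["it"]], shape_factors[["it"]])
  fs <- section(params$shaft_width_mm, mean(a[regions == 5L]),
                cortical_factors[["fs"]], shape_factors[["fs"]])
  out <- c(NSA = params$neck_shaft_angle_deg,
           HAL = params$hip_axis_length_mm,
           stats::setNames(nn, paste0("NN_", names(nn))),
           stats::setNames(it, paste0("IT_", names(it))),
           stats::setNames(fs, paste0("FS_", names(fs))))
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient shape and density parameters from realistic
#' post-menopausal distributions, generates each phantom, assembles the HSA
#' table and patient metadata, and (optionally) writes everything to disk in
#' the pipeline's input layout. When `effect_spec` is supplied, a synthetic
#' risk response driven by the named HSA variables is recorded in the truth
#' bundle for parameter-recovery studies.
#'
#' @param n number of patients (>= 3)
#' @param effect_spec optional list with `coefficients` (named numeric vector
#'   of effects on z-scored HSA columns) and `noise_sd` (SD of the additive
#'   Gaussian noise on the same z scale); drives `truth$rf_hat_true`
#' @param seed integer seed governing all randomness
#' @param dir optional output directory; when given, per-patient
#'   subdirectories plus `hsa.csv`, `patients.csv` and `truth.json` are written
#' @param spacing_mm image pixel spacing
#' @param noise_sd gray-noise SD passed to [generate_femur_image()]
#' @param write_images write image/mask TIFFs (set `FALSE` for statistics-only
#'   cohorts; requires `dir = NULL`)
#' @return invisibly, a list of class `femur_cohort`: `patients` (list of
#'   phantoms), `hsa` (data.frame), `metadata` (data.frame), `truth` (list:
#'   per-patient truth bundles, drivers, `rf_hat_true` when `effect_spec`
#'   given), `dir`
#' @export
generate_cohort <- function(n, effect_spec = NULL, seed = 1, dir = NULL,
                            spacing_mm = 0.5, noise_sd = 250,
                            write_images = TRUE) {
  if (n < 3) stop("n < 3: cohort statistics undefined")
  set.seed(seed)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  nsa <- clip(stats::rnorm(n, 125, 5.5), 106, 144)
  nw <- clip(stats::rnorm(n, 33, 3), 25, 42)
  hr <- clip(stats::rnorm(n, 24, 2), 19, 30)
  nw <- pmin(nw, 2 * hr - 4)
  hal <- clip(stats::rnorm(n, 105, 6), 88, 125)
  sw <- clip(stats::rnorm(n, 30, 2.5), 23, 38)
  bmd <- clip(stats::rnorm(n, 0.80, 0.13), 0.45, 1.15)
  height <- clip(stats::rnorm(n, 1.61, 0.065), 1.42, 1.82)
  weight <- clip(stats::rnorm(n, 66, 11), 40, 105)
  # independent cortical-geometry and section-shape variation per patient
  # and region
  cortf <- matrix(exp(stats::rnorm(3 * n, 0, 0.2)), n, 3,
                  dimnames = list(NULL, c("nn", "it", "fs")))
  shapef <- matrix(exp(stats::rnorm(3 * n, 0, 0.2)), n, 3,
                   dimnames = list(NULL, c("nn", "it", "fs")))
  itwf <- exp(stats::rnorm(n, 0, 0.08))
  pat_seed <- sample.int(2^31 - 2, n)

  ids <- sprintf("P%02d", seq_len(n))
  patients <- vector("list", n)
  hsa <- NULL
  tscore <- numeric(n)
  for (i in seq_len(n)) {
    p <- femur_shape_params(nsa[i], nw[i], hal[i], hr[i], sw[i], spacing_mm)
    ph <- generate_femur_image(p, bmd_level = bmd[i], noise_sd = noise_sd,
                               seed = pat_seed[i],
                               cortical_factors = cortf[i, ],
                               shape_factors = shapef[i, ],
                               it_width_factor = itwf[i])
    patients[[i]] <- ph
    hsa <- rbind(hsa, ph$truth$hsa_row)
    # femoral-neck T-score against a young-adult reference (0.849 +/- 0.111)
    tscore[i] <- (ph$truth$roi_mean_bmd[["neck"]] - 0.849) / 0.111
  }
  hsa <- as.data.frame(hsa)
  # HSA measurement/model error by variable class, mirroring the precision
  # ordering of the estimates: 1 deg on NSA, ~2% on direct length
  # measurements (widths, HAL), ~4% on CSMI and ~6% on the buckling ratio
  # (worst reported precision; depends on the modelled cortical shell).
  # ED, CSA and SM are computed from the same profile as the rest of the
  # table and are internally consistent to ~0.5% -- they are the redundant
  # derived columns that collinearity screening exists to discard.
  set.seed(pat_seed[n] %% (2^31 - 2))
  hsa$NSA <- hsa$NSA + stats::rnorm(n, 0, 1)
  for (cn in setdiff(names(hsa), "NSA")) {
    rel <- if (cn %in% c("HAL", "NN_W", "IT_W", "FS_W")) 0.02
    else if (grepl("_BR$", cn)) 0.10
    else if (grepl("_CSMI$", cn)) 0.04
    else if (grepl("_CSA$", cn)) 0.02
    else 0.003
    hsa[[cn]] <- hsa[[cn]] * (1 + stats::rnorm(n, 0, rel))
  }
  hsa <- cbind(patient_id = ids, hsa)

  metadata <- data.frame(patient_id = ids, height_m = height,
                         weight_kg = weight, tscore = tscore)

  truth <- list(patients = lapply(patients, `[[`, "truth"))
  if (!is.null(effect_spec)) {
    if (is.null(effect_spec$coefficients) || is.null(names(effect_spec$coefficients)))
      stop("effect_spec$coefficients must be a named numeric vector")
    bad <- setdiff(names(effect_spec$coefficients), names(hsa))
    if (length(bad)) stop("effect_spec names not in HSA table: ",
                          paste(bad, collapse = ", "))
    nsd <- if (is.null(effect_spec$noise_sd)) 1.155 else effect_spec$noise_sd
    lp <- rep(0, n)
    for (v in names(effect_spec$coefficients))
      lp <- lp + effect_spec$coefficients[[v]] * as.numeric(scale(hsa[[v]]))
    truth$drivers <- names(effect_spec$coefficients)[effect_spec$coefficients != 0]
    truth$effect_spec <- effect_spec
    truth$rf_hat_true <- 0.65 + 0.18 * (lp + stats::rnorm(n, 0, nsd))
  }

  out <- list(patients = stats::setNames(patients, ids), hsa = hsa,
              metadata = metadata, truth = truth, dir = dir)
  class(out) <- "femur_cohort"
  if (!is.null(dir)) write_cohort(out, dir, write_images = write_images)
  invisible(out)
}
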