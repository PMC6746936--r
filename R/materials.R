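# Density chain: areal BMD -> volumetric density (divide by plate thickness)
# -> apparent density (divide by the ash fraction) -> Young's modulus through
# the piecewise density-modulus power law, then grouped into at most 35 bins,
# each element receiving the median raw modulus of its bin.

#' Piecewise density-to-modulus power law
#'
#' E = c_low * rho^p_low for rho <= rho_switch, c_high * rho^p_high above.
#' Defaults are the pooled-site empirical constants for trabecular/cortical
#' bone (E in MPa, apparent density in g/cm^3).
#'
#' @param c_low,p_low low-density branch coefficient (MPa) and exponent
#' @param c_high,p_high high-density branch coefficient and exponent
#' @param rho_switch branch-switch apparent density in g/cm^3 (low branch
#'   applies at the boundary)
#' @return object of class `morgan_law`
#' @export
morgan_law <- function(c_low = 15010, p_low = 2.18,
                       c_high = 6850, p_high = 1.49,
                       rho_switch = 0.28) {
  structure(list(c_low = c_low, p_low = p_low, c_high = c_high,
                 p_high = p_high, rho_switch = rho_switch),
            class = "morgan_law")
}

#' Areal to volumetric bone density
#'
#' @param abmd areal BMD in g/cm^2 (vectorised)
#' @param thickness_t plate thickness in mm
#' @return volumetric density in g/cm^3
#' @export
abmd_to_volumetric <- function(abmd, thickness_t) {
  stopifnot_scalar_num(thickness_t, "thickness_t", positive = TRUE)
  abmd / (thickness_t / 10)
}

#' Volumetric to apparent (wet tissue) density
#'
#' @param rho_vol volumetric density in g/cm^3 (vectorised)
#' @param ash_fraction mineral (ash) mass fraction of apparent density, in
#'   (0, 1]; the conventional value 0.6 is the default
#' @return apparent density in g/cm^3
#' @export
volumetric_to_apparent <- function(rho_vol, ash_fraction = 0.6) {
  if (ash_fraction <= 0 || ash_fraction > 1)
    stop("ash_fraction must lie in (0, 1]")
  rho_vol / ash_fraction
}

#' Young's modulus from apparent density
#'
#' @param rho_app apparent density in g/cm^3 (vectorised, >= 0)
#' @param law a [morgan_law()]
#' @return Young's modulus in MPa
#' @export
morgan_modulus <- function(rho_app, law = morgan_law()) {
  if (any(rho_app < 0, na.rm = TRUE)) stop("apparent density must be >= 0")
  ifelse(rho_app <= law$rho_switch,
         law$c_low * rho_app^law$p_low,
         law$c_high * rho_app^law$p_high)
}

#' Bin element moduli into at most n_bins discrete values
#'
#' Bins are equal-width in E over the observed per-model range, left-open
#' (values exactly on an interior edge fall into the lower bin); each element
#' is assigned the median raw modulus of the elements sharing its bin.
#'
#' @param e_raw numeric vector of per-element raw moduli (MPa)
#' @param n_bins number of bins (default 35)
#' @return list with `e` (binned moduli), `bin_id` (integer in 1..n_bins)
#'   and `bin_width`
#' @export
bin_moduli <- function(e_raw, n_bins = 35L) {
  if (!length(e_raw)) stop("no elements to bin")
  if (any(!is.finite(e_raw))) stop("non-finite moduli")
  lo <- min(e_raw); hi <- max(e_raw)
  if (hi == lo)
    return(list(e = e_raw, bin_id = rep(1L, length(e_raw)), bin_width = 0))
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin_id <- findInterval(e_raw, breaks, left.open = TRUE, all.inside = TRUE)
  med <- tapply(e_raw, bin_id, stats::median)
  list(e = as.numeric(med[as.character(bin_id)]),
       bin_id = as.integer(bin_id),
       bin_width = (hi - lo) / n_bins)
}

#' Per-element material field from a BMD map
#'
#' Runs the full density chain for every mesh element using the element's
#' source pixel, then bins the moduli. A small positive floor keeps the
#' stiffness matrix positive definite where the mapped BMD is (numerically)
#' zero.
#'
#' @param mesh a [build_mesh()] result
#' @param bmd_map an [apply_calibration()] result
#' @param law a [morgan_law()]
#' @param n_bins number of modulus bins (default 35)
#' @param ash_fraction see [volumetric_to_apparent()]
#' @param nu Poisson ratio (uniform; default 0.3)
#' @param e_min modulus floor in MPa (default 1)
#' @return object of class `material_field`: `e` (binned MPa), `e_raw`,
#'   `rho_app`, `bin_id`, `nu`, `n_bins`, `bin_width`
#' @export
material_field <- function(mesh, bmd_map, law = morgan_law(), n_bins = 35L,
                           ash_fraction = 0.6, nu = 0.3, e_min = 1) {
  stopifnot(inherits(mesh, "planar_mesh"), inherits(bmd_map, "bmd_map"))
  abmd <- elem_pixel_values(mesh, bmd_map$abmd)
  if (any(is.na(abmd)))
    stop("some elements map to background pixels with undefined BMD")
  rho_app <- volumetric_to_apparent(
    abmd_to_volumetric(abmd, mesh$thickness_t), ash_fraction)
  e_raw <- pmax(morgan_modulus(rho_app, law), e_min)
  b <- bin_moduli(e_raw, n_bins)
  structure(list(e = pmax(b$e, e_min), e_raw = e_raw, rho_app = rho_app,
                 bin_id = b$bin_id, nu = nu, n_bins = as.integer(n_bins),
                 bin_width = b$bin_width),
            class = "material_field")
}
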