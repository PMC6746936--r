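# Layered pipeline configuration: every tunable of the analysis chain with
# its documented default; unknown sections or keys are rejected so typos
# cannot silently fall back to defaults.

pipeline_defaults <- function() {
  list(
    calibration = list(fraction_f = 0.20),
    mesh = list(element_size_mm = 0.5),
    thickness = list(method = "mean"),
    material = list(n_bins = 35L, ash_fraction = 0.6, nu = 0.3, e_min = 1),
    impact = list(effective_mass_fraction = 0.5, fall_height_fraction = 0.51,
                  contact_stiffness_k = 5e4, damping_ratio_zeta = 0,
                  gravity_g = 9.81),
    bc = list(force_angle_deg = 30, head_spring_total = 10000,
              arc_fraction = 0.35),
    risk = list(tensile_limit_et = 0.0073, compressive_limit_ec = 0.0104,
                prevailing_rule = "max_ratio"),
    stats = list(vif_threshold = 10, aicc = FALSE),
    output = list(write_vtk = TRUE)
  )
}

#' Pipeline configuration
#'
#' Returns the default configuration, optionally overridden section by
#' section, e.g. `pipeline_config(calibration = list(fraction_f = 0.25))`.
#' Unknown sections or keys raise an error.
#'
#' @param ... named lists overriding individual keys of the named sections
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("configuration overrides must be named sections")
    for (sec in names(over)) {
      if (!sec %in% names(cfg)) stop(sprintf("unknown config section '%s'", sec))
      for (key in names(over[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop(sprintf("unknown config key '%s.%s'", sec, key))
        cfg[[sec]][[key]] <- over[[sec]][[key]]
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (calibration$fraction_f < 0 || calibration$fraction_f >= 1)
      stop("calibration.fraction_f must lie in [0, 1)")
    if (mesh$element_size_mm <= 0) stop("mesh.element_size_mm must be > 0")
    if (!thickness$method %in% c("mean", "area", "inertia"))
      stop("thickness.method must be one of mean/area/inertia")
    if (material$n_bins < 1) stop("material.n_bins must be >= 1")
    if (material$ash_fraction <= 0 || material$ash_fraction > 1)
      stop("material.ash_fraction must lie in (0, 1]")
    if (material$nu <= -1 || material$nu >= 0.5)
      stop("material.nu must lie in (-1, 0.5)")
    if (impact$damping_ratio_zeta < 0 || impact$damping_ratio_zeta >= 1)
      stop("impact.damping_ratio_zeta must lie in [0, 1)")
    if (bc$head_spring_total <= 0) stop("bc.head_spring_total must be > 0")
    if (bc$arc_fraction <= 0 || bc$arc_fraction > 1)
      stop("bc.arc_fraction must lie in (0, 1]")
    if (risk$tensile_limit_et <= 0 || risk$compressive_limit_ec <= 0)
      stop("risk strain limits must be > 0")
    if (!risk$prevailing_rule %in% c("max_ratio", "max_magnitude"))
      stop("risk.prevailing_rule must be max_ratio or max_magnitude")
    if (stats$vif_threshold <= 1) stop("stats.vif_threshold must be > 1")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  for (sec in names(x)) {
    kv <- vapply(names(x[[sec]]),
                 function(k) paste0(k, " = ", format(x[[sec]][[k]])),
                 character(1))
    cat(sprintf("  %s: %s\n", sec, paste(kv, collapse = ", ")))
  }
  invisible(x)
}
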