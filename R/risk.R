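# Principal-strain Risk of Fracture: per-element ratio of the prevailing
# principal strain to its material limit, the patient-wise maximum outside
# the head and trochanteric regions (RF^), and the cohort-percentile
# prognostic rule.

#' Principal-strain fracture criterion
#'
#' @param tensile_limit_et tensile yield strain (default 0.0073)
#' @param compressive_limit_ec compressive yield strain (default 0.0104)
#' @param prevailing_rule `"max_ratio"` (default; the larger of the tensile
#'   and compressive strain/limit ratios) or `"max_magnitude"` (the
#'   larger-magnitude principal strain divided by its own limit)
#' @return object of class `fracture_criterion`
#' @export
fracture_criterion <- function(tensile_limit_et = 0.0073,
                               compressive_limit_ec = 0.0104,
                               prevailing_rule = c("max_ratio", "max_magnitude")) {
  stopifnot_scalar_num(tensile_limit_et, "tensile_limit_et", positive = TRUE)
  stopifnot_scalar_num(compressive_limit_ec, "compressive_limit_ec", positive = TRUE)
  structure(list(tensile_limit_et = tensile_limit_et,
                 compressive_limit_ec = compressive_limit_ec,
                 prevailing_rule = match.arg(prevailing_rule)),
            class = "fracture_criterion")
}

#' Per-element Risk of Fracture from principal strains
#'
#' @param e1,e3 principal strains (vectorised), `e1 >= e3`
#' @param criterion a [fracture_criterion()]
#' @return dimensionless RF >= 0, same length as the inputs
#' @export
element_rf <- function(e1, e3, criterion = fracture_criterion()) {
  stopifnot(inherits(criterion, "fracture_criterion"))
  if (any(e1 < e3)) stop("principal strains must satisfy e1 >= e3")
  et <- criterion$tensile_limit_et
  ec <- criterion$compressive_limit_ec
  if (criterion$prevailing_rule == "max_ratio") {
    pmax(pmax(e1, 0) / et, pmax(-e3, 0) / ec)
  } else {
    prevail <- ifelse(abs(e1) >= abs(e3), e1, e3)
    ifelse(prevail > 0, prevail / et, -prevail / ec)
  }
}

#' Extract the patient RF^ outside the excluded regions
#'
#' The head and trochanteric regions are excluded because their strains are
#' polluted by the boundary conditions (grounding springs, load patch). Ties
#' resolve to the lowest element id.
#'
#' @param rf numeric vector of per-element RF values
#' @param elem_region integer vector of per-element anatomical labels
#'   (1 head, 2 neck, 3 trochanter, 4 intertrochanter, 5 shaft)
#' @param excluded_regions region labels ineligible for RF^ (default head
#'   and trochanter)
#' @return object of class `rf_hat`: `value`, `element_id`,
#'   `location_label` (`"intracapsular"` if the RF^ element lies in the neck
#'   region, `"extracapsular"` otherwise)
#' @export
extract_rf_hat <- function(rf, elem_region, excluded_regions = c(1L, 3L)) {
  if (length(rf) != length(elem_region))
    stop("rf and elem_region lengths differ")
  eligible <- which(!(elem_region %in% excluded_regions))
  if (!length(eligible)) stop("all elements excluded: RF^ undefined")
  i <- eligible[which.max(rf[eligible])]
  structure(list(value = rf[i], element_id = i,
                 location_label = if (elem_region[i] == 2L)
                   "intracapsular" else "extracapsular"),
            class = "rf_hat")
}

#' Cohort-level prognostic classification
#'
#' Computes the 90th, 98th and 99.9th percentiles of the pooled per-element
#' RF of the whole cohort (linear interpolation between order statistics)
#' and flags a patient as at risk of fracture iff their RF^ exceeds the
#' 99.9th percentile or reaches 1.
#'
#' @param pooled_rf numeric vector: all per-element RF values of every
#'   patient in the cohort
#' @param rf_hat_per_patient numeric vector (optionally named) of per-patient
#'   RF^ values
#' @return object of class `cohort_classification`: `thresholds` (named:
#'   p90, p98, p999), `at_risk` (logical per patient), `rf_hat`, `n_at_risk`
#' @export
cohort_classify <- function(pooled_rf, rf_hat_per_patient) {
  if (!length(pooled_rf)) stop("pooled RF set is empty")
  if (length(rf_hat_per_patient) < 2L)
    warning("fewer than 2 patients; thresholds computed on a degenerate cohort")
  thr <- stats::quantile(pooled_rf, c(0.90, 0.98, 0.999), names = FALSE,
                         type = 7)
  names(thr) <- c("p90", "p98", "p999")
  at_risk <- rf_hat_per_patient > thr[["p999"]] | rf_hat_per_patient >= 1
  structure(list(thresholds = thr, at_risk = at_risk,
                 rf_hat = rf_hat_per_patient,
                 n_at_risk = sum(at_risk)),
            class = "cohort_classification")
}

#' @export
print.rf_hat <- function(x, ...) {
  cat(sprintf("RF^ = %.4f at element %d (%s)\n",
              x$value, x$element_id, x$location_label))
  invisible(x)
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf(paste0("cohort RF percentiles: P90 = %.3f, P98 = %.3f, ",
                     "P99.9 = %.3f\n%d of %d patients at risk ",
                     "(RF^ > P99.9 or RF^ >= 1)\n"),
              x$thresholds[["p90"]], x$thresholds[["p98"]],
              x$thresholds[["p999"]], x$n_at_risk, length(x$at_risk)))
  invisible(x)
}
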