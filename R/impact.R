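# Patient-specific sideways-fall impact force from a single-degree-of-freedom
# spring-mass-damper model of the falling body hitting the ground on the
# greater trochanter.

#' Impact-model parameters
#'
#' The body falls from a height proportional to standing height; the impact
#' is modelled as a mass (a fraction of body mass) hitting a contact spring
#' (optionally damped) with the fall velocity. Defaults follow the common
#' sideways-fall convention: effective mass half the body mass, fall height
#' 0.51 of standing height, contact stiffness 5e4 N/m.
#'
#' @param body_height_H standing height in m
#' @param body_mass_M body mass in kg
#' @param effective_mass_fraction fraction of body mass participating in the
#'   impact (default 0.5)
#' @param fall_height_fraction fall height as a fraction of body height
#'   (default 0.51)
#' @param contact_stiffness_k trochanteric soft-tissue/ground contact
#'   stiffness in N/m (default 5e4)
#' @param damping_ratio_zeta damping ratio in `[0, 1)` (default 0)
#' @param gravity_g gravitational acceleration in m/s^2
#' @return object of class `impact_parameters`
#' @export
impact_parameters <- function(body_height_H, body_mass_M,
                              effective_mass_fraction = 0.5,
                              fall_height_fraction = 0.51,
                              contact_stiffness_k = 5e4,
                              damping_ratio_zeta = 0,
                              gravity_g = 9.81) {
  stopifnot_scalar_num(body_height_H, "body_height_H", positive = TRUE)
  stopifnot_scalar_num(body_mass_M, "body_mass_M", positive = TRUE)
  stopifnot_scalar_num(contact_stiffness_k, "contact_stiffness_k", positive = TRUE)
  if (effective_mass_fraction <= 0 || effective_mass_fraction > 1)
    stop("effective_mass_fraction must lie in (0, 1]")
  if (fall_height_fraction <= 0 || fall_height_fraction > 1)
    stop("fall_height_fraction must lie in (0, 1]")
  if (damping_ratio_zeta < 0 || damping_ratio_zeta >= 1)
    stop("damping_ratio_zeta must lie in [0, 1); the overdamped regime is out of scope")
  structure(list(body_height_H = body_height_H, body_mass_M = body_mass_M,
                 effective_mass_fraction = effective_mass_fraction,
                 fall_height_fraction = fall_height_fraction,
                 contact_stiffness_k = contact_stiffness_k,
                 damping_ratio_zeta = damping_ratio_zeta,
                 gravity_g = gravity_g),
            class = "impact_parameters")
}

#' Peak impact force of the 1-DOF fall model
#'
#' Impact velocity v = sqrt(2 g h H) with h the fall-height fraction. For
#' zero damping the peak spring force is v * sqrt(k * m_eff). For an
#' underdamped system (0 < zeta < 1) the closed-form peak of the spring force
#' k * x(t) with x(t) = (v/wd) exp(-zeta w t) sin(wd t) is evaluated at
#' t* = atan(sqrt(1 - zeta^2)/zeta) / wd.
#'
#' @param params an [impact_parameters()] object
#' @return peak impact force in N
#' @export
impact_force <- function(params) {
  stopifnot(inherits(params, "impact_parameters"))
  v <- sqrt(2 * params$gravity_g * params$fall_height_fraction *
              params$body_height_H)
  m_eff <- params$effective_mass_fraction * params$body_mass_M
  k <- params$contact_stiffness_k
  z <- params$damping_ratio_zeta
  if (z == 0) return(v * sqrt(k * m_eff))
  w <- sqrt(k / m_eff)
  wd <- w * sqrt(1 - z^2)
  t_star <- atan2(sqrt(1 - z^2), z) / wd
  k * (v / wd) * exp(-z * w * t_star) * sin(wd * t_star)
}
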