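# Cell-driven ECM microstructure updates. Orientation converges to the travel
# direction by sign-matched vector blending (monotone in angle); anisotropy
# and density follow scalar ODEs integrated exactly over the step, which
# removes dt-sensitivity and preserves the [0,1] bounds by construction.
# Anisotropy is modeled as stable-or-increasing only.

#' Construct an ECM element
#'
#' A convenience container for the per-element state; the orientation is
#' normalized and anisotropy/density clamped to `[0, 1]`.
#' @param orientation length-3 fiber orientation (sign is immaterial).
#' @param anisotropy,density scalars in `[0, 1]`.
#' @return list of class `ecm_element`.
#' @export
ecm_element <- function(orientation = c(1, 0, 0), anisotropy = 0,
                        density = 0.5) {
  n <- sqrt(sum(orientation^2))
  if (n < 1e-12) stop("orientation must be a non-zero vector")
  structure(list(orientation = orientation / n,
                 anisotropy = min(max(anisotropy, 0), 1),
                 density = min(max(density, 0), 1)),
            class = "ecm_element")
}

#' Instantaneous fiber remodeling
#'
#' The limit of infinitely fast remodeling: the element's orientation snaps
#' to the cell's direction of travel and its anisotropy saturates at 1.
#' Density is untouched. A stationary cell leaves the element unchanged.
#'
#' @param element an [ecm_element()].
#' @param v cell velocity (length 3, um/min).
#' @return the updated element.
#' @export
remodel_instant <- function(element, v) {
  sp <- sqrt(sum(v^2))
  if (sp == 0) return(element)
  element$orientation <- v / sp
  element$anisotropy <- 1
  element
}

#' Rate-limited fiber reorientation
#'
#' The cell's unit travel direction is first sign-matched to the current
#' orientation (`sign(0)` counts as +1), then blended in with weight
#' `k = min(1, r_f0 * |v| * dt / v_ref)` and the result renormalized. The
#' angle to the travel axis decreases monotonically, and `k = 1` reproduces
#' the instantaneous limit in a single step.
#'
#' @param element an [ecm_element()].
#' @param v cell velocity (um/min).
#' @param dt time step, min.
#' @param r_f0 reorientation rate, 1/min.
#' @param v_ref speed normalization, um/min (default 1), making the printed
#'   rates dimensionally usable as stated.
#' @return the updated element.
#' @export
remodel_orientation <- function(element, v, dt, r_f0, v_ref = .v_ref) {
  stopifnot(dt > 0)
  sp <- sqrt(sum(v^2))
  if (sp == 0 || r_f0 <= 0) return(element)
  vhat <- v / sp
  f <- element$orientation
  sgn <- if (sum(f * vhat) >= 0) 1 else -1
  k <- min(1, r_f0 * sp * dt / v_ref)
  fnew <- (1 - k) * f + k * sgn * vhat
  nn <- sqrt(sum(fnew^2))
  if (nn > 1e-12) element$orientation <- fnew / nn
  element
}

#' Anisotropy growth
#'
#' `da/dt = r_a0 * (|v| / v_ref) * (1 - a)`, integrated exactly:
#' `a <- 1 - (1 - a) * exp(-r_a0 * (|v|/v_ref) * dt)`. Anisotropy grows
#' proportionally to cell speed and never decreases.
#'
#' @param element an [ecm_element()].
#' @param speed cell speed `|v|`, um/min.
#' @param dt time step, min.
#' @param r_a0 realignment rate, 1/min.
#' @param v_ref speed normalization, um/min.
#' @return the updated element.
#' @export
remodel_anisotropy <- function(element, speed, dt, r_a0, v_ref = .v_ref) {
  stopifnot(dt > 0)
  element$anisotropy <-
    min(1, 1 - (1 - element$anisotropy) * exp(-r_a0 * (speed / v_ref) * dt))
  element
}

#' Density remodeling toward a target
#'
#' `drho/dt = r_rho * (rho_target - rho)`, integrated exactly; density moves
#' monotonically toward the target from either side, covering both deposition
#' (target above current density) and degradation (target below).
#'
#' @param element an [ecm_element()].
#' @param dt time step, min.
#' @param r_rho density remodeling rate, 1/min.
#' @param rho_target target density in `[0, 1]`.
#' @return the updated element.
#' @export
remodel_density <- function(element, dt, r_rho, rho_target) {
  stopifnot(dt > 0, rho_target >= 0, rho_target <= 1)
  element$density <- min(1, max(0,
    rho_target + (element$density - rho_target) * exp(-r_rho * dt)))
  element
}
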