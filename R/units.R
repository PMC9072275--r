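# Unit conversions and viewing geometry.
#
# The prism-diopter <-> degree mapping is deliberately LINEAR at 0.57 deg/PD,
# matching the conversion table printed for the study's Fresnel foil set
# (2 PD -> 1.14 deg, 10 PD -> 5.70 deg); the optical arctan(pd/100) form would
# give 1.146 and 5.71 instead.

#' Degrees of visual angle per prism diopter (linear convention)
#'
#' @format A numeric constant, 0.57 deg/PD.
#' @export
DEG_PER_PD <- 0.57

.check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric, got %s", name,
                 paste(utils::head(x, 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Convert prism diopters to degrees of visual angle
#'
#' Uses the linear convention of 0.57 degrees per prism diopter, so the
#' standard clinical foil set maps to 1 PD = 0.57, 2 PD = 1.14, 4 PD = 2.28,
#' 6 PD = 3.42, 8 PD = 4.56 and 10 PD = 5.70 degrees.
#'
#' @param pd Numeric vector of prism diopters (1 PD deflects light 1 cm at 1 m).
#' @return Numeric vector of degrees (positive = upward deflection).
#' @seealso [deg_to_pd()]
#' @examples
#' pd_to_deg(c(1, 2, 4, 6, 8, 10))
#' @export
pd_to_deg <- function(pd) {
  .check_finite_scalar(pd, "pd")
  pd * DEG_PER_PD
}

#' Convert degrees of visual angle to prism diopters
#'
#' Inverse of [pd_to_deg()]; exact round trip to machine precision.
#'
#' @param deg Numeric vector of degrees.
#' @return Numeric vector of prism diopters.
#' @export
deg_to_pd <- function(deg) {
  .check_finite_scalar(deg, "deg")
  deg / DEG_PER_PD
}

#' Visual angle subtended by a target
#'
#' Angle of a target of a given size viewed at a given distance,
#' `atan(size / distance)` expressed in degrees. A 4 mm fixation dot at
#' 260 mm subtends 0.881 degrees.
#'
#' @param size_mm Target size (mm), >= 0.
#' @param distance_mm Viewing distance (mm), > 0.
#' @return Visual angle in degrees.
#' @examples
#' visual_angle_deg(4, 260)
#' @export
visual_angle_deg <- function(size_mm, distance_mm) {
  .check_finite_scalar(size_mm, "size_mm")
  .check_finite_scalar(distance_mm, "distance_mm")
  if (any(distance_mm <= 0)) stop("`distance_mm` must be > 0", call. = FALSE)
  if (any(size_mm < 0)) stop("`size_mm` must be >= 0", call. = FALSE)
  atan(size_mm / distance_mm) * 180 / pi
}
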