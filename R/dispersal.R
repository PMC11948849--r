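#' Physical parameters for pollen dispersal
#'
#' Defaults are standard near-surface air at sea level and a measured
#' pollen density of 0.988 g cm^-3 (converted once to SI), with a
#' horizontal wind speed of 3 m/s.
#'
#' @param g gravitational acceleration, m s^-2.
#' @param rho_m air density, kg m^-3.
#' @param mu dynamic viscosity of air, Pa s.
#' @param rho_p pollen density, kg m^-3.
#' @param u_bar horizontal wind speed, m s^-1.
#' @param h_r pollen release height, m.
#' @return An object of class \code{dispersal_params}.
#' @export
dispersal_params <- function(g = 9.81, rho_m = 1.225, mu = 1.78e-5,
                             rho_p = 988, u_bar = 3, h_r = 1.5) {
  stopifnot(g > 0, rho_m > 0, mu > 0, rho_p > 0, u_bar > 0, h_r > 0)
  if (rho_p <= rho_m) stop("pollen density must exceed air density")
  structure(list(g = g, rho_m = rho_m, mu = mu, rho_p = rho_p,
                 u_bar = u_bar, h_r = h_r), class = "dispersal_params")
}

#' Stokes settling velocity of a pollen grain
#'
#' Terminal fall speed in still air under Stokes drag:
#' \code{V_set = g d^2 (rho_p - rho_m) / (18 mu)}. Valid for small
#' particles in the Stokes regime; no Reynolds-number correction is
#' applied.
#'
#' @param d pollen diameter in metres (vectorized).
#' @param params a \code{\link{dispersal_params}}.
#' @return settling velocity in m s^-1.
#' @export
settling_velocity <- function(d, params = dispersal_params()) {
  if (any(d <= 0)) stop("pollen diameter must be positive")
  params$g * d^2 * (params$rho_p - params$rho_m) / (18 * params$mu)
}

#' Ballistic pollen dispersal distance
#'
#' Horizontal distance travelled while falling from the release height at
#' constant wind speed: \code{D = h_r * u_bar / V_set(d)}.
#'
#' @param d pollen diameter in metres (vectorized).
#' @param params a \code{\link{dispersal_params}} (supplies \code{h_r} and
#'   \code{u_bar}).
#' @return dispersal distance in metres.
#' @export
dispersal_distance <- function(d, params = dispersal_params()) {
  params$h_r * params$u_bar / settling_velocity(d, params)
}

#' Dispersal-distance surface over diameter and release height
#'
#' Evaluates the ballistic distance on the Cartesian grid of pollen
#' diameters and release heights. Distances decrease along the diameter
#' axis and increase along the height axis.
#'
#' @param d_values pollen diameters in metres.
#' @param h_r_values release heights in metres.
#' @param params a \code{\link{dispersal_params}}.
#' @return matrix of distances (rows = diameters, cols = heights) with
#'   dimnames giving the grid values.
#' @export
distance_grid <- function(d_values, h_r_values,
                          params = dispersal_params()) {
  if (length(d_values) == 0L || length(h_r_values) == 0L) {
    stop("grid ranges must be non-empty")
  }
  v <- settling_velocity(d_values, params)
  out <- outer(1 / v, h_r_values * params$u_bar)
  dimnames(out) <- list(d = format(d_values, scientific = TRUE),
                        h_r = format(h_r_values))
  out
}
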