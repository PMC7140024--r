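#' Exponential decay rate of the fluid column
#'
#' Under Darcy flow through the sample and mass conservation between pipette
#' and sample chamber, the column height decays exponentially with rate
#' \deqn{r = K \frac{A_s}{A_p} \frac{\gamma}{\Delta x}}
#' where \eqn{K} is the permeability (mm^4/(N s)), \eqn{A_s/A_p} the
#' sample-to-pipette area ratio, \eqn{\gamma} the fluid specific weight
#' (N/mm^3) and \eqn{\Delta x} the sample thickness (mm).
#'
#' @param k Permeability coefficient in mm^4/(N s), `>= 0`.
#' @param geom A [device_geometry()].
#' @param fluid A [fluid_properties()].
#' @return Decay rate in 1/s; zero iff `k = 0`.
#' @examples
#' decay_rate(1000, device_geometry(), fluid_properties())
#' @export
decay_rate <- function(k, geom = device_geometry(), fluid = fluid_properties()) {
  check_permeability(k)
  stopifnot(inherits(geom, "device_geometry"), inherits(fluid, "fluid_properties"))
  k * (geom$sample_area_mm2 / geom$pipette_area_mm2) *
    fluid$specific_weight_N_mm3 / geom$sample_thickness_mm
}

#' Closed-form fluid column height over time
#'
#' The falling-head model: \eqn{H(t) = H(t_0)\, e^{-r (t - t_0)}} with the
#' rate \eqn{r} of [decay_rate()]. This is the analytic solution of the
#' continuity equation \eqn{A_p \, dH/dt = -Q(H)} with the Darcy flux
#' \eqn{Q(H)} of [darcy_flux()].
#'
#' @param t Time(s) of evaluation (s); vectorized.
#' @param t0 Start time of the filtration run (s).
#' @inheritParams decay_rate
#' @return Column height(s) in mm; strictly positive, equal to
#'   `geom$initial_height_mm` at `t = t0`, non-increasing in `t`.
#' @examples
#' column_height(c(0, 300, 600), t0 = 0, k = 1000)
#' @export
column_height <- function(t, t0 = 0, k = 0, geom = device_geometry(),
                          fluid = fluid_properties()) {
  if (any(t < t0)) stop("invalid-time-order: t must be >= t0", call. = FALSE)
  geom$initial_height_mm * exp(-decay_rate(k, geom, fluid) * (t - t0))
}

#' Darcy flux through the sample at a given column height
#'
#' \deqn{Q = K A_s \gamma H / \Delta x} in mm^3/s; linear in both the
#' height and the permeability.
#'
#' @param h Column height in mm, `>= 0`; vectorized.
#' @inheritParams decay_rate
#' @return Volumetric flux in mm^3/s.
#' @export
darcy_flux <- function(k, geom = device_geometry(), fluid = fluid_properties(),
                       h) {
  check_permeability(k)
  if (any(h < 0)) stop("invalid-height: h must be >= 0", call. = FALSE)
  k * geom$sample_area_mm2 * fluid$specific_weight_N_mm3 * h /
    geom$sample_thickness_mm
}

#' Pressure gradient across the sample
#'
#' The hydrostatic head \eqn{\gamma H} divided by the sample thickness,
#' reported in kPa/mm. With water (\eqn{\gamma} = 9.81 kN/m^3) and a 2 mm
#' sample, the 210 mm and 100 mm window endpoints give 1.03 and
#' 0.49 kPa/mm.
#'
#' @param h Column height in mm, `>= 0`; vectorized.
#' @param geom A [device_geometry()].
#' @param fluid A [fluid_properties()].
#' @return Pressure gradient in kPa/mm, linear in `h`.
#' @examples
#' pressure_gradient(c(210, 100))
#' @export
pressure_gradient <- function(h, geom = device_geometry(),
                              fluid = fluid_properties()) {
  if (any(h < 0)) stop("invalid-height: h must be >= 0", call. = FALSE)
  # gamma*h/dx is N/mm^3 = MPa/mm; x1000 -> kPa/mm
  fluid$specific_weight_N_mm3 * h / geom$sample_thickness_mm * 1000
}

#' Time at which the column reaches a target height
#'
#' Analytic inverse of [column_height()]:
#' \eqn{t = t_0 + \ln(H(t_0)/h_{target})/r}.
#'
#' @param h_target Target height in mm, `0 < h_target <= H(t0)`.
#' @param t0 Start time (s).
#' @inheritParams decay_rate
#' @return Time in s; `column_height()` at that time returns `h_target`.
#' @examples
#' time_to_height(100, k = 1000)
#' @export
time_to_height <- function(h_target, k, geom = device_geometry(),
                           fluid = fluid_properties(), t0 = 0) {
  check_permeability(k)
  if (any(h_target <= 0) || any(h_target > geom$initial_height_mm)) {
    stop("invalid-height: h_target must be in (0, H(t0)]", call. = FALSE)
  }
  r <- decay_rate(k, geom, fluid)
  if (r == 0) {
    if (any(h_target < geom$initial_height_mm)) {
      stop("unreachable-height: k = 0 never reaches a height below H(t0)",
           call. = FALSE)
    }
    return(rep(t0, length(h_target)))
  }
  t0 + log(geom$initial_height_mm / h_target) / r
}
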