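#' Permeameter device geometry
#'
#' Describes the falling-head permeability device: a cylindrical tissue
#' sample confined between porous plates, topped by a fluid-filled pipette.
#' The fluid column drains through the sample under its own weight and its
#' height over time carries all the information about the sample's
#' permeability.
#'
#' @param sample_diameter_mm Diameter of the cylindrical sample chamber (mm).
#' @param sample_thickness_mm Sample thickness along the flow axis,
#'   \eqn{\Delta x} (mm).
#' @param pipette_diameter_mm Internal diameter of the standpipe (mm).
#' @param initial_height_mm Fluid column height at the start of a run,
#'   \eqn{H(t_0)} (mm).
#' @param window_mm Closed height interval (mm) inside which observations
#'   are used for fitting, as `c(lower, upper)`.
#'
#' @details The defaults encode a bench device with a 3 mm diameter, 2 mm
#'   thick sample chamber, a 6 mm standpipe, a 210 mm starting column and a
#'   210--100 mm analysis window. Derived cross-section areas
#'   `sample_area_mm2` (\eqn{A_s}) and `pipette_area_mm2` (\eqn{A_p}) are
#'   stored on the object.
#'
#' @return An object of class `device_geometry`.
#' @examples
#' geom <- device_geometry()
#' geom$sample_area_mm2 / geom$pipette_area_mm2  # 0.25
#' @export
device_geometry <- function(sample_diameter_mm = 3,
                            sample_thickness_mm = 2,
                            pipette_diameter_mm = 6,
                            initial_height_mm = 210,
                            window_mm = c(100, 210)) {
  for (v in c(sample_diameter_mm, sample_thickness_mm, pipette_diameter_mm,
              initial_height_mm)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid-geometry: all device lengths must be single positive numbers",
           call. = FALSE)
    }
  }
  window_mm <- sort(as.numeric(window_mm))
  if (length(window_mm) != 2L || any(!is.finite(window_mm)) ||
      window_mm[1] <= 0 || window_mm[2] > initial_height_mm) {
    stop("invalid-geometry: analysis window must satisfy 0 < lower <= upper <= initial height",
         call. = FALSE)
  }
  structure(
    list(
      sample_diameter_mm = sample_diameter_mm,
      sample_thickness_mm = sample_thickness_mm,
      pipette_diameter_mm = pipette_diameter_mm,
      initial_height_mm = initial_height_mm,
      window_mm = window_mm,
      sample_area_mm2 = pi * (sample_diameter_mm / 2)^2,
      pipette_area_mm2 = pi * (pipette_diameter_mm / 2)^2
    ),
    class = "device_geometry"
  )
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("Falling-head permeameter geometry\n")
  cat(sprintf("  sample:   d = %g mm, thickness = %g mm (A_s = %.4g mm^2)\n",
              x$sample_diameter_mm, x$sample_thickness_mm, x$sample_area_mm2))
  cat(sprintf("  pipette:  d = %g mm (A_p = %.4g mm^2)\n",
              x$pipette_diameter_mm, x$pipette_area_mm2))
  cat(sprintf("  column:   H(t0) = %g mm, analysis window [%g, %g] mm\n",
              x$initial_height_mm, x$window_mm[1], x$window_mm[2]))
  invisible(x)
}

#' Permeating fluid properties
#'
#' @param specific_weight_N_mm3 Specific weight \eqn{\gamma} of the
#'   permeating fluid in N/mm^3. The default, `9.81e-6` N/mm^3
#'   (= 9.81 kN/m^3), is water at bench temperature and reproduces the
#'   device's nominal pressure-gradient endpoints; the fluid is configurable
#'   because culture medium or PBS differ slightly.
#'
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()$specific_weight_N_mm3
#' @export
fluid_properties <- function(specific_weight_N_mm3 = 9.81e-6) {
  if (!is.numeric(specific_weight_N_mm3) || length(specific_weight_N_mm3) != 1L ||
      !is.finite(specific_weight_N_mm3) || specific_weight_N_mm3 <= 0) {
    stop("invalid-fluid: specific weight must be a single positive number",
         call. = FALSE)
  }
  structure(list(specific_weight_N_mm3 = specific_weight_N_mm3),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: specific weight gamma = %g N/mm^3 (%g kN/m^3)\n",
              x$specific_weight_N_mm3, x$specific_weight_N_mm3 * 1e9 / 1e3))
  invisible(x)
}

check_permeability <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("invalid-permeability: k must be a single finite number >= 0",
         call. = FALSE)
  }
  k
}

#' Convert a permeability coefficient between mm- and SI-based units
#'
#' The working unit is mm^4/(N s); the SI equivalent is m^4/(N s)
#' (1 mm^4 = 1e-12 m^4).
#'
#' @param k_mm4_per_Ns Permeability in mm^4/(N s).
#' @param k_m4_per_Ns Permeability in m^4/(N s).
#' @return The converted coefficient.
#' @examples
#' k_to_si(1000)      # 1e-9 m^4/(N s)
#' k_from_si(1e-9)    # 1000 mm^4/(N s)
#' @export
k_to_si <- function(k_mm4_per_Ns) k_mm4_per_Ns * 1e-12

#' @rdname k_to_si
#' @export
k_from_si <- function(k_m4_per_Ns) k_m4_per_Ns * 1e12

#' Read device geometry and fluid properties from a JSON config
#'
#' Expects a JSON object with a `device` block (keys
#' `sample_diameter_mm`, `sample_thickness_mm`, `pipette_diameter_mm`,
#' `initial_height_mm`, `window_mm`) and a `fluid` block
#' (`specific_weight_N_mm3`). Missing keys fall back to the defaults of
#' [device_geometry()] and [fluid_properties()]; unknown keys are rejected.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `geom` and `fluid`.
#' @export
read_device_config <- function(path) {
  if (!file.exists(path)) stop("empty-file: config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_dev <- c("sample_diameter_mm", "sample_thickness_mm",
                 "pipette_diameter_mm", "initial_height_mm", "window_mm")
  known_fluid <- "specific_weight_N_mm3"
  dev <- if (is.null(cfg$device)) list() else as.list(cfg$device)
  flu <- if (is.null(cfg$fluid)) list() else as.list(cfg$fluid)
  bad <- c(setdiff(names(dev), known_dev), setdiff(names(flu), known_fluid),
           setdiff(names(cfg), c("device", "fluid")))
  if (length(bad)) {
    stop("schema-mismatch: unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(geom = do.call(device_geometry, dev),
       fluid = do.call(fluid_properties, flu))
}
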