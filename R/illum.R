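# Illumination-side computations: thermal-image-derived laser power maps,
# beam inclination geometry, and irradiance-above-threshold coverage.

#' Construct a thermal map
#'
#' @param temperature Matrix of surface temperatures (degrees C).
#' @param pixel_scale mm per pixel (> 0).
#' @param time_label Acquisition time label (e.g. `"t=0"`, `"t=5"`).
#' @return An object of class `fgs_thermal_map`.
#' @export
thermal_map <- function(temperature, pixel_scale, time_label = "") {
  temperature <- as.matrix(temperature)
  if (any(!is.finite(temperature))) stop("temperatures must be finite")
  if (pixel_scale <= 0) stop("pixel scale must be positive")
  structure(list(temperature = temperature, pixel_scale = pixel_scale,
                 time_label = time_label), class = "fgs_thermal_map")
}

#' Estimate the laser power distribution from thermal images
#'
#' Surface temperature maps before and after a fixed period of laser
#' illumination give a heating map `dT(x, y)`; rescaling `dT / max(dT)` by
#' the measured maximum laser power estimates the surface power
#' distribution.  Heating is assumed proportional to absorbed power with
#' uniform absorptivity; negative `dT` values are clipped to 0.
#'
#' @param t0,t5 `fgs_thermal_map` objects of equal shape and pixel scale
#'   (before / after illumination).
#' @param p_max Measured maximum laser power, mW/cm^2 (> 0).
#' @return An object of class `fgs_power_map` with fields `irradiance`
#'   (matrix, mW/cm^2), `pixel_scale` and `p_max`.
#' @export
power_from_thermal <- function(t0, t5, p_max) {
  stopifnot(inherits(t0, "fgs_thermal_map"), inherits(t5, "fgs_thermal_map"))
  if (!all(dim(t0$temperature) == dim(t5$temperature)))
    stop("thermal maps must have equal shapes")
  if (t0$pixel_scale != t5$pixel_scale)
    stop("thermal maps must have equal pixel scales")
  if (p_max <= 0) stop("p_max must be positive")
  dT <- pmax(t5$temperature - t0$temperature, 0)
  dT_max <- max(dT)
  if (dT_max <= 0) stop("no heating detected: max temperature rise is <= 0")
  structure(list(irradiance = dT / dT_max * p_max,
                 pixel_scale = t0$pixel_scale, p_max = p_max),
            class = "fgs_power_map")
}

#' Wrap an irradiance grid as a power map
#'
#' @param irradiance Matrix of irradiances, mW/cm^2 (>= 0).
#' @param pixel_scale mm per pixel.
#' @param p_max Peak power label; defaults to the grid maximum.
#' @return An `fgs_power_map`.
#' @export
power_map <- function(irradiance, pixel_scale, p_max = max(irradiance)) {
  irradiance <- as.matrix(irradiance)
  if (any(irradiance < 0)) stop("irradiance values must be >= 0")
  if (pixel_scale <= 0) stop("pixel scale must be positive")
  structure(list(irradiance = irradiance, pixel_scale = pixel_scale,
                 p_max = p_max), class = "fgs_power_map")
}

#' Laser inclination angle of a converging diode array
#'
#' For a diode mounted a distance `d` off the array center with all beams
#' intersecting the optical axis at working distance `L`, the inclination
#' is `theta = atan(d / L)`.
#'
#' @param L Working distance (mm, > 0) where the beams intersect.
#' @param d Distance between the individual laser center and the array
#'   center (mm, >= 0).
#' @return Inclination angle in degrees.
#' @export
inclination_angle <- function(L, d) {
  if (L <= 0) stop("working distance L must be positive")
  if (any(d < 0)) stop("d must be non-negative")
  atan(d / L) * 180 / pi
}

#' Irradiated area above a threshold
#'
#' Area (cm^2) of pixels at or above the irradiance threshold, and the
#' diameter (cm) of the circle of equal area — a single "diameter" summary
#' for a generally non-circular beam superposition.
#'
#' @param power An `fgs_power_map`.
#' @param threshold Irradiance threshold, mW/cm^2 (> 0).
#' @return `list(area_cm2 =, diameter_cm =)`.
#' @export
coverage_above <- function(power, threshold) {
  stopifnot(inherits(power, "fgs_power_map"))
  if (threshold <= 0) stop("threshold must be positive")
  px_area_cm2 <- (power$pixel_scale / 10)^2
  area <- sum(power$irradiance >= threshold) * px_area_cm2
  list(area_cm2 = area, diameter_cm = 2 * sqrt(area / pi))
}
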