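# Illumination, optical channels, noise, frame rendering and
# laser-synchronized stream generation.

# Reference irradiance (mW/cm^2) at which the excitation-filter leak
# fractions are calibrated: the per-well irradiance used when the phantom
# was characterized.
FGS_REFERENCE_IRRADIANCE <- 20

#' Laser-diode array illumination model
#'
#' A circular array of `n_beams` Gaussian beams whose axes converge on the
#' optical axis at working distance `L` (the beams cross there and diverge
#' beyond it).  The beam footprint radius grows linearly with propagation;
#' per-beam peak irradiance decays with the footprint area so that energy
#' is conserved.  Defaults qualitatively reproduce a three-diode array
#' whose lasers intersect at 40 cm with a peak irradiance of ~20 mW/cm^2
#' at that distance, decaying toward ~5 mW/cm^2 at 60 cm.
#'
#' @param n_beams Number of diodes on the circle.
#' @param d Radius of the source circle: distance between an individual
#'   laser center and the array center, mm.
#' @param L Working distance at which the beams intersect, mm.
#' @param beam_peak Per-beam peak irradiance at the source, mW/cm^2.
#' @param beam_radius 1/e^2 beam radius at the source, mm.
#' @param beam_divergence Linear footprint growth (mm radius per mm
#'   propagated).
#' @param white_ambient Dimensionless white-light level scaling visible
#'   reflectance.
#' @param nir_ambient Dimensionless ambient NIR (room light) intensity on
#'   the NIR sensor.
#' @return An object of class `fgs_illumination`.
#' @export
illumination_model <- function(n_beams = 3, d = 30, L = 400,
                               beam_peak = 22, beam_radius = 5,
                               beam_divergence = 0.01,
                               white_ambient = 1, nir_ambient = 0.05) {
  if (L <= 0) stop("working distance L must be positive")
  if (d < 0) stop("source circle radius d must be non-negative")
  if (beam_peak < 0) stop("irradiance must be non-negative")
  structure(list(n_beams = n_beams, d = d, L = L, beam_peak = beam_peak,
                 beam_radius = beam_radius,
                 beam_divergence = beam_divergence,
                 white_ambient = white_ambient, nir_ambient = nir_ambient),
            class = "fgs_illumination")
}

#' Spatially uniform illumination
#'
#' An illumination model delivering a constant excitation irradiance over
#' the whole target plane.  This emulates acquisition protocols that
#' equalize per-target irradiance (e.g. a motorized stage positioning each
#' phantom well under the beam center in turn), and is the default for the
#' well-plate sensitivity experiment.
#'
#' @param irradiance Excitation irradiance, mW/cm^2; defaults to the
#'   20 mW/cm^2 reference level.
#' @param white_ambient,nir_ambient As in [illumination_model()].
#' @return An `fgs_illumination` whose irradiance varies by less than one
#'   part in 1e9 over any desk-scale plane.
#' @export
uniform_illumination <- function(irradiance = FGS_REFERENCE_IRRADIANCE,
                                 white_ambient = 1, nir_ambient = 0.05) {
  illumination_model(n_beams = 1, d = 0, L = 500, beam_peak = irradiance,
                     beam_radius = 1e8, beam_divergence = 0,
                     white_ambient = white_ambient,
                     nir_ambient = nir_ambient)
}

#' Vectorized irradiance function at a working distance
#'
#' At plane z = `distance`, each beam's center is displaced from the axis
#' by `d * (1 - distance / L)` along its azimuth (beams converge at `L`,
#' then diverge), with 1/e^2 radius `w = beam_radius + beam_divergence *
#' distance` and peak scaled by `(beam_radius / w)^2`.
#'
#' @param ill An `fgs_illumination`.
#' @param distance Plane distance in mm (> 0).
#' @return A function `f(x, y)` returning irradiance in mW/cm^2 at plane
#'   coordinates in mm.
#' @export
irradiance_fn <- function(ill, distance) {
  if (distance <= 0) stop("distance must be positive")
  w <- ill$beam_radius + ill$beam_divergence * distance
  peak <- ill$beam_peak * (ill$beam_radius / w)^2
  off <- ill$d * (1 - distance / ill$L)
  phi <- 2 * pi * (seq_len(ill$n_beams) - 1) / ill$n_beams
  cx <- off * cos(phi); cy <- off * sin(phi)
  function(x, y) {
    v <- numeric(length(x))
    for (i in seq_along(cx)) {
      r2 <- (x - cx[i])^2 + (y - cy[i])^2
      v <- v + peak * exp(-2 * r2 / w^2)
    }
    v
  }
}

#' Irradiance map on a plane grid
#'
#' @inheritParams irradiance_fn
#' @param extent Grid extent `c(width, height)` in mm.
#' @param res Grid resolution in px/mm.
#' @return A list with `irradiance` (matrix, mW/cm^2), `pixel_scale`
#'   (mm/px), `x`, `y` (coordinate vectors, mm).
#' @export
irradiance_map <- function(ill, distance, extent = c(120, 120), res = 2) {
  fn <- irradiance_fn(ill, distance)
  nx <- round(extent[1] * res); ny <- round(extent[2] * res)
  x <- (seq_len(nx) - 1 - (nx - 1) / 2) / res
  y <- (seq_len(ny) - 1 - (ny - 1) / 2) / res
  xs <- rep(x, each = ny); ys <- rep(y, times = nx)
  list(irradiance = matrix(fn(xs, ys), ny, nx), pixel_scale = 1 / res,
       x = x, y = y)
}

#' Optical detection channel
#'
#' Collapses the spectral realism of an excitation-filter stack into two
#' scalars: the leak fraction (the fraction of excitation irradiance that
#' registers on the NIR sensor through the emission filter, an effective
#' optical density) and the emission gain (detected intensity per molar of
#' fluorophore per mW/cm^2 of excitation).
#'
#' @param kind `"nir"` or `"visible"`; visible channels have zero leak and
#'   gain.
#' @param leak Leak fraction in [0, 1].
#' @param gain Emission gain, intensity per molar per (mW/cm^2).
#' @return An object of class `fgs_channel`.
#' @export
optical_channel <- function(kind = c("nir", "visible"), leak = 0.0041,
                            gain = 2.05e6) {
  kind <- match.arg(kind)
  if (kind == "visible") { leak <- 0; gain <- 0 }
  if (leak < 0 || leak > 1) stop("leak fraction must be in [0, 1]")
  if (gain < 0) stop("emission gain must be non-negative")
  structure(list(kind = kind, leak = leak, gain = gain),
            class = "fgs_channel")
}

#' Excitation-filter channel presets
#'
#' The four filter options are characterized by their measured excitation
#' leak: the maximum laser-ON minus laser-OFF pixel intensity on white
#' paper of 0.53 (single 830 nm longpass), 0.082 (double 830 nm LP), 0.106
#' (832 nm bandpass) and 0.090 (808 nm LP).  Leak fractions are calibrated
#' so a noiseless render of a uniform card at the reference irradiance of
#' 20 mW/cm^2 reproduces those values exactly.  The emission gain is a
#' camera/fluorophore property shared by all filters.
#'
#' @param name One of `"830lp"`, `"dbl_830lp"`, `"832bp"`, `"808lp"`.
#' @param gain Emission gain passed to [optical_channel()].
#' @return An `fgs_channel` of kind `"nir"`.
#' @export
filter_channel <- function(name = c("dbl_830lp", "830lp", "832bp", "808lp"),
                           gain = 2.05e6) {
  name <- match.arg(name)
  leaks <- c("830lp" = 0.53, "dbl_830lp" = 0.082,
             "832bp" = 0.106, "808lp" = 0.090) / FGS_REFERENCE_IRRADIANCE
  optical_channel("nir", leak = unname(leaks[name]), gain = gain)
}

#' Pre-noise detected intensity
#'
#' The scalar forward model of the NIR channel:
#' `I = min(1, exposure * (gain * C * E + leak * E + ambient))`,
#' monotone non-decreasing in every argument.  Fluorescence is
#' proportional to concentration times irradiance; leaked excitation is
#' proportional to irradiance; ambient NIR adds a constant.
#'
#' @param C Fluorophore concentration, molar (vectorized).
#' @param E Excitation irradiance, mW/cm^2 (vectorized).
#' @param channel An `fgs_channel`.
#' @param ambient Ambient intensity term.
#' @param exposure Exposure/gain scalar applied before saturation.
#' @return Intensities in [0, 1].
#' @export
detected_intensity <- function(C, E, channel, ambient = 0, exposure = 1) {
  stopifnot(inherits(channel, "fgs_channel"))
  if (any(C < 0) || any(E < 0) || any(ambient < 0))
    stop("concentration, irradiance and ambient must be non-negative")
  pmin(1, exposure * (channel$gain * C * E + channel$leak * E + ambient))
}

#' Sensor noise model
#'
#' Poisson shot noise on a photoelectron scale, then additive Gaussian read
#' noise.  Identical seeds reproduce identical frames bit-for-bit.
#'
#' @param shot_scale Photoelectrons at full scale (0 disables shot noise).
#' @param read_sd Gaussian read-noise standard deviation, intensity units.
#' @param seed Integer seed.
#' @return An object of class `fgs_noise`.
#' @export
noise_model <- function(shot_scale = 5000, read_sd = 0.002, seed = 1L) {
  if (shot_scale < 0 || read_sd < 0) stop("noise parameters must be >= 0")
  structure(list(shot_scale = shot_scale, read_sd = read_sd,
                 seed = as.integer(seed)), class = "fgs_noise")
}

apply_noise <- function(intensity, noise, frame_index = 0L) {
  if (is.null(noise)) return(intensity)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((noise$seed + 9973L * (frame_index %% 100000L)) %% 2147483647L)
  v <- intensity
  if (noise$shot_scale > 0)
    v <- stats::rpois(length(v), pmax(v, 0) * noise$shot_scale) /
      noise$shot_scale
  if (noise$read_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$read_sd)
  matrix(v, nrow(intensity), ncol(intensity))
}

quantize_intensity <- function(intensity, bit_depth) {
  levels <- 2^bit_depth - 1
  round(pmax(pmin(intensity, 1), 0) * levels) / levels
}

#' Construct a frame
#'
#' @param intensity Matrix of intensities in [0, 1] (rows = y).
#' @param t_ms Timestamp in ms.
#' @param laser_state `"on"`, `"off"`, or `NA` when unknown.
#' @param channel_kind `"nir"` or `"visible"`.
#' @return An object of class `fgs_frame`.
#' @export
frame <- function(intensity, t_ms = 0, laser_state = NA_character_,
                  channel_kind = "nir") {
  if (any(intensity < -1e-12) || any(intensity > 1 + 1e-12))
    stop("frame intensities must lie in [0, 1]")
  structure(list(intensity = intensity, t_ms = t_ms,
                 laser_state = laser_state, channel_kind = channel_kind),
            class = "fgs_frame")
}

#' Construct a frame stream
#'
#' @param frames List of `fgs_frame` objects with strictly increasing
#'   timestamps spaced by the frame period.
#' @param period_ms Frame period in ms.
#' @param fps Declared frame rate; must match `1000 / period_ms` within 1%.
#' @return An object of class `fgs_stream`.
#' @export
frame_stream <- function(frames, period_ms, fps = 1000 / period_ms) {
  ts <- vapply(frames, function(f) f$t_ms, numeric(1))
  if (length(ts) > 1) {
    if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(diff(ts) - period_ms)) > 1e-9)
      stop("timestamps must be spaced by the frame period")
  }
  if (abs(fps - 1000 / period_ms) / (1000 / period_ms) > 0.01 + 1e-12)
    stop("declared rate must equal 1000/period within 1%")
  structure(list(frames = frames, period_ms = period_ms, fps = fps),
            class = "fgs_stream")
}

#' @export
print.fgs_stream <- function(x, ...) {
  states <- vapply(x$frames, function(f) as.character(f$laser_state),
                   character(1))
  cat(sprintf("<fgs_stream> %d frames @ %g fps (period %g ms)\n",
              length(x$frames), x$fps, x$period_ms))
  cat("  laser: ", paste(substr(states, 1, 2), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.fgs_stream <- function(x) length(x$frames)

#' Render a single frame of a planar target
#'
#' Back-projects each (supersampled) pixel through the camera onto the
#' target plane, evaluates the target reflectance and fluorophore
#' concentration there, and applies the channel forward model.  For the
#' NIR channel the intensity is `detected_intensity()` with the excitation
#' term present only when the laser is on; for the visible channel it is
#' reflectance times the white-light ambient level.  Noise is applied
#' (Poisson then Gaussian), then the result is quantized to the camera bit
#' depth and clipped to [0, 1].
#'
#' @param target An `fgs_target` (plane must be in front of the camera).
#' @param camera An `fgs_camera`.
#' @param ill An `fgs_illumination`.
#' @param channel An `fgs_channel`.
#' @param laser_state `"on"` or `"off"`.
#' @param noise An `fgs_noise` or `NULL` for noiseless rendering.
#' @param t_ms Timestamp recorded on the frame.
#' @param frame_index Index used to decorrelate noise between frames.
#' @param supersample Samples per pixel axis for anti-aliasing.
#' @param exposure Exposure scalar (see [detected_intensity()]).
#' @param excitation_scale Multiplies the excitation irradiance (used by
#'   [generate_stream()] for the laser/exposure overlap factor, including
#'   bleed-through into nominally laser-off frames).  Defaults to 1 for
#'   laser-on frames and 0 for laser-off frames.
#' @param quantize Quantize to `2^bit_depth` levels (default `TRUE`).
#' @return An `fgs_frame`.
#' @export
render_frame <- function(target, camera, ill, channel,
                         laser_state = c("on", "off"), noise = NULL,
                         t_ms = 0, frame_index = 0L, supersample = 2,
                         exposure = 1, excitation_scale = NULL,
                         quantize = TRUE) {
  laser_state <- match.arg(laser_state)
  if (is.null(excitation_scale))
    excitation_scale <- if (laser_state == "on") 1 else 0
  stopifnot(inherits(target, "fgs_target"), inherits(camera, "fgs_camera"))
  # depth of the plane in the camera frame along the optical axis
  zc <- camera$orientation %*% (c(0, 0, target$distance) - camera$position)
  if (zc[3] <= 0) stop("target plane behind camera")
  nx <- camera$resolution[1]; ny <- camera$resolution[2]
  f_px <- camera$focal_length / camera$pixel_pitch
  Rt <- t(camera$orientation)
  E_on <- excitation_scale > 0
  Efn <- if (E_on) irradiance_fn(ill, target$distance) else NULL
  s <- max(1L, as.integer(supersample))
  off <- (seq_len(s) - 0.5) / s - 0.5
  acc <- matrix(0, ny, nx)
  for (oy in off) for (ox in off) {
    xs <- rep(seq_len(nx) - 1 + ox, each = ny) - camera$principal_point[1]
    ys <- rep(seq_len(ny) - 1 + oy, times = nx) - camera$principal_point[2]
    # world-frame ray directions for each sample
    dir <- cbind(xs / f_px, ys / f_px, 1) %*% t(Rt)
    tt <- (target$distance - camera$position[3]) / dir[, 3]
    px <- camera$position[1] + tt * dir[, 1]
    py <- camera$position[2] + tt * dir[, 2]
    rho <- target$reflectance_fn(px, py)
    if (channel$kind == "visible") {
      I <- pmin(1, exposure * ill$white_ambient * rho)
    } else {
      C <- target$concentration_fn(px, py)
      E <- if (E_on) Efn(px, py) * excitation_scale else 0
      I <- detected_intensity(C, E, channel, ambient = ill$nir_ambient,
                              exposure = exposure)
    }
    acc <- acc + matrix(I, ny, nx)
  }
  img <- acc / s^2
  img <- apply_noise(img, noise, frame_index)
  img <- if (quantize) quantize_intensity(img, camera$bit_depth) else
    pmax(pmin(img, 1), 0)
  frame(img, t_ms = t_ms, laser_state = laser_state,
        channel_kind = channel$kind)
}

#' Generate a laser-synchronized frame stream
#'
#' The laser is triggered on every other frame (trigger period twice the
#' frame period) and stays on for `duty` of a frame period.  The effective
#' excitation contribution of each frame is the overlap of the laser-on
#' window with that frame's exposure window; with the default exposure
#' offset of 0 the laser-on frames receive an excitation factor equal to
#' `duty` and the off frames none.  A positive `exposure_offset` (fraction
#' of the frame period by which exposure windows lead the frame boundary)
#' reproduces excitation bleed-through into the following frame when
#' `duty` exceeds `1 - exposure_offset`.
#'
#' @inheritParams render_frame
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate; the frame period is `round(1000 / fps)` ms.
#' @param duty Laser on-fraction of a frame period, in (0, 1].
#' @param phase 0-based index parity of laser-on frames (default 1: the
#'   second frame is laser-on).
#' @param exposure_offset Fraction of a frame period by which the exposure
#'   window leads the frame boundary.
#' @return An `fgs_stream`.
#' @export
generate_stream <- function(target, camera, ill, channel, n_frames = 8,
                            fps = 30, duty = 0.7, phase = 1L, noise = NULL,
                            supersample = 2, exposure = 1,
                            exposure_offset = 0, quantize = TRUE) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  period <- round(1000 / fps)
  # overlap (fractions of a period) of a laser-on window [0, duty] with the
  # exposure windows [-off, 1 - off) (this frame) and [1 - off, 2 - off)
  # (the next frame)
  ov_same <- min(duty, 1 - exposure_offset)
  ov_next <- max(0, duty - (1 - exposure_offset))
  frames <- vector("list", n_frames)
  for (n in seq_len(n_frames) - 1L) {
    on_frame <- (n %% 2L) == (phase %% 2L)
    prev_on <- n > 0 && ((n - 1L) %% 2L) == (phase %% 2L)
    scale <- if (on_frame) ov_same else if (prev_on) ov_next else 0
    frames[[n + 1L]] <- render_frame(
      target, camera, ill, channel,
      laser_state = if (on_frame) "on" else "off",
      noise = noise, t_ms = n * period, frame_index = n,
      supersample = supersample, exposure = exposure,
      excitation_scale = scale, quantize = quantize)
  }
  frame_stream(frames, period_ms = period, fps = fps)
}
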