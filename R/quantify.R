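# Leak-threshold characterization, well-plate SBR, per-pixel SBR maps,
# threshold masking and coaligned overlays.

#' Excitation-leak threshold from a uniform non-fluorescent target
#'
#' The maximum pixel intensity of the laser-ON minus laser-OFF images of a
#' uniform non-fluorescent target (white paper).  This measures the
#' residual excitation light passing the emission filter; a per-pixel SBR
#' of 1 corresponds to a signal indistinguishable from this leak.
#'
#' @param on,off Intensity matrices of equal shape.
#' @return The leak threshold (scalar > 0).
#' @export
leak_threshold <- function(on, off) {
  if (!all(dim(on) == dim(off))) stop("on/off images must have equal shape")
  m <- max(on - off)
  if (m <= 0)
    stop("no detectable leak: laser-ON minus laser-OFF has no positive pixels")
  m
}

#' Circular well regions of interest
#'
#' @param plate An `fgs_well_plate`.
#' @param camera An `fgs_camera` viewing the plate.
#' @param distance Plate distance in mm.
#' @param shrink Fraction of the well radius retained (avoids edge pixels).
#' @return Data frame with columns `row`, `col`, `cx_px`, `cy_px`,
#'   `radius_px`, `concentration`, `is_control`.
#' @export
well_rois <- function(plate, camera, distance, shrink = 0.7) {
  stopifnot(inherits(plate, "fgs_well_plate"))
  lay <- plate$layout
  px <- project_points(camera, cbind(lay$cx, lay$cy, distance))
  r_px <- (plate$well_diameter / 2) * shrink / mm_per_px(camera, distance)
  data.frame(row = lay$row, col = lay$col, cx_px = px[, 1], cy_px = px[, 2],
             radius_px = r_px, concentration = lay$concentration,
             is_control = lay$is_control)
}

roi_values <- function(image, cx, cy, radius) {
  nr <- nrow(image); nc <- ncol(image)
  if (cx - radius < 0 || cx + radius > nc - 1 ||
      cy - radius < 0 || cy + radius > nr - 1)
    stop("ROI outside image bounds")
  xs <- seq(max(0, floor(cx - radius)), min(nc - 1, ceiling(cx + radius)))
  ys <- seq(max(0, floor(cy - radius)), min(nr - 1, ceiling(cy + radius)))
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= radius^2
  image[cbind(gy[keep] + 1, gx[keep] + 1)]
}

#' Per-well signal-to-background ratios
#'
#' Background-subtracted (laser-ON minus laser-OFF, negatives clipped to
#' 0) intensities are summarized per well and divided by the control-well
#' summary.  Duplicate wells (equal concentrations) are averaged after the
#' per-well SBR computation.
#'
#' @param on,off Intensity matrices of equal shape.
#' @param wells Data frame of ROIs as returned by [well_rois()]; must
#'   contain one row with `is_control = TRUE`.
#' @param stat `"mean"` (default) or `"median"` well statistic.
#' @return A list with `wells` (per-well table with `sbr`) and `curve`
#'   (per-concentration table averaging duplicates, control excluded).
#' @export
well_sbr <- function(on, off, wells, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!all(dim(on) == dim(off))) stop("on/off images must have equal shape")
  if (sum(wells$is_control) != 1) stop("exactly one control ROI is required")
  diff <- pmax(on - off, 0)
  fn <- if (stat == "mean") mean else stats::median
  wells$signal <- vapply(seq_len(nrow(wells)), function(i) {
    fn(roi_values(diff, wells$cx_px[i], wells$cy_px[i], wells$radius_px[i]))
  }, numeric(1))
  ctrl <- wells$signal[wells$is_control]
  if (ctrl <= 0) stop("control-well background-subtracted mean is <= 0")
  wells$sbr <- wells$signal / ctrl
  pos <- wells[!wells$is_control & wells$concentration > 0, ]
  curve <- stats::aggregate(sbr ~ concentration, data = pos, FUN = mean)
  list(wells = wells, curve = curve[order(curve$concentration), ])
}

#' Per-pixel SBR map
#'
#' `(on - off) / leak` per pixel with negatives clipped to 0: an SBR of 1
#' marks a signal level equal to the excitation-leak threshold.
#'
#' @param on,off Intensity matrices of equal shape.
#' @param leak Leak threshold (> 0), e.g. from [leak_threshold()].
#' @return An object of class `fgs_sbr_map`: a matrix with attributes
#'   `leak` and class.
#' @export
sbr_map <- function(on, off, leak) {
  if (!all(dim(on) == dim(off))) stop("on/off images must have equal shape")
  if (!is.numeric(leak) || leak <= 0) stop("leak threshold must be > 0")
  m <- pmax(on - off, 0) / leak
  structure(m, leak = leak, class = c("fgs_sbr_map", class(m)))
}

#' Peak SBR
#'
#' Maximum SBR over all pixels, optionally restricted to a circular ROI.
#'
#' @param map An `fgs_sbr_map` (or plain matrix).
#' @param roi Optional `list(cx =, cy =, radius =)` in pixel coordinates.
#' @return Scalar peak SBR.
#' @export
peak_sbr <- function(map, roi = NULL) {
  if (is.null(roi)) return(max(map))
  max(roi_values(unclass(map), roi$cx, roi$cy, roi$radius))
}

#' False-color SBR overlay on a coaligned visible image
#'
#' The SBR map is warped into the visible image frame by the coalignment
#' homography, pixels below the SBR threshold are made fully transparent,
#' and the remainder is alpha-blended in false color over the (grayscale)
#' visible image.
#'
#' @param map An `fgs_sbr_map`.
#' @param visible Grayscale visible image matrix.
#' @param H An `fgs_homography` mapping NIR pixel coordinates to visible
#'   pixel coordinates (identity if `NULL`).
#' @param threshold SBR masking threshold (default 1.5).
#' @param alpha Overlay opacity in (0, 1].
#' @param colormap Palette name passed to [grDevices::hcl.colors()].
#' @param interpolation Warp interpolation, `"nearest"` (default, keeps
#'   the mask binary) or `"bilinear"`.
#' @return An rows x cols x 3 RGB array in [0, 1], with attribute
#'   `opaque_count` (number of overlaid pixels).
#' @export
overlay <- function(map, visible, H = NULL, threshold = 1.5, alpha = 0.6,
                    colormap = "Inferno",
                    interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  if (is.null(H)) H <- identity_homography()
  warped <- warp_image(H, unclass(map), output_shape = dim(visible),
                       interpolation = interpolation)
  mask <- warped >= threshold
  pal <- grDevices::hcl.colors(256, colormap)
  top <- max(warped[mask], threshold)
  idx <- pmax(1, pmin(256, 1 + floor(255 * warped / top)))
  col <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(dim(visible), 3))
  for (ch in 1:3) {
    layer <- matrix(col[ch, ], nrow(visible), ncol(visible))
    out[, , ch] <- ifelse(mask, (1 - alpha) * visible + alpha * layer,
                          visible)
  }
  attr(out, "opaque_count") <- sum(mask)
  out
}

#' Fit a log-log sensitivity curve
#'
#' Points with SBR below `1 + plateau_factor` form the plateau (their mean
#' SBR is the plateau level); the remaining points form the linear region,
#' fit by ordinary least squares on (log10 concentration, log10 SBR).
#' With fewer than two linear-region points the fit is marked unavailable
#' and the plateau is still reported.
#'
#' @param curve Data frame with columns `concentration` (molar, > 0) and
#'   `sbr`, e.g. `well_sbr(...)$curve`.
#' @param plateau_factor Plateau split: plateau points satisfy
#'   `sbr < 1 + plateau_factor` (default 0.5, mirroring the SBR > 1.5
#'   overlay masking threshold).
#' @return An object of class `fgs_sensitivity_curve` with fields `curve`
#'   (with a `region` column), `slope`, `intercept`, `plateau`,
#'   `linear_range` (concentration bounds) and `available`.
#' @export
fit_sensitivity <- function(curve, plateau_factor = 0.5) {
  curve <- as.data.frame(curve)
  stopifnot(all(c("concentration", "sbr") %in% names(curve)))
  if (any(curve$concentration <= 0))
    stop("concentrations must be strictly positive within the fit")
  if (length(unique(curve$concentration)) < 3)
    stop("at least 3 distinct positive concentrations are required")
  curve <- curve[order(curve$concentration), ]
  curve$region <- ifelse(curve$sbr < 1 + plateau_factor, "plateau",
                         "linear")
  plateau_pts <- curve$sbr[curve$region == "plateau"]
  plateau <- if (length(plateau_pts)) mean(plateau_pts) else NA_real_
  lin <- curve[curve$region == "linear", ]
  if (nrow(lin) >= 2) {
    fit <- stats::lm(log10(sbr) ~ log10(concentration), data = lin)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    available <- TRUE
    linear_range <- range(lin$concentration)
  } else {
    slope <- NA_real_; intercept <- NA_real_
    available <- FALSE; linear_range <- c(NA_real_, NA_real_)
  }
  structure(list(curve = curve, slope = slope, intercept = intercept,
                 plateau = plateau, linear_range = linear_range,
                 available = available, plateau_factor = plateau_factor),
            class = "fgs_sensitivity_curve")
}

#' @export
print.fgs_sensitivity_curve <- function(x, ...) {
  cat("<fgs_sensitivity_curve>\n")
  if (x$available)
    cat(sprintf("  log-log slope %.3f (intercept %.3f) over [%.3g, %.3g] M\n",
                x$slope, x$intercept, x$linear_range[1], x$linear_range[2]))
  else cat("  linear fit unavailable (fewer than 2 linear-region points)\n")
  cat(sprintf("  plateau level: %s\n",
              if (is.na(x$plateau)) "none detected" else
                sprintf("%.3f", x$plateau)))
  invisible(x)
}
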