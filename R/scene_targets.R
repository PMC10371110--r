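# Planar targets: resolution targets with fiducials, uniform cards, and
# fluorescent well-plate phantoms.  A target lives on a fronto-parallel
# plane at a given working distance; plane coordinates are in mm with the
# origin on the optical axis of the world frame, x rightward and y downward
# (matching the image convention).

#' Specify a bar-pattern resolution target with fiducial squares
#'
#' @param fiducials Data frame with columns `cx`, `cy` (centers, mm) and
#'   `side` (square side, mm).  At least four non-collinear fiducials are
#'   required for projective calibration.
#' @param groups Data frame with columns `label`, `freq` (line pairs per
#'   mm), `bars` (bar count), `orientation` (`"vertical"` bars localize
#'   horizontal position, `"horizontal"` bars vertical position), `cx`,
#'   `cy` (group center, mm) and `length` (bar length, mm).  May be empty.
#' @param background Background reflectance of the chart.
#' @param foreground Reflectance of bars and fiducials.
#' @return An object of class `fgs_resolution_target`.
#' @export
resolution_target_spec <- function(fiducials, groups = NULL,
                                   background = 0, foreground = 1) {
  fiducials <- as.data.frame(fiducials)
  stopifnot(all(c("cx", "cy", "side") %in% names(fiducials)))
  if (nrow(fiducials) >= 3) {
    ok <- tryCatch({
      check_not_collinear(as.matrix(fiducials[, c("cx", "cy")])[1:3, ,
                                                                drop = FALSE],
                          "fiducial")
      TRUE
    }, error = function(e) FALSE)
    if (!ok && nrow(fiducials) == 3) stop("fiducials must be non-collinear")
  }
  if (is.null(groups))
    groups <- data.frame(label = character(), freq = numeric(),
                         bars = integer(), orientation = character(),
                         cx = numeric(), cy = numeric(), length = numeric())
  groups <- as.data.frame(groups)
  spec <- structure(list(fiducials = fiducials, groups = groups,
                         background = background, foreground = foreground),
                    class = "fgs_resolution_target")
  rects <- target_rects(spec)
  if (nrow(groups) > 1 && rects_overlap(group_bboxes(spec)))
    stop("line-pair groups overlap")
  spec
}

# Rectangles (xmin, xmax, ymin, ymax, value) composing the target.
target_rects <- function(spec) {
  out <- list()
  f <- spec$fiducials
  for (i in seq_len(nrow(f))) {
    h <- f$side[i] / 2
    out[[length(out) + 1]] <- c(f$cx[i] - h, f$cx[i] + h,
                                f$cy[i] - h, f$cy[i] + h)
  }
  g <- spec$groups
  for (i in seq_len(nrow(g))) {
    bw <- 1 / (2 * g$freq[i])           # bar width: half a line-pair period
    n <- g$bars[i]
    span <- (2 * n - 1) * bw            # bars separated by equal gaps
    for (b in seq_len(n)) {
      off <- -span / 2 + (2 * b - 2) * bw
      if (g$orientation[i] == "vertical") {
        out[[length(out) + 1]] <- c(g$cx[i] + off, g$cx[i] + off + bw,
                                    g$cy[i] - g$length[i] / 2,
                                    g$cy[i] + g$length[i] / 2)
      } else {
        out[[length(out) + 1]] <- c(g$cx[i] - g$length[i] / 2,
                                    g$cx[i] + g$length[i] / 2,
                                    g$cy[i] + off, g$cy[i] + off + bw)
      }
    }
  }
  if (length(out) == 0) return(matrix(numeric(), 0, 4))
  do.call(rbind, out)
}

group_bboxes <- function(spec) {
  g <- spec$groups
  if (nrow(g) == 0) return(matrix(numeric(), 0, 4))
  t(vapply(seq_len(nrow(g)), function(i) {
    bw <- 1 / (2 * g$freq[i]); span <- (2 * g$bars[i] - 1) * bw
    if (g$orientation[i] == "vertical")
      c(g$cx[i] - span / 2, g$cx[i] + span / 2,
        g$cy[i] - g$length[i] / 2, g$cy[i] + g$length[i] / 2)
    else
      c(g$cx[i] - g$length[i] / 2, g$cx[i] + g$length[i] / 2,
        g$cy[i] - span / 2, g$cy[i] + span / 2)
  }, numeric(4)))
}

rects_overlap <- function(r) {
  n <- nrow(r)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r[i, 1] < r[j, 2] && r[j, 1] < r[i, 2] &&
        r[i, 3] < r[j, 4] && r[j, 3] < r[i, 4]) return(TRUE)
  }
  FALSE
}

#' Default desk-scale alignment target
#'
#' Four 13 mm fiducial squares at (+/-40, +/-40) mm plus one vertical-bar
#' and one horizontal-bar line-pair group near the center.  The group
#' frequency defaults to 0.125 line pairs/mm (4 mm bars) so that the bars
#' remain resolvable when rendered through the binned desk-scale camera;
#' on the physical chart the corresponding analysis uses the group labeled
#' 1.0.
#'
#' @param freq Line-pair frequency in lp/mm for the two groups.
#' @return An `fgs_resolution_target`.
#' @export
default_alignment_target <- function(freq = 0.125) {
  fid <- data.frame(cx = c(-40, 40, 40, -40), cy = c(-40, -40, 40, 40),
                    side = 13)
  grp <- data.frame(
    label = c("g1.0-v", "g1.0-h"),
    freq = freq, bars = 4L,
    orientation = c("vertical", "horizontal"),
    cx = 0, cy = c(-16, 16), length = 20)
  resolution_target_spec(fid, grp)
}

#' Specify a fluorescent well-plate phantom
#'
#' A grid of wells embedded with a NIR dye at stated molar concentrations,
#' with exactly one designated zero-concentration control well.
#'
#' @param layout Data frame with columns `row`, `col`, `concentration`
#'   (molar) and `is_control` (logical; exactly one `TRUE`, concentration
#'   0).
#' @param pitch Center-to-center well spacing in mm (9 mm for a standard
#'   96-well plate).
#' @param well_diameter Well diameter in mm.
#' @param origin Plane coordinates (mm) of the row-1/col-1 well center.
#' @return An object of class `fgs_well_plate`.
#' @export
well_plate_phantom <- function(layout, pitch = 9, well_diameter = 6.9,
                               origin = NULL) {
  layout <- as.data.frame(layout)
  stopifnot(all(c("row", "col", "concentration", "is_control") %in%
                  names(layout)))
  if (any(layout$concentration < 0))
    stop("concentrations must be non-negative")
  if (sum(layout$is_control) != 1)
    stop("exactly one control well must be designated")
  if (layout$concentration[layout$is_control] != 0)
    stop("the control well must have concentration 0")
  nr <- max(layout$row); ncl <- max(layout$col)
  if (is.null(origin))
    origin <- c(-(ncl - 1) * pitch / 2, -(nr - 1) * pitch / 2)
  layout$cx <- origin[1] + (layout$col - 1) * pitch
  layout$cy <- origin[2] + (layout$row - 1) * pitch
  structure(list(layout = layout, pitch = pitch,
                 well_diameter = well_diameter, origin = origin),
            class = "fgs_well_plate")
}

#' Default IR-125 dilution-series phantom
#'
#' Duplicate wells (two rows) at the dilution series 250 pM, 500 pM, 1 nM,
#' 5 nM, 7.5 nM, 10 nM, 25 nM, 50 nM, 75 nM and 100 nM, plus a duplicate
#' zero-concentration column; the first of the zero wells is the designated
#' control.
#'
#' @return An `fgs_well_plate`.
#' @export
default_ir125_phantom <- function() {
  conc <- c(0, 250e-12, 500e-12, 1e-9, 5e-9, 7.5e-9, 10e-9,
            25e-9, 50e-9, 75e-9, 100e-9)
  layout <- data.frame(
    row = rep(1:2, each = length(conc)),
    col = rep(seq_along(conc), times = 2),
    concentration = rep(conc, 2),
    is_control = FALSE)
  layout$is_control[1] <- TRUE
  well_plate_phantom(layout)
}

# ---- planar targets --------------------------------------------------------

#' Construct a planar target for rendering
#'
#' Wraps a pattern specification (or explicit reflectance/concentration
#' functions) together with its working distance and extent.
#'
#' @param spec An `fgs_resolution_target`, `fgs_well_plate`, or `NULL` for
#'   a uniform card.
#' @param distance Distance of the plane from the world origin along the
#'   viewing axis, mm.
#' @param extent Physical extent `c(width, height)` in mm; pattern values
#'   outside the extent are 0.
#' @param reflectance Uniform-card reflectance, or the plate/chart
#'   background reflectance override.
#' @param concentration Uniform fluorophore concentration (molar) for a
#'   uniform card; patterns carry their own concentrations.
#' @return An object of class `fgs_target` with vectorized
#'   `reflectance_fn(x, y)` and `concentration_fn(x, y)` closures.
#' @export
planar_target <- function(spec = NULL, distance = 500, extent = c(200, 200),
                          reflectance = 1, concentration = 0) {
  if (any(extent <= 0)) stop("target extent must be positive")
  inside <- function(x, y) {
    as.numeric(abs(x) <= extent[1] / 2 & abs(y) <= extent[2] / 2)
  }
  if (is.null(spec)) {
    kind <- "uniform_card"
    refl <- function(x, y) reflectance * inside(x, y)
    conc <- function(x, y) concentration * inside(x, y)
  } else if (inherits(spec, "fgs_resolution_target")) {
    kind <- "resolution_target"
    rects <- target_rects(spec)
    bg <- spec$background; fg <- spec$foreground
    refl <- function(x, y) {
      v <- rep(bg, length(x))
      for (i in seq_len(nrow(rects))) {
        hit <- x >= rects[i, 1] & x <= rects[i, 2] &
          y >= rects[i, 3] & y <= rects[i, 4]
        v[hit] <- fg
      }
      v * inside(x, y)
    }
    conc <- function(x, y) numeric(length(x))
  } else if (inherits(spec, "fgs_well_plate")) {
    kind <- "well_plate"
    lay <- spec$layout
    r2 <- (spec$well_diameter / 2)^2
    refl <- function(x, y) reflectance * inside(x, y)
    conc <- function(x, y) {
      v <- numeric(length(x))
      for (i in seq_len(nrow(lay))) {
        hit <- (x - lay$cx[i])^2 + (y - lay$cy[i])^2 <= r2
        v[hit] <- lay$concentration[i]
      }
      v * inside(x, y)
    }
  } else stop("unsupported target spec")
  structure(list(kind = kind, spec = spec, distance = distance,
                 extent = extent, reflectance_fn = refl,
                 concentration_fn = conc),
            class = "fgs_target")
}

#' Rasterize a pattern specification in plane coordinates
#'
#' Renders the pattern at a fixed resolution with anti-aliased edges.
#' Rectangular elements (bars, fiducials) use exact area-weighted coverage;
#' well discs use 4x4 supersampled coverage.  Ground-truth fiducial centers
#' and line-pair bar positions are returned in both mm and pixel units.
#'
#' @param spec An `fgs_resolution_target` or `fgs_well_plate`.
#' @param res Resolution in px/mm.
#' @param extent Rendered extent `c(width, height)` in mm.
#' @return A list with `image` (matrix, rows = y), `res`, `extent`,
#'   `origin_px` (pixel coordinate of plane origin) and, for resolution
#'   targets, `fiducials_px` and `bar_positions`.
#' @export
render_pattern <- function(spec, res = 10, extent = c(120, 120)) {
  nx <- round(extent[1] * res); ny <- round(extent[2] * res)
  # pixel (i, j) center at plane mm coordinate ((j - (nx-1)/2)/res, ...)
  origin_px <- c((nx - 1) / 2, (ny - 1) / 2)
  px_x <- (seq_len(nx) - 1 - origin_px[1]) / res
  px_y <- (seq_len(ny) - 1 - origin_px[2]) / res
  if (inherits(spec, "fgs_resolution_target")) {
    img <- matrix(spec$background, ny, nx)
    rects <- target_rects(spec)
    half <- 0.5 / res
    for (i in seq_len(nrow(rects))) {
      # exact coverage of each pixel footprint by the rectangle
      covx <- pmax(0, pmin(rects[i, 2], px_x + half) -
                     pmax(rects[i, 1], px_x - half)) * res
      covy <- pmax(0, pmin(rects[i, 4], px_y + half) -
                     pmax(rects[i, 3], px_y - half)) * res
      cov <- outer(covy, covx)
      img <- img + (spec$foreground - spec$background) * cov
    }
    fid_px <- cbind(x = spec$fiducials$cx * res + origin_px[1],
                    y = spec$fiducials$cy * res + origin_px[2])
    bars <- bar_positions(spec)
    return(list(image = img, res = res, extent = extent,
                origin_px = origin_px, fiducials_px = fid_px,
                bar_positions = bars))
  }
  if (inherits(spec, "fgs_well_plate")) {
    target <- planar_target(spec, distance = 1, extent = extent)
    img <- supersample_grid(function(x, y) {
      as.numeric(target$concentration_fn(x, y) > 0)
    }, px_x, px_y, s = 4)
    return(list(image = img, res = res, extent = extent,
                origin_px = origin_px,
                wells_px = cbind(x = spec$layout$cx * res + origin_px[1],
                                 y = spec$layout$cy * res + origin_px[2])))
  }
  stop("unsupported pattern spec")
}

# Ground-truth bar center positions (mm) for each group.
bar_positions <- function(spec) {
  g <- spec$groups
  lapply(seq_len(nrow(g)), function(i) {
    bw <- 1 / (2 * g$freq[i]); n <- g$bars[i]
    span <- (2 * n - 1) * bw
    centers <- -span / 2 + (2 * seq_len(n) - 2) * bw + bw / 2
    list(label = g$label[i], orientation = g$orientation[i],
         centers = centers + if (g$orientation[i] == "vertical") g$cx[i]
                             else g$cy[i],
         period = 1 / g$freq[i])
  })
}

supersample_grid <- function(fn, px_x, px_y, s = 4) {
  off <- (seq_len(s) - 0.5) / s - 0.5
  acc <- matrix(0, length(px_y), length(px_x))
  step_x <- if (length(px_x) > 1) px_x[2] - px_x[1] else 1
  step_y <- if (length(px_y) > 1) px_y[2] - px_y[1] else 1
  for (oy in off) for (ox in off) {
    xs <- rep(px_x + ox * step_x, each = length(px_y))
    ys <- rep(px_y + oy * step_y, times = length(px_x))
    acc <- acc + matrix(fn(xs, ys), length(px_y), length(px_x))
  }
  acc / s^2
}
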