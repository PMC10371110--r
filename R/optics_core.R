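# Pinhole camera geometry and projective-transform (homography) estimation.
#
# Image coordinate convention used throughout the package: origin at the
# top-left pixel center, x rightward along columns, y downward along rows,
# 0-based, real-valued sub-pixel coordinates.  Images are stored as R
# matrices with rows indexing y and columns indexing x, so pixel (x, y)
# lives at mat[y + 1, x + 1].

#' Construct a pinhole camera model
#'
#' The camera model carries the intrinsic and extrinsic parameters shared by
#' the scene simulator, the dual-camera calibration and the eye-alignment
#' audit.  The default parameters describe a fixed-focus CMOS module with a
#' 3.04 mm lens whose effective pixel pitch gives a scene-space sampling of
#' 0.15 mm per pixel at a 50 cm working distance.
#'
#' @param focal_length Focal length in mm; must be positive.
#' @param pixel_pitch Sensor pixel pitch in mm per pixel; must be positive.
#' @param resolution Integer pair `c(width, height)` in pixels.
#' @param principal_point Principal point `c(x, y)` in pixels (0-based);
#'   defaults to the image center.
#' @param position Camera center in world coordinates (mm).
#' @param orientation Either a 3x3 proper rotation matrix (world to camera)
#'   or an axis-angle specification created by [rotation_axis_angle()].
#' @param bit_depth Integer; intensities are quantized to `2^bit_depth`
#'   levels when rendering with quantization enabled.
#' @return An object of class `fgs_camera`.
#' @seealso [project_points()], [binned_camera()]
#' @export
camera_model <- function(focal_length = 3.04,
                         pixel_pitch = 9.12e-4,
                         resolution = c(3280, 2464),
                         principal_point = (resolution - 1) / 2,
                         position = c(0, 0, 0),
                         orientation = diag(3),
                         bit_depth = 8) {
  stopifnot(length(resolution) == 2, length(principal_point) == 2,
            length(position) == 3)
  if (!is.numeric(focal_length) || focal_length <= 0)
    stop("focal_length must be positive")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be positive")
  if (any(resolution < 1)) stop("resolution components must be >= 1")
  R <- as_rotation_matrix(orientation)
  cam <- structure(list(
    focal_length = focal_length,
    pixel_pitch = pixel_pitch,
    resolution = as.numeric(resolution),
    principal_point = as.numeric(principal_point),
    position = as.numeric(position),
    orientation = R,
    bit_depth = as.integer(bit_depth)
  ), class = "fgs_camera")
  cam
}

#' Axis-angle rotation specification
#'
#' @param axis 3-vector rotation axis (need not be normalized).
#' @param angle_deg Rotation angle in degrees.
#' @return An object of class `fgs_axis_angle` accepted by [camera_model()].
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  structure(list(axis = as.numeric(axis), angle_deg = angle_deg),
            class = "fgs_axis_angle")
}

as_rotation_matrix <- function(orientation, tol = 1e-9) {
  if (inherits(orientation, "fgs_axis_angle")) {
    a <- orientation$axis
    n <- sqrt(sum(a^2))
    if (n == 0) stop("rotation axis must be non-zero")
    a <- a / n
    th <- orientation$angle_deg * pi / 180
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    return(R)
  }
  R <- as.matrix(orientation)
  if (!all(dim(R) == c(3, 3))) stop("orientation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("orientation is not orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > 1e-6)
    stop("orientation must be a proper rotation (det = +1)")
  R
}

#' Derive a pixel-binned version of a camera
#'
#' Binning by an integer factor divides the resolution and multiplies the
#' pixel pitch, leaving the field of view and the scene-space mm-per-pixel
#' relationship of the full sensor unchanged.  Used to render experiments at
#' desk scale without rastering the full sensor.
#'
#' @param camera An `fgs_camera`.
#' @param factor Integer binning factor.
#' @return A new `fgs_camera`.
#' @export
binned_camera <- function(camera, factor) {
  stopifnot(inherits(camera, "fgs_camera"), factor >= 1)
  camera_model(
    focal_length = camera$focal_length,
    pixel_pitch = camera$pixel_pitch * factor,
    resolution = floor(camera$resolution / factor),
    principal_point = (camera$principal_point + 0.5) / factor - 0.5,
    position = camera$position,
    orientation = camera$orientation,
    bit_depth = camera$bit_depth
  )
}

#' Scene-space size of one pixel at a working distance
#'
#' @param camera An `fgs_camera`.
#' @param distance Working distance in mm.
#' @return mm per pixel at the fronto-parallel plane at `distance`.
#' @export
mm_per_px <- function(camera, distance) {
  distance * camera$pixel_pitch / camera$focal_length
}

#' Project world points through a pinhole camera
#'
#' Perspective projection of 3D world points (mm) onto the sensor.  A point
#' on the optical axis maps to the principal point.  Points with
#' non-positive depth in the camera frame raise an error.
#'
#' @param camera An `fgs_camera`.
#' @param points Numeric 3-vector or n x 3 matrix of world points in mm.
#' @return n x 2 matrix of 0-based pixel coordinates (x, y).
#' @export
project_points <- function(camera, points) {
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  pc <- (p - matrix(camera$position, nrow(p), 3, byrow = TRUE)) %*%
    t(camera$orientation)
  if (any(pc[, 3] <= 0))
    stop("point behind camera: non-positive depth in camera frame")
  f_px <- camera$focal_length / camera$pixel_pitch
  cbind(x = camera$principal_point[1] + f_px * pc[, 1] / pc[, 3],
        y = camera$principal_point[2] + f_px * pc[, 2] / pc[, 3])
}

#' @export
print.fgs_camera <- function(x, ...) {
  cat(sprintf(
    "<fgs_camera> f = %.3g mm, pitch = %.3g mm/px, %d x %d px, %d-bit\n",
    x$focal_length, x$pixel_pitch, x$resolution[1], x$resolution[2],
    x$bit_depth))
  cat(sprintf("  position (mm): [%s]\n", paste(signif(x$position, 4),
                                               collapse = ", ")))
  invisible(x)
}

# ---- Homography ------------------------------------------------------------

#' Construct a homography (3x3 projective transform)
#'
#' The stored matrix is normalized so that the lower-right entry equals 1
#' whenever its magnitude exceeds 1e-8 of the largest entry; otherwise the
#' matrix is scaled to unit Frobenius norm and flagged accordingly.
#'
#' @param entries 3x3 numeric matrix (or row-major 9-vector).
#' @return An object of class `fgs_homography`.
#' @export
homography <- function(entries) {
  H <- if (is.matrix(entries)) entries else
    matrix(as.numeric(entries), 3, 3, byrow = TRUE)
  stopifnot(all(dim(H) == c(3, 3)))
  if (abs(det(H)) < .Machine$double.eps)
    stop("homography must be invertible (determinant != 0)")
  if (abs(H[3, 3]) > 1e-8 * max(abs(H))) {
    H <- H / H[3, 3]
    convention <- "h33"
  } else {
    H <- H / sqrt(sum(H^2))
    convention <- "frobenius"
  }
  structure(list(entries = H, convention = convention),
            class = "fgs_homography")
}

#' @export
print.fgs_homography <- function(x, ...) {
  cat(sprintf("<fgs_homography> (normalization: %s)\n", x$convention))
  print(signif(x$entries, 6))
  invisible(x)
}

#' Identity homography
#' @return An `fgs_homography` equal to the identity map.
#' @export
identity_homography <- function() homography(diag(3))

#' Invert a homography
#' @param H An `fgs_homography`.
#' @return The inverse `fgs_homography`.
#' @export
invert_homography <- function(H) {
  stopifnot(inherits(H, "fgs_homography"))
  homography(solve(H$entries))
}

#' Point correspondences for projective fitting
#'
#' Validates a set of matched sub-pixel source/target coordinates: at least
#' four pairs are required, and when exactly four are supplied no three
#' source or target points may be collinear (tolerance 1e-6 of the
#' bounding-box diagonal).
#'
#' @param src,dst n x 2 matrices of 0-based pixel coordinates.
#' @return An object of class `fgs_correspondences`.
#' @export
point_correspondences <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2)
  if (nrow(src) != nrow(dst))
    stop("source and target must have the same number of points")
  if (nrow(src) < 4)
    stop("at least 4 point correspondences are required")
  if (nrow(src) == 4) {
    check_not_collinear(src, "source")
    check_not_collinear(dst, "target")
  }
  structure(list(src = src, dst = dst), class = "fgs_correspondences")
}

check_not_collinear <- function(pts, label, tol_frac = 1e-6) {
  rng <- apply(pts, 2, range)
  diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  tol <- tol_frac * max(diag_len, .Machine$double.eps)
  idx <- utils::combn(nrow(pts), 3)
  for (k in seq_len(ncol(idx))) {
    a <- pts[idx[1, k], ]; b <- pts[idx[2, k], ]; c <- pts[idx[3, k], ]
    ab <- b - a; ac <- c - a
    len <- sqrt(sum(ab^2))
    # perpendicular distance of c from line ab
    d <- if (len == 0) 0 else abs(ab[1] * ac[2] - ab[2] * ac[1]) / len
    if (d < tol)
      stop(sprintf("degenerate configuration: three %s points are collinear",
                   label))
  }
  invisible(TRUE)
}

hartley_normalization <- function(pts) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  mean_dist <- mean(sqrt(rowSums(centered^2)))
  s <- if (mean_dist > 0) sqrt(2) / mean_dist else 1
  T <- matrix(c(s, 0, 0,
                0, s, 0,
                -s * ctr[1], -s * ctr[2], 1), 3, 3)
  T
}

#' Fit a projective transform by the direct linear transform (DLT)
#'
#' Least-squares homography estimation with Hartley pre-normalization
#' (translate to centroid, scale mean distance to sqrt(2)); over-determined
#' systems are solved by singular-value decomposition, taking the singular
#' vector of the smallest singular value.  With exactly four non-degenerate
#' pairs the fit is exact.
#'
#' @param corr An `fgs_correspondences` object, or an n x 2 source matrix if
#'   `dst` is supplied.
#' @param dst Optional n x 2 target matrix.
#' @return An `fgs_homography` mapping source to target coordinates, with
#'   attribute `residual` (RMS reprojection residual in target pixels).
#' @export
fit_projective_transform <- function(corr, dst = NULL) {
  if (!inherits(corr, "fgs_correspondences"))
    corr <- point_correspondences(corr, dst)
  src <- corr$src; dstp <- corr$dst
  Ts <- hartley_normalization(src)
  Td <- hartley_normalization(dstp)
  sh <- cbind(src, 1) %*% t(Ts)
  dh <- cbind(dstp, 1) %*% t(Td)
  n <- nrow(sh)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- sh[i, ]; x <- dh[i, 1]; y <- dh[i, 2]; w <- dh[i, 3]
    A[2 * i - 1, ] <- c(rep(0, 3), -w * X, y * X)
    A[2 * i, ]     <- c(w * X, rep(0, 3), -x * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(det(H)) < 1e-14 * max(abs(H))^3)
    stop("degenerate configuration: fitted transform is singular")
  out <- homography(H)
  pred <- transform_points(out, src)
  attr(out, "residual") <- sqrt(mean(rowSums((pred - dstp)^2)))
  out
}

#' Apply a homography to pixel coordinates
#'
#' Homogeneous multiplication followed by perspective division.  Points
#' mapping to the plane at infinity (|w| < 1e-12) raise an error.
#'
#' @param H An `fgs_homography`.
#' @param points n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(H, points) {
  stopifnot(inherits(H, "fgs_homography"))
  p <- if (is.null(dim(points))) matrix(points, 1, 2) else as.matrix(points)
  ph <- cbind(p, 1) %*% t(H$entries)
  if (any(abs(ph[, 3]) < 1e-12))
    stop("point maps to the plane at infinity (|w| < 1e-12)")
  cbind(x = ph[, 1] / ph[, 3], y = ph[, 2] / ph[, 3])
}

#' Warp an image by a homography
#'
#' Inverse-mapping warp: each output pixel is sampled at `solve(H)` applied
#' to its coordinate.  Pixels sampling outside the source are filled with 0.
#'
#' @param H An `fgs_homography` mapping source pixel coordinates to output
#'   pixel coordinates.
#' @param image Numeric matrix (rows = y, cols = x).
#' @param output_shape `c(rows, cols)` of the output; defaults to the input
#'   shape.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Numeric matrix of shape `output_shape`.
#' @export
warp_image <- function(H, image, output_shape = dim(image),
                       interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(H, "fgs_homography"))
  interpolation <- match.arg(interpolation)
  if (length(image) == 0) stop("image must be non-empty")
  Hi <- solve(H$entries)
  nr <- output_shape[1]; nc <- output_shape[2]
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  w <- Hi[3, 1] * xs + Hi[3, 2] * ys + Hi[3, 3]
  bad <- abs(w) < 1e-12
  w[bad] <- 1
  sx <- (Hi[1, 1] * xs + Hi[1, 2] * ys + Hi[1, 3]) / w
  sy <- (Hi[2, 1] * xs + Hi[2, 2] * ys + Hi[2, 3]) / w
  out <- sample_image(image, sx, sy, interpolation)
  out[bad] <- 0
  matrix(out, nr, nc)
}

# Bilinear / nearest sampling at 0-based real coordinates; outside -> 0.
sample_image <- function(image, sx, sy, interpolation = "bilinear") {
  nr <- nrow(image); nc <- ncol(image)
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= nc - 1 & iy >= 0 & iy <= nr - 1
    v <- numeric(length(sx))
    v[ok] <- image[cbind(iy[ok] + 1, ix[ok] + 1)]
    return(v)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  v <- numeric(length(sx))
  # accumulate the four bilinear taps, treating out-of-range taps as 0
  for (k in 1:4) {
    dx <- (k - 1) %% 2; dy <- (k - 1) %/% 2
    xi <- x0 + dx; yi <- y0 + dy
    wgt <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1 & wgt > 0
    if (any(ok))
      v[ok] <- v[ok] + wgt[ok] * image[cbind(yi[ok] + 1, xi[ok] + 1)]
  }
  v
}

# ---- JSON serialization ----------------------------------------------------

#' Serialize a homography to JSON
#'
#' Row-major 9-entry list plus the normalization convention tag.
#'
#' @param H An `fgs_homography`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
homography_to_json <- function(H, path = NULL) {
  stopifnot(inherits(H, "fgs_homography"))
  obj <- list(entries = as.numeric(t(H$entries)), convention = H$convention)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a homography from JSON
#' @param x JSON string or path to a JSON file written by
#'   [homography_to_json()].
#' @return An `fgs_homography`.
#' @export
homography_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  homography(matrix(obj$entries, 3, 3, byrow = TRUE))
}
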