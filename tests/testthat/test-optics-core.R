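# Pinhole projection and homography estimation.

test_that("points on the optical axis project to the principal point", {
  cam <- camera_model(resolution = c(640, 480))
  for (depth in c(50, 500, 5000)) {
    p <- project_points(cam, c(0, 0, depth))
    expect_equal(as.numeric(p), cam$principal_point, tolerance = 1e-12)
  }
})

test_that("off-axis projection matches the closed-form pinhole model", {
  cam <- camera_model(focal_length = 3.04, pixel_pitch = 0.00112,
                      resolution = c(3280, 2464))
  p <- project_points(cam, c(69.5, 0, 500))
  # closed form: f * X / Z / pitch
  expect_equal(p[1] - cam$principal_point[1], 3.04 * 69.5 / 500 / 0.00112,
               tolerance = 1e-12)
  expect_equal(p[2], cam$principal_point[2], tolerance = 1e-12)
})

test_that("non-positive depth raises a behind-camera error", {
  cam <- camera_model()
  expect_error(project_points(cam, c(0, 0, 0)), "behind camera")
  expect_error(project_points(cam, c(10, 10, -5)), "behind camera")
})

test_that("camera model validates its invariants", {
  expect_error(camera_model(focal_length = 0), "focal_length")
  expect_error(camera_model(pixel_pitch = -1), "pixel_pitch")
  bad <- diag(3); bad[1, 1] <- 1 + 1e-6
  expect_error(camera_model(orientation = bad), "orthonormal")
  # axis-angle input produces a proper rotation
  cam <- camera_model(orientation = rotation_axis_angle(c(0, 0, 1), 30))
  expect_equal(det(cam$orientation), 1, tolerance = 1e-12)
})

test_that("minimal homography fits are exact: identity and translation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H_id <- fit_projective_transform(sq, sq)
  expect_equal(H_id$entries, diag(3), tolerance = 1e-9)
  H_tr <- fit_projective_transform(sq, sweep(sq, 2, c(-5, 3)))
  expect_equal(H_tr$entries,
               matrix(c(1, 0, 5, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
  expect_lt(attr(H_tr, "residual"), 1e-9)
})

test_that("a random ground-truth homography is recovered from 8 points", {
  set.seed(7)
  for (rep in 1:5) {
    H_true <- diag(3) + matrix(stats::rnorm(9, sd = 0.05), 3, 3)
    H_true[3, 3] <- 1
    src <- matrix(stats::runif(16, 0, 100), 8, 2)
    dst <- transform_points(homography(H_true), src)
    H_fit <- fit_projective_transform(src, dst)
    expect_equal(H_fit$entries, homography(H_true)$entries,
                 tolerance = 1e-9)
    expect_lt(attr(H_fit, "residual"), 1e-9)
  }
})

test_that("degenerate correspondences are rejected by name", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(point_correspondences(sq[1:3, ], sq[1:3, ]), "at least 4")
  col <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 0))
  expect_error(point_correspondences(col, sq), "collinear")
})

test_that("transform_points round-trips through the inverse", {
  set.seed(11)
  H <- homography(diag(3) + matrix(stats::rnorm(9, sd = 0.03), 3, 3))
  pts <- matrix(stats::runif(200, 0, 300), 100, 2)
  back <- transform_points(invert_homography(H), transform_points(H, pts))
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
  # a pure translation moves every point by the same offset
  H_tr <- homography(matrix(c(1, 0, 4.5, 0, 1, -2.25, 0, 0, 1), 3, 3,
                            byrow = TRUE))
  moved <- transform_points(H_tr, pts)
  expect_equal(moved - pts, matrix(rep(c(4.5, -2.25), each = 100), 100, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("points mapping to the plane at infinity raise an error", {
  H <- homography(matrix(c(1, 0, 0, 0, 1, 0, 1, 0, 1), 3, 3, byrow = TRUE))
  expect_error(transform_points(H, c(-1, 5)), "infinity")
})

test_that("warp_image reproduces its input under identity and shifts", {
  set.seed(3)
  img <- matrix(stats::runif(30 * 40), 30, 40)
  expect_equal(warp_image(identity_homography(), img), img,
               tolerance = 1e-12)
  H <- homography(matrix(c(1, 0, 3, 0, 1, 2, 0, 0, 1), 3, 3, byrow = TRUE))
  shifted <- warp_image(H, img, interpolation = "nearest")
  # output pixel (x, y) samples source (x - 3, y - 2)
  expect_equal(shifted[3:30, 4:40], img[1:28, 1:37], tolerance = 1e-12)
  expect_true(all(shifted[1:2, ] == 0))
})

test_that("warp round trip on a smooth 8-bit image stays within 2 levels", {
  xs <- seq(0, 1, length.out = 64)
  img <- outer(xs, xs, function(a, b)
    0.5 + 0.4 * sin(2 * pi * a) * cos(2 * pi * b))
  img <- round(img * 255) / 255
  H <- homography(matrix(c(cos(0.05), -sin(0.05), 2,
                           sin(0.05), cos(0.05), -1,
                           1e-5, 0, 1), 3, 3, byrow = TRUE))
  back <- warp_image(invert_homography(H), warp_image(H, img))
  interior <- 6:59
  expect_lt(mean(abs(back[interior, interior] - img[interior, interior])),
            2 / 2^8)
})

test_that("warp rejects empty input and non-invertible transforms", {
  expect_error(warp_image(identity_homography(), matrix(numeric(), 0, 0)),
               "non-empty")
  expect_error(homography(matrix(0, 3, 3)), "invertible")
})

test_that("one homography aligns shared-center cameras at every depth", {
  base <- default_audit_camera()
  # in-plane sensor shift plus a small rotation about the optical axis
  shifted <- camera_model(
    focal_length = base$focal_length, pixel_pitch = base$pixel_pitch,
    resolution = base$resolution,
    principal_point = base$principal_point + c(3.7, 12.2),
    orientation = rotation_axis_angle(c(0, 0, 1), 0.5))
  fid <- cbind(c(-40, 40, 40, -40), c(-40, -40, 40, 40))
  world <- function(d) cbind(fid, d)
  H <- fit_projective_transform(project_points(shifted, world(500)),
                                project_points(base, world(500)))
  for (d in seq(300, 700, by = 50)) {
    pred <- transform_points(H, project_points(shifted, world(d)))
    expect_lt(max(abs(pred - project_points(base, world(d)))), 1e-6)
  }
})

test_that("a translated camera sees a scene-space offset equal to its baseline", {
  base <- default_audit_camera()
  B <- c(26.5, 69.5)
  moved <- camera_model(
    focal_length = base$focal_length, pixel_pitch = base$pixel_pitch,
    resolution = base$resolution, position = c(B, 0))
  for (d in c(350, 500, 650)) {
    pt <- c(10, -20, d)
    dpx <- project_points(moved, pt) - project_points(base, pt)
    expect_equal(as.numeric(dpx) * mm_per_px(base, d), -B,
                 tolerance = 1e-9)
  }
})

test_that("homographies survive a JSON round trip", {
  H <- homography(matrix(c(1.1, 0.02, 5, -0.01, 0.95, -3, 1e-4, 2e-4, 1),
                         3, 3, byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  homography_to_json(H, path)
  H2 <- homography_from_json(path)
  expect_equal(H2$entries, H$entries, tolerance = 1e-12)
  expect_identical(H2$convention, H$convention)
})

test_that("homography normalization falls back to unit Frobenius norm", {
  H <- homography(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0) * 2, 3, 3,
                         byrow = TRUE) + diag(c(0, 0, 1e-12)))
  expect_identical(H$convention, "frobenius")
  expect_equal(sqrt(sum(H$entries^2)), 1, tolerance = 1e-9)
})
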