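# Leak thresholds, SBR tables and maps, overlays, sensitivity fits.

render_card_pair <- function(channel, exposure = 1) {
  cam <- binned_camera(camera_model(), 32)
  ill <- uniform_illumination(nir_ambient = 0.02)
  tgt <- card_target()
  list(on = render_frame(tgt, cam, ill, channel, "on", quantize = FALSE,
                         exposure = exposure)$intensity,
       off = render_frame(tgt, cam, ill, channel, "off", quantize = FALSE,
                          exposure = exposure)$intensity)
}

test_that("identical on/off images mean no detectable leak", {
  img <- matrix(0.4, 8, 8)
  expect_error(leak_threshold(img, img), "no detectable leak")
  expect_error(leak_threshold(img, matrix(0.4, 8, 9)), "equal shape")
})

test_that("the white-card leak reproduces the four filter characterizations", {
  expected <- c("830lp" = 0.53, "dbl_830lp" = 0.082, "832bp" = 0.106,
                "808lp" = 0.090)
  for (nm in names(expected)) {
    pair <- render_card_pair(filter_channel(nm))
    expect_equal(leak_threshold(pair$on, pair$off), unname(expected[nm]),
                 tolerance = 1e-6)
  }
})

test_that("the leak threshold equals leak times peak irradiance", {
  ch <- filter_channel("dbl_830lp")
  cam <- binned_camera(camera_model(), 32)
  ill <- illumination_model(nir_ambient = 0.02)   # converging-beam array
  tgt <- card_target()
  on <- render_frame(tgt, cam, ill, ch, "on", quantize = FALSE,
                     supersample = 1)$intensity
  off <- render_frame(tgt, cam, ill, ch, "off", quantize = FALSE,
                      supersample = 1)$intensity
  # oracle: max of the rendered irradiance field at pixel centers
  fn <- irradiance_fn(ill, 500)
  f_px <- cam$focal_length / cam$pixel_pitch
  xs <- rep(seq_len(cam$resolution[1]) - 1, each = cam$resolution[2])
  ys <- rep(seq_len(cam$resolution[2]) - 1, times = cam$resolution[1])
  Emax <- max(fn((xs - cam$principal_point[1]) / f_px * 500,
                 (ys - cam$principal_point[2]) / f_px * 500))
  expect_equal(leak_threshold(on, off), ch$leak * Emax, tolerance = 1e-9)
})

test_that("well SBR follows the forward-model oracle 1 + kC/l", {
  plate <- default_ir125_phantom()
  cam <- default_audit_camera()
  tgt <- planar_target(plate, distance = 450, extent = c(160, 120),
                       reflectance = 0.05)
  rois <- well_rois(plate, cam, 450)
  ch <- filter_channel("dbl_830lp")
  ill <- uniform_illumination(nir_ambient = 0.02)
  on <- render_frame(tgt, cam, ill, ch, "on", exposure = 0.15,
                     quantize = FALSE)$intensity
  off <- render_frame(tgt, cam, ill, ch, "off", exposure = 0.15,
                      quantize = FALSE)$intensity
  res <- well_sbr(on, off, rois)
  # control against itself
  expect_equal(res$wells$sbr[res$wells$is_control], 1, tolerance = 1e-12)
  ideal <- 1 + ch$gain * res$curve$concentration / ch$leak
  expect_equal(res$curve$sbr, ideal, tolerance = 1e-6)
  # local log-log slope far above the knee is within 0.05 of 1
  knee <- ch$leak / ch$gain
  hi <- res$curve[res$curve$concentration >= 25 * knee, ]
  sl <- diff(log10(hi$sbr)) / diff(log10(hi$concentration))
  expect_true(all(abs(sl - 1) < 0.05))
  # duplicate wells averaged after per-well SBR
  expect_equal(nrow(res$curve),
               length(unique(rois$concentration[rois$concentration > 0])))
})

test_that("SBR is invariant to a global additive background", {
  plate <- default_ir125_phantom()
  cam <- default_audit_camera()
  tgt <- planar_target(plate, distance = 450, extent = c(160, 120))
  rois <- well_rois(plate, cam, 450)
  ch <- filter_channel("dbl_830lp")
  ill <- uniform_illumination(nir_ambient = 0)
  on <- render_frame(tgt, cam, ill, ch, "on", exposure = 0.15,
                     quantize = FALSE)$intensity
  off <- render_frame(tgt, cam, ill, ch, "off", exposure = 0.15,
                      quantize = FALSE)$intensity
  r1 <- well_sbr(on, off, rois)
  r2 <- well_sbr(on + 0.11, off + 0.11, rois)
  expect_equal(r2$wells$sbr, r1$wells$sbr, tolerance = 1e-12)
  m1 <- sbr_map(on, off, 0.01)
  m2 <- sbr_map(on + 0.11, off + 0.11, 0.01)
  expect_equal(unclass(m2), unclass(m1), tolerance = 1e-12)
})

test_that("the SBR map is 1 at leak-equal signal and scales inversely with leak", {
  off <- matrix(0.1, 10, 10)
  leak <- 0.082
  on <- off + leak
  m <- sbr_map(on, off, leak)
  expect_equal(max(abs(unclass(m) - 1)), 0, tolerance = 1e-12)
  expect_true(all(sbr_map(off, off, leak) == 0))
  m2 <- sbr_map(on, off, 2 * leak)
  expect_equal(unclass(m2), unclass(m) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(sbr_map(on, off, 0), "> 0")
})

test_that("peak SBR equals the brute-force maximum", {
  expect_equal(peak_sbr(sbr_map(matrix(0.5, 5, 5), matrix(0.2, 5, 5), 0.1)),
               3, tolerance = 1e-12)
  hot <- matrix(0.1, 9, 9); hot[4, 7] <- 0.9
  expect_equal(peak_sbr(sbr_map(hot, matrix(0, 9, 9), 0.1)), 9,
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:5) {
    on <- matrix(stats::runif(64), 8, 8); off <- matrix(stats::runif(64), 8, 8)
    m <- sbr_map(on, off, 0.3)
    brute <- -Inf
    for (i in 1:8) for (j in 1:8) brute <- max(brute, m[i, j])
    expect_equal(peak_sbr(m), brute)
  }
})

test_that("well-SBR and the SBR map agree algebraically", {
  plate <- default_ir125_phantom()
  cam <- default_audit_camera()
  tgt <- planar_target(plate, distance = 450, extent = c(160, 120))
  rois <- well_rois(plate, cam, 450)
  ch <- filter_channel("dbl_830lp")
  ill <- uniform_illumination(nir_ambient = 0.02)
  on <- render_frame(tgt, cam, ill, ch, "on", exposure = 0.15,
                     quantize = FALSE)$intensity
  off <- render_frame(tgt, cam, ill, ch, "off", exposure = 0.15,
                      quantize = FALSE)$intensity
  res <- well_sbr(on, off, rois)
  leak <- leak_threshold(on, off)
  m <- sbr_map(on, off, leak)
  ctrl <- res$wells$signal[res$wells$is_control]
  for (i in which(!res$wells$is_control)[c(3, 8, 15)]) {
    map_mean <- mean(roi_values_for_test(unclass(m), res$wells$cx_px[i],
                                         res$wells$cy_px[i],
                                         res$wells$radius_px[i]))
    expect_equal(map_mean, res$wells$sbr[i] * ctrl / leak,
                 tolerance = 1e-9)
  }
})

test_that("overlays mask below threshold and count opaque pixels", {
  vis <- matrix(0.5, 20, 20)
  on <- matrix(0.1, 20, 20); on[5:8, 5:8] <- 0.9
  m <- sbr_map(on, matrix(0.1, 20, 20), 0.2)
  # all below threshold: output equals the visible image
  low <- sbr_map(matrix(0.11, 20, 20), matrix(0.1, 20, 20), 0.2)
  out_low <- overlay(low, vis, threshold = 1.5)
  for (ch in 1:3) expect_equal(out_low[, , ch], vis, tolerance = 1e-12)
  expect_equal(attr(out_low, "opaque_count"), 0)
  # identity H, alpha 1: masked region is pure false color
  out <- overlay(m, vis, alpha = 1, threshold = 1.5)
  expect_equal(attr(out, "opaque_count"), sum(unclass(m) >= 1.5))
  expect_equal(attr(out, "opaque_count"), 16)
  untouched <- out[1, 1, ]
  expect_equal(untouched, rep(0.5, 3), tolerance = 1e-12)
})

test_that("the warped overlay mask count follows the homography", {
  vis <- matrix(0.2, 30, 30)
  on <- matrix(0, 30, 30); on[10:14, 10:14] <- 1
  m <- sbr_map(on, matrix(0, 30, 30), 0.25)
  H <- homography(matrix(c(1, 0, 3, 0, 1, -2, 0, 0, 1), 3, 3, byrow = TRUE))
  out <- overlay(m, vis, H = H, threshold = 1.5, interpolation = "nearest")
  expect_equal(attr(out, "opaque_count"), 25)
})

test_that("sensitivity fits recover a unit slope on oracle data", {
  x <- 10^seq(1, 3, length.out = 8)        # kC/l from 10 to 1000
  leak <- 0.0041; gain <- 2.05e6
  conc <- x * leak / gain
  curve <- data.frame(concentration = conc, sbr = 1 + x)
  fit <- fit_sensitivity(curve)
  expect_true(fit$available)
  expect_equal(fit$slope, 1, tolerance = 0.02)
  expect_equal(nrow(fit$curve[fit$curve$region == "plateau", ]), 0)
  expect_true(is.na(fit$plateau))
})

test_that("all-plateau data leaves the fit unavailable with plateau near 1", {
  curve <- data.frame(concentration = c(1e-10, 2e-10, 4e-10),
                      sbr = c(1.01, 1.05, 1.1))
  fit <- fit_sensitivity(curve)
  expect_false(fit$available)
  expect_equal(fit$plateau, mean(curve$sbr), tolerance = 1e-12)
  expect_true(is.na(fit$slope))
})

test_that("region membership is monotone for monotone curves", {
  conc <- c(2.5e-10, 5e-10, 1e-9, 5e-9, 1e-8, 1e-7)
  curve <- data.frame(concentration = conc, sbr = 1 + conc / 2e-9)
  fit <- fit_sensitivity(curve)
  plat <- fit$curve$concentration[fit$curve$region == "plateau"]
  lin <- fit$curve$concentration[fit$curve$region == "linear"]
  expect_true(max(plat) < min(lin))
  expect_error(fit_sensitivity(data.frame(concentration = c(0, 1e-9, 1e-8),
                                          sbr = c(1, 2, 3))),
               "strictly positive")
})
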