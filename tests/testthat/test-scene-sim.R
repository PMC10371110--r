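# Synthetic scene generation: illumination, forward model, pattern
# rasterization, frame rendering and laser-synchronized streams.

test_that("beams converge at L: centers coincide and peaks add", {
  ill <- illumination_model(n_beams = 3, d = 30, L = 400, beam_peak = 22,
                            beam_radius = 5, beam_divergence = 0.01)
  fn <- irradiance_fn(ill, 400)
  w <- ill$beam_radius + ill$beam_divergence * 400
  single_peak <- ill$beam_peak * (ill$beam_radius / w)^2
  expect_equal(fn(0, 0), 3 * single_peak, tolerance = 1e-12)
})

test_that("a single on-axis beam gives a radially symmetric map", {
  ill <- illumination_model(n_beams = 1, d = 0)
  m <- irradiance_map(ill, 500, extent = c(60, 60), res = 2)$irradiance
  expect_lt(max(abs(m - m[rev(seq_len(nrow(m))), ])), 1e-9)
  expect_lt(max(abs(m - m[, rev(seq_len(ncol(m)))])), 1e-9)
  expect_lt(max(abs(m - t(m))), 1e-9)
})

test_that("the area above a threshold is maximal at the convergence distance", {
  ill <- illumination_model()
  # threshold above any single displaced beam but below the combined peak,
  # so only the converged superposition clears it
  area_above <- function(distance) {
    m <- irradiance_map(ill, distance, extent = c(120, 120), res = 2)
    sum(m$irradiance >= 15) * m$pixel_scale^2
  }
  a <- vapply(c(0.8, 1, 1.2) * ill$L, area_above, numeric(1))
  expect_gt(a[2], a[1])
  expect_gt(a[2], a[3])
})

test_that("detected intensity follows the leak/fluorescence algebra", {
  ch <- optical_channel("nir", leak = 0.005, gain = 1e6)
  E <- c(0, 1, 5, 20)
  # leak-only when C = 0, ambient = 0
  expect_equal(detected_intensity(0, E, ch), 0.005 * E)
  # exactly linear in C below saturation when leak and ambient are absent
  ch0 <- optical_channel("nir", leak = 0, gain = 1e6)
  C <- c(1e-9, 2e-9, 4e-9)
  expect_equal(detected_intensity(C, 10, ch0), 1e6 * C * 10)
  # monotone and saturating at 1
  expect_equal(detected_intensity(1, 100, ch), 1)
  expect_error(detected_intensity(-1, 1, ch), "non-negative")
})

test_that("the implied SBR curve is log-log linear with a unit slope then flat", {
  leak <- 0.0041; gain <- 2.05e6
  sbr <- function(C) 1 + gain * C / leak   # (kCE + lE) / lE
  # slope 1 when fluorescence dominates the leak
  C_hi <- c(1e-7, 1e-6)
  slope_hi <- diff(log10(sbr(C_hi))) / diff(log10(C_hi))
  expect_equal(slope_hi, 1, tolerance = 0.02)
  # plateau at 1 when the leak dominates
  C_lo <- c(1e-12, 1e-11)
  expect_equal(sbr(C_lo), c(1, 1), tolerance = 0.01)
  slope_lo <- diff(log10(sbr(C_lo))) / diff(log10(C_lo))
  expect_lt(slope_lo, 0.01)
})

test_that("visible channels force zero leak and gain", {
  ch <- optical_channel("visible", leak = 0.5, gain = 100)
  expect_equal(ch$leak, 0)
  expect_equal(ch$gain, 0)
})

test_that("filter presets are ordered by leak as measured on the bench", {
  leaks <- vapply(c("830lp", "832bp", "808lp", "dbl_830lp"),
                  function(nm) filter_channel(nm)$leak, numeric(1))
  expect_true(all(diff(leaks) < 0))
  expect_equal(unname(leaks["830lp"]) * 20, 0.53, tolerance = 1e-12)
})

test_that("render_pattern places fiducials and line pairs at ground truth", {
  # empty spec: uniform background
  empty <- resolution_target_spec(
    data.frame(cx = numeric(), cy = numeric(), side = numeric()))
  rp <- render_pattern(empty, res = 5, extent = c(20, 20))
  expect_true(all(rp$image == empty$background))
  # one fiducial: rendered centroid within 0.05 px of ground truth
  one <- resolution_target_spec(
    data.frame(cx = 3.37, cy = -2.81, side = 6))
  rp <- render_pattern(one, res = 10, extent = c(40, 40))
  w <- rp$image
  xs <- (seq_len(ncol(w)) - 1); ys <- (seq_len(nrow(w)) - 1)
  cx <- sum(w %*% cbind(xs)) / sum(w)
  cy <- sum(rbind(ys) %*% w) / sum(w)
  expect_lt(abs(cx - rp$fiducials_px[1, "x"]), 0.05)
  expect_lt(abs(cy - rp$fiducials_px[1, "y"]), 0.05)
  # bar spacing equals one line-pair period
  tgt <- default_alignment_target(freq = 0.125)
  bars <- bar_positions(tgt)
  for (b in bars) {
    expect_equal(unique(round(diff(b$centers), 9)), 1 / 0.125)
  }
})

test_that("overlapping line-pair groups are rejected", {
  fid <- data.frame(cx = c(-40, 40, 40, -40), cy = c(-40, -40, 40, 40),
                    side = 10)
  grp <- data.frame(label = c("a", "b"), freq = 0.125, bars = 4L,
                    orientation = "vertical", cx = c(0, 2), cy = 0,
                    length = 20)
  expect_error(resolution_target_spec(fid, grp), "overlap")
})

test_that("ambient-only frames are uniform and renders are deterministic", {
  cam <- small_cam()
  ill <- illumination_model(nir_ambient = 0.07)
  ch <- filter_channel("dbl_830lp")
  tgt <- card_target()
  f_off <- render_frame(tgt, cam, ill, ch, "off", quantize = FALSE)
  expect_equal(max(f_off$intensity) - min(f_off$intensity), 0)
  expect_equal(f_off$intensity[1, 1], 0.07, tolerance = 1e-12)
  noise <- noise_model(seed = 99)
  f1 <- render_frame(tgt, cam, ill, ch, "on", noise = noise, frame_index = 4L)
  f2 <- render_frame(tgt, cam, ill, ch, "on", noise = noise, frame_index = 4L)
  expect_identical(f1$intensity, f2$intensity)
  f3 <- render_frame(tgt, cam, ill, ch, "on", noise = noise, frame_index = 5L)
  expect_false(identical(f1$intensity, f3$intensity))
})

test_that("laser-on minus laser-off recovers the leak map exactly", {
  cam <- small_cam()
  ill <- illumination_model(nir_ambient = 0.05)
  ch <- filter_channel("dbl_830lp")
  tgt <- card_target()
  on <- render_frame(tgt, cam, ill, ch, "on", quantize = FALSE,
                     supersample = 1)
  off <- render_frame(tgt, cam, ill, ch, "off", quantize = FALSE,
                      supersample = 1)
  diff <- on$intensity - off$intensity
  # oracle: leak * E at each back-projected pixel center
  fn <- irradiance_fn(ill, 500)
  f_px <- cam$focal_length / cam$pixel_pitch
  xs <- rep(seq_len(cam$resolution[1]) - 1, each = cam$resolution[2])
  ys <- rep(seq_len(cam$resolution[2]) - 1, times = cam$resolution[1])
  px <- (xs - cam$principal_point[1]) / f_px * 500
  py <- (ys - cam$principal_point[2]) / f_px * 500
  oracle <- matrix(ch$leak * fn(px, py), cam$resolution[2])
  expect_equal(diff, oracle, tolerance = 1e-12)
})

test_that("plane behind the camera is an error", {
  cam <- camera_model(position = c(0, 0, 600))
  expect_error(render_frame(card_target(500), cam, illumination_model(),
                            optical_channel("visible"), "off"),
               "behind camera")
})

test_that("streams alternate laser state with configurable phase and duty", {
  cam <- binned_camera(camera_model(), 32)
  ill <- uniform_illumination(nir_ambient = 0.02)
  ch <- filter_channel("dbl_830lp")
  tgt <- card_target(concentration = 5e-9)
  st <- generate_stream(tgt, cam, ill, ch, n_frames = 4, fps = 30,
                        duty = 0.7, quantize = FALSE)
  states <- vapply(st$frames, function(f) f$laser_state, character(1))
  expect_equal(states, c("off", "on", "off", "on"))
  expect_equal(st$period_ms, 33)
  expect_equal(vapply(st$frames, function(f) f$t_ms, numeric(1)),
               c(0, 33, 66, 99))
  st0 <- generate_stream(tgt, cam, ill, ch, n_frames = 4, phase = 0L,
                         quantize = FALSE)
  expect_equal(vapply(st0$frames, function(f) f$laser_state, character(1)),
               c("on", "off", "on", "off"))
  # on-frame excitation scales with the exposure-overlap factor
  st1 <- generate_stream(tgt, cam, ill, ch, n_frames = 4, duty = 1,
                         quantize = FALSE)
  exc07 <- mean(st$frames[[2]]$intensity - st$frames[[1]]$intensity)
  exc10 <- mean(st1$frames[[2]]$intensity - st1$frames[[1]]$intensity)
  expect_equal(exc07 / exc10, 0.7, tolerance = 1e-9)
  expect_error(generate_stream(tgt, cam, ill, ch, duty = 1.2), "duty")
  expect_error(generate_stream(tgt, cam, ill, ch, n_frames = 1), "n_frames")
})

test_that("a leading exposure window produces bleed-through above 70% duty", {
  cam <- binned_camera(camera_model(), 32)
  ill <- uniform_illumination(nir_ambient = 0)
  ch <- filter_channel("dbl_830lp")
  tgt <- card_target(concentration = 5e-9)
  st <- generate_stream(tgt, cam, ill, ch, n_frames = 5, duty = 0.9,
                        exposure_offset = 0.3, quantize = FALSE)
  on_mean <- mean(st$frames[[2]]$intensity)
  bleed_mean <- mean(st$frames[[3]]$intensity)  # frame after laser-on
  clean_off <- mean(st$frames[[1]]$intensity)
  expect_gt(bleed_mean, clean_off + 1e-6)
  # overlap split: 0.7 into the on frame, 0.2 into the next
  expect_equal(bleed_mean / on_mean, 0.2 / 0.7, tolerance = 1e-9)
})

test_that("identical seeds reproduce identical streams bit-for-bit", {
  cam <- binned_camera(camera_model(), 32)
  ill <- uniform_illumination()
  ch <- filter_channel("dbl_830lp")
  tgt <- card_target(concentration = 1e-8)
  noise <- noise_model(seed = 123)
  s1 <- generate_stream(tgt, cam, ill, ch, n_frames = 4, noise = noise)
  s2 <- generate_stream(tgt, cam, ill, ch, n_frames = 4, noise = noise)
  expect_identical(lapply(s1$frames, `[[`, "intensity"),
                   lapply(s2$frames, `[[`, "intensity"))
})

test_that("frame and stream invariants are enforced", {
  expect_error(frame(matrix(2, 2, 2)), "\\[0, 1\\]")
  f1 <- frame(matrix(0.5, 2, 2), t_ms = 0)
  f2 <- frame(matrix(0.5, 2, 2), t_ms = 33)
  expect_error(frame_stream(list(f1, f2), period_ms = 33, fps = 40),
               "within 1%")
  f_bad <- frame(matrix(0.5, 2, 2), t_ms = 20)
  expect_error(frame_stream(list(f1, f_bad), period_ms = 33),
               "frame period")
})
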