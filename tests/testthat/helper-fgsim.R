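# Shared fixtures: desk-scale cameras and targets kept small so rendering
# stays fast.

audit_cam <- function() default_audit_camera()            # 410 x 308
small_cam <- function() binned_camera(camera_model(), 16) # 205 x 154

small_target <- function(distance = 500)
  planar_target(default_alignment_target(), distance = distance)

card_target <- function(distance = 500, reflectance = 1, concentration = 0)
  planar_target(NULL, distance = distance, extent = c(700, 700),
                reflectance = reflectance, concentration = concentration)

# Hand-built stream of explicit intensity matrices (period 33 ms, 30 fps)
matrix_stream <- function(mats, states = rep(NA_character_, length(mats))) {
  frames <- lapply(seq_along(mats), function(i)
    frame(mats[[i]], t_ms = (i - 1) * 33, laser_state = states[i]))
  frame_stream(frames, period_ms = 33, fps = 30)
}

# internal circular-ROI reader used for map/table consistency checks
roi_values_for_test <- function(image, cx, cy, radius)
  fgsim:::roi_values(image, cx, cy, radius)

# fiducial-only chart (no bar groups): robust detection at coarse
# resolutions where bars blur together
fid_target <- function(distance = 500) {
  spec <- resolution_target_spec(
    data.frame(cx = c(-40, 40, 40, -40), cy = c(-40, -40, 40, 40),
               side = 13))
  planar_target(spec, distance = distance)
}
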