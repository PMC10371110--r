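# File-based experiment configuration (YAML or JSON).

#' Read an experiment configuration from YAML or JSON
#'
#' The file holds named blocks mapped onto [experiment_config()]:
#' `seed`, `camera` (fields of [camera_model()] plus optional `bin`),
#' `geometry` (`preset`, `offset_mm`, `sensor_shift_px`), `illumination`
#' (fields of [illumination_model()], or `uniform: <irradiance>`),
#' `channel` (`filter` preset name, or `leak`/`gain`), `noise`
#' (`shot_scale`, `read_sd`; `false` disables noise), and scalar
#' processing parameters (`d_cal`, `distances`, `duty`, `fps`,
#' `n_frames`, `n_replicates`, `exposure`, `sbr_threshold`).  Lengths are
#' mm; `cm` and `um` suffixed keys (e.g. `d_cal_cm`) are converted.
#' Unknown keys raise an error naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `fgs_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  known <- c("seed", "camera", "geometry", "illumination", "channel",
             "noise", "d_cal", "d_cal_cm", "distances", "distances_cm",
             "duty", "fps", "n_frames", "n_replicates", "exposure",
             "sbr_threshold")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unresolvable config keys: ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$seed)) args$seed <- as.integer(raw$seed)
  if (!is.null(raw$camera)) {
    cb <- raw$camera
    bin <- if (is.null(cb$bin)) 1 else cb$bin
    cb$bin <- NULL
    cam <- do.call(camera_model, cb)
    args$camera <- if (bin > 1) binned_camera(cam, bin) else cam
  }
  if (!is.null(raw$geometry))
    args$geometry <- do.call(mount_geometry, raw$geometry)
  if (!is.null(raw$illumination)) {
    ib <- raw$illumination
    args$illumination <- if (!is.null(ib$uniform))
      uniform_illumination(ib$uniform) else do.call(illumination_model, ib)
  }
  if (!is.null(raw$channel)) {
    chb <- raw$channel
    args$channel <- if (!is.null(chb$filter)) filter_channel(chb$filter)
      else do.call(optical_channel, c(list(kind = "nir"), chb))
  }
  if (!is.null(raw$noise)) {
    args$noise <- if (identical(raw$noise, FALSE)) NULL
      else do.call(noise_model, raw$noise)
  }
  if (!is.null(raw$d_cal_cm)) args$d_cal <- raw$d_cal_cm * 10
  if (!is.null(raw$distances_cm)) args$distances <- raw$distances_cm * 10
  for (key in c("d_cal", "distances", "duty", "fps", "n_frames",
                "n_replicates", "exposure", "sbr_threshold"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(experiment_config, args)
}
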