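# Image and report I/O: frame streams as numbered grayscale PNG/TIFF with
# a JSON sidecar, thermal maps from CSV grids.

#' Write a frame stream to disk
#'
#' Frames are written as numbered 8-bit grayscale PNG (or 8/16-bit TIFF)
#' files plus a `stream.json` sidecar holding timestamps, laser states,
#' the frame rate and bit depth.  An 8-bit-quantized stream survives the
#' PNG round trip bit-exactly.
#'
#' @param stream An `fgs_stream`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` (8-bit) or `"tiff"`.
#' @param bits 8 or 16 (TIFF only; PNG is written at 8 bits).
#' @return The directory path, invisibly.
#' @export
write_stream <- function(stream, dir, format = c("png", "tiff"), bits = 8) {
  stopifnot(inherits(stream, "fgs_stream"))
  format <- match.arg(format)
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") "png" else "tiff"
  for (i in seq_along(stream$frames)) {
    path <- file.path(dir, sprintf("frame_%04d.%s", i - 1, ext))
    img <- stream$frames[[i]]$intensity
    if (format == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path, bits.per.sample = bits)
  }
  sidecar <- list(
    fps = stream$fps, period_ms = stream$period_ms, format = format,
    bits = if (format == "png") 8 else bits,
    n_frames = length(stream$frames),
    timestamps_ms = vapply(stream$frames, function(f) f$t_ms, numeric(1)),
    laser_states = vapply(stream$frames,
                          function(f) as.character(f$laser_state),
                          character(1)),
    channel = stream$frames[[1]]$channel_kind)
  jsonlite::write_json(sidecar, file.path(dir, "stream.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame stream from disk
#'
#' Reads the numbered frames written by [write_stream()].  A missing
#' sidecar yields a stream with unknown laser states (and a warning);
#' parity must then be recovered with [detect_laser_parity()].  Mixed
#' image formats/bit depths in one directory raise an error.
#'
#' @param dir Directory containing `frame_*.png`/`frame_*.tiff` and
#'   optionally `stream.json`.
#' @param fps Frame rate used when the sidecar is absent.
#' @return An `fgs_stream`.
#' @export
read_stream <- function(dir, fps = 30) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(png|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame files found in ", dir)
  exts <- unique(tools::file_ext(files))
  if (length(exts) > 1) stop("mixed image formats in stream directory")
  sidecar_path <- file.path(dir, "stream.json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::fromJSON(sidecar_path)
    fps <- as.numeric(side$fps)
    period <- as.numeric(side$period_ms)
    ts <- as.numeric(side$timestamps_ms)
    states <- side$laser_states
    channel <- side$channel
  } else {
    warning("missing stream.json sidecar: laser states unknown")
    period <- round(1000 / fps)
    ts <- (seq_along(files) - 1) * period
    states <- rep(NA_character_, length(files))
    channel <- "nir"
  }
  frames <- lapply(seq_along(files), function(i) {
    img <- if (exts == "png") png::readPNG(files[i])
           else tiff::readTIFF(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    frame(img, t_ms = ts[i], laser_state = states[i],
          channel_kind = channel)
  })
  frame_stream(frames, period_ms = period, fps = fps)
}

#' Read a thermal map from a CSV grid
#'
#' @param path CSV file of temperatures (rows = y), no header.
#' @param pixel_scale mm per pixel.
#' @param time_label Label stored on the map.
#' @return An `fgs_thermal_map`.
#' @export
read_thermal_csv <- function(path, pixel_scale, time_label = "") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  thermal_map(m, pixel_scale, time_label)
}

#' Write an RGB array or grayscale matrix as PNG
#'
#' @param image Matrix or rows x cols x 3 array with values in [0, 1].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmax(pmin(image, 1), 0), path)
  invisible(path)
}
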