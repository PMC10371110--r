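# Demultiplexing of laser-synchronized streams and real-time
# NIR-background subtraction.

#' Consecutive-frame background subtraction
#'
#' Computes the absolute difference of consecutive frames,
#' `dF[n] = |F[n] - F[n - 1]|`, sliding (one output per input after the
#' first), so the output preserves the full input frame rate.  Under
#' frame-alternating laser excitation this removes any static NIR
#' background (room lights) and leaves the excitation-dependent signal.
#' Differences are taken in double precision, so integer wraparound of
#' quantized inputs cannot occur.
#'
#' @param stream An `fgs_stream` with at least two frames of equal shape.
#' @return An object of class `fgs_subtracted_stream`: list of difference
#'   frames (`frames`, each a matrix), source laser states, timestamps and
#'   `fps` equal to the source rate.
#' @export
background_subtract <- function(stream) {
  stopifnot(inherits(stream, "fgs_stream"))
  n <- length(stream$frames)
  if (n < 2) stop("stream must have at least 2 frames")
  dims <- vapply(stream$frames, function(f) dim(f$intensity), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mismatched frame shapes")
  out <- vector("list", n - 1)
  for (i in 2:n) {
    out[[i - 1]] <- abs(stream$frames[[i]]$intensity -
                          stream$frames[[i - 1]]$intensity)
  }
  structure(list(
    frames = out,
    t_ms = vapply(stream$frames[-1], function(f) f$t_ms, numeric(1)),
    laser_state = vapply(stream$frames[-1],
                         function(f) as.character(f$laser_state),
                         character(1)),
    fps = stream$fps, period_ms = stream$period_ms
  ), class = "fgs_subtracted_stream")
}

#' @export
length.fgs_subtracted_stream <- function(x) length(x$frames)

#' Detect the laser-on frame parity of a stream
#'
#' When laser-state metadata is absent, the parity (even-indexed or
#' odd-indexed frames, 0-based) whose frames have the larger mean
#' intensity is taken as laser-on.  The relative margin between the two
#' parity means is reported; a margin below the threshold raises a
#' "parity ambiguous" error.
#'
#' @param stream An `fgs_stream` with at least 4 frames.
#' @param threshold Minimum relative mean difference (default 1%).
#' @return `"even-on"` or `"odd-on"`, with attribute `margin`.
#' @export
detect_laser_parity <- function(stream, threshold = 0.01) {
  stopifnot(inherits(stream, "fgs_stream"))
  n <- length(stream$frames)
  if (n < 4) stop("at least 4 frames are required to detect parity")
  means <- vapply(stream$frames, function(f) mean(f$intensity), numeric(1))
  idx <- seq_len(n) - 1
  m_even <- mean(means[idx %% 2 == 0])
  m_odd <- mean(means[idx %% 2 == 1])
  denom <- (m_even + m_odd) / 2
  margin <- if (denom > 0) abs(m_even - m_odd) / denom else 0
  if (margin < threshold)
    stop(sprintf("parity ambiguous: relative margin %.3g below %.3g",
                 margin, threshold))
  out <- if (m_even > m_odd) "even-on" else "odd-on"
  attr(out, "margin") <- margin
  out
}

#' Pair laser-on frames with adjacent laser-off frames
#'
#' Consecutive frames are paired two at a time from the start of the
#' stream; within each pair the laser-on frame is identified by the given
#' parity.  An odd leftover frame is dropped with a warning.
#'
#' @param stream An `fgs_stream`.
#' @param parity `"even-on"` or `"odd-on"` (0-based frame indices), e.g.
#'   from [detect_laser_parity()] or stream metadata.
#' @return A list of `list(on =, off =)` pairs of `fgs_frame` objects.
#' @export
pair_on_off <- function(stream, parity = c("odd-on", "even-on")) {
  stopifnot(inherits(stream, "fgs_stream"))
  parity <- match.arg(parity)
  n <- length(stream$frames)
  n_pairs <- n %/% 2
  if (n %% 2 == 1)
    warning(sprintf("odd leftover frame dropped (%d frames -> %d pairs)",
                    n, n_pairs))
  on_first <- parity == "even-on"
  lapply(seq_len(n_pairs), function(k) {
    a <- stream$frames[[2 * k - 1]]   # even 0-based index
    b <- stream$frames[[2 * k]]       # odd 0-based index
    if (on_first) list(on = a, off = b) else list(on = b, off = a)
  })
}

#' Laser trigger schedule for a frame rate
#'
#' The frame period is `round(1000 / fps)` ms, the trigger period twice
#' that (the laser turns on with every other frame), and the on-duration
#' is `duty` of a frame period.
#'
#' @param fps Frame rate (> 0).
#' @param duty On-fraction of a frame period, in (0, 1].
#' @return An object of class `fgs_schedule` with fields `frame_period_ms`,
#'   `trigger_period_ms`, `on_duration_ms`, `duty`.
#' @export
make_schedule <- function(fps = 30, duty = 0.7) {
  if (fps <= 0) stop("fps must be positive")
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  period <- round(1000 / fps)
  structure(list(frame_period_ms = period,
                 trigger_period_ms = 2 * period,
                 on_duration_ms = duty * period,
                 duty = duty), class = "fgs_schedule")
}

#' @export
print.fgs_schedule <- function(x, ...) {
  cat(sprintf(
    "<fgs_schedule> frame %g ms, trigger %g ms, on %g ms (duty %.2f)\n",
    x$frame_period_ms, x$trigger_period_ms, x$on_duration_ms, x$duty))
  invisible(x)
}
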