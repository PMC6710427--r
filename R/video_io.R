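#' Open a video file
#'
#' Decodes the container headers and returns a `video_source` object holding
#' the video's dimensions, frame rate and frame count, plus the information
#' needed to read individual frames on demand. Frames are indexed from 0 and
#' yielded in strictly increasing order.
#'
#' The decoding backend reads uncompressed RGB24 AVI containers (the format
#' [render_video()] emits). Compressed streams and non-RIFF files raise a
#' decode error naming the path.
#'
#' @param path Path to the video file.
#' @param fps Optional override for the container's frame rate, for
#'   recordings whose metadata misreports it.
#' @return A `video_source` with fields `path`, `width`, `height`, `fps` and
#'   `frame_count`.
#' @seealso [read_frame()], [track()], [render_video()]
#' @export
#' @examples
#' spec <- trajectory_spec(
#'   centres = linear_trajectory(c(20, 120), c(2, 0), 30),
#'   shape = shape_disc(8), n_frames = 30, fps = 30,
#'   width = 320, height = 240
#' )
#' out <- render_video(spec, file.path(tempdir(), "blob.avi"))
#' v <- open_video(out$video)
#' v$frame_count
open_video <- function(path, fps = NULL) {
  if (!file.exists(path)) {
    stop("cannot open video '", path, "': file does not exist", call. = FALSE)
  }
  parsed <- parse_avi(path)
  n <- length(parsed$offsets)
  if (n == 0L) {
    stop("video '", path, "' contains no frames", call. = FALSE)
  }
  structure(list(
    path = path,
    width = parsed$meta$width,
    height = parsed$meta$height,
    fps = if (is.null(fps)) parsed$meta$fps else fps,
    frame_count = n,
    .offsets = parsed$offsets,
    .sizes = parsed$sizes
  ), class = "video_source")
}

#' @export
print.video_source <- function(x, ...) {
  cat(sprintf("<video_source> %s\n  %d x %d px, %g fps, %d frames\n",
              x$path, x$width, x$height, x$fps, x$frame_count))
  invisible(x)
}

#' Read a single frame from an open video
#'
#' @param video A `video_source` from [open_video()].
#' @param index 0-based frame index.
#' @return An integer array of dimension `height x width x 3` (RGB, 0-255).
#'   Pixel `(x, y)` in 0-based image coordinates (origin top-left, x
#'   rightward, y downward) is `frame[y + 1, x + 1, ]`.
#' @export
read_frame <- function(video, index) {
  stopifnot(inherits(video, "video_source"))
  if (index < 0L || index >= video$frame_count) {
    stop("frame index ", index, " out of range [0, ",
         video$frame_count - 1L, "]")
  }
  con <- file(video$path, "rb")
  on.exit(close(con))
  i <- index + 1L
  .read_avi_frame(con, video$.offsets[i], video$.sizes[i],
                  video$width, video$height)
}

# Stream all frames through a callback FUN(frame, index0) using a single
# connection; returns the list of callback results in frame order.
video_apply <- function(video, FUN) {
  stopifnot(inherits(video, "video_source"))
  con <- file(video$path, "rb")
  on.exit(close(con))
  out <- vector("list", video$frame_count)
  for (i in seq_len(video$frame_count)) {
    fr <- .read_avi_frame(con, video$.offsets[i], video$.sizes[i],
                          video$width, video$height)
    out[[i]] <- FUN(fr, i - 1L)
  }
  out
}

#' Rectangular crop region
#'
#' Defines the region kept when cropping frames before detection, in 0-based
#' pixel coordinates of the uncropped frame (origin top-left).
#'
#' @param x,y Left/top edge of the kept region, in pixels (>= 0).
#' @param w,h Width and height of the kept region, in pixels (>= 1).
#' @return A `crop_rect`.
#' @export
crop_rect <- function(x, y, w, h) {
  if (x < 0 || y < 0 || w < 1 || h < 1) {
    stop("invalid crop rectangle: require x >= 0, y >= 0, w >= 1, h >= 1")
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "crop_rect")
}

#' Crop a frame to a rectangle
#'
#' Pixel (0, 0) of the output is pixel (`rect$x`, `rect$y`) of the input; all
#' detection coordinates downstream of a crop are in cropped-frame space.
#' A rectangle extending outside the frame is an error, never silently
#' clamped.
#'
#' @param frame `height x width x 3` integer RGB array.
#' @param rect A [crop_rect()].
#' @return The cropped `rect$h x rect$w x 3` array.
#' @export
crop_frame <- function(frame, rect) {
  stopifnot(inherits(rect, "crop_rect"))
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("frame must be a height x width x 3 colour array; ",
         "single-channel input is not supported")
  }
  if (rect$x + rect$w > d[2L] || rect$y + rect$h > d[1L]) {
    stop("crop rectangle (x=", rect$x, ", y=", rect$y, ", w=", rect$w,
         ", h=", rect$h, ") exceeds frame bounds ", d[2L], " x ", d[1L])
  }
  frame[(rect$y + 1L):(rect$y + rect$h), (rect$x + 1L):(rect$x + rect$w), ,
        drop = FALSE]
}

#' Pixel-to-millimetre scale calibration
#'
#' Converts a reference length drawn or measured on the frame (for example a
#' ruler visible in the video) into a pixels-per-millimetre factor used for
#' all distance outputs.
#'
#' @param reference_pixels Length of the reference object in pixels (> 0).
#' @param reference_mm Its physical length in millimetres (> 0).
#' @return A `scale_calibration` with `pixels_per_mm = reference_pixels /
#'   reference_mm`.
#' @export
#' @examples
#' calibrate_scale(600, 300)$pixels_per_mm  # 2 px/mm
calibrate_scale <- function(reference_pixels, reference_mm) {
  if (!is.finite(reference_pixels) || reference_pixels <= 0 ||
      !is.finite(reference_mm) || reference_mm <= 0) {
    stop("scale calibration requires positive reference_pixels and reference_mm")
  }
  structure(list(pixels_per_mm = reference_pixels / reference_mm,
                 reference_pixels = reference_pixels,
                 reference_mm = reference_mm,
                 calibrated = TRUE),
            class = "scale_calibration")
}

#' Uncalibrated scale (distances reported in pixels)
#'
#' Used when no reference length is available: the scaling factor is 1, so
#' "mm" outputs are actually pixels, and summaries flag the run as
#' uncalibrated.
#'
#' @return A `scale_calibration` with `pixels_per_mm = 1` and
#'   `calibrated = FALSE`.
#' @export
identity_scale <- function() {
  structure(list(pixels_per_mm = 1, reference_pixels = 1, reference_mm = 1,
                 calibrated = FALSE),
            class = "scale_calibration")
}
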