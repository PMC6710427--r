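#' Euclidean step distance between two points
#'
#' The per-step distance whose sum over consecutive detected positions gives
#' the total distance travelled: `sqrt((x1 - x2)^2 + (y1 - y2)^2)`.
#'
#' @param p1,p2 Numeric length-2 vectors `(x, y)` in pixels.
#' @return Distance in pixels.
#' @export
#' @examples
#' step_distance(c(0, 0), c(3, 4))  # 5
step_distance <- function(p1, p2) {
  sqrt((p1[1L] - p2[1L])^2 + (p1[2L] - p2[2L])^2)
}

.det_cols <- c("frame", "found", "centroid_x", "centroid_y", "rect_cx",
               "rect_cy", "rect_w", "rect_l", "rect_angle", "area")

.detection_row <- function(frame_index, det) {
  if (isTRUE(det$found)) {
    data.frame(frame = frame_index, found = TRUE,
               centroid_x = det$centroid_x, centroid_y = det$centroid_y,
               rect_cx = det$rect_cx, rect_cy = det$rect_cy,
               rect_w = det$rect_w, rect_l = det$rect_l,
               rect_angle = det$rect_angle, area = det$area)
  } else {
    data.frame(frame = frame_index, found = FALSE,
               centroid_x = NA_real_, centroid_y = NA_real_,
               rect_cx = NA_real_, rect_cy = NA_real_,
               rect_w = NA_real_, rect_l = NA_real_,
               rect_angle = NA_real_, area = NA_real_)
  }
}

#' Construct a tracked path from a detection table
#'
#' The container every analytic operates on: one row per frame (found or
#' not) plus the frame rate and scale calibration. [track()] builds it from
#' a video; this constructor builds it directly, e.g. from ground-truth
#' centroids or a re-read path CSV.
#'
#' @param detections Data frame with columns `frame`, `found`, `centroid_x`,
#'   `centroid_y` and optionally the rotated-rectangle columns `rect_cx`,
#'   `rect_cy`, `rect_w`, `rect_l`, `rect_angle`, `area` (filled with `NA`
#'   when absent). Frames must be strictly increasing with no duplicates.
#' @param fps Frames per second.
#' @param scale A `scale_calibration` ([calibrate_scale()] or
#'   [identity_scale()]).
#' @param video_id Identifier recorded in summaries.
#' @param threshold Optional [hsv_range()] used to produce the detections.
#' @param gap_policy `"bridge"` (default) or `"skip"`; see [total_distance()].
#' @return A `tracked_path`.
#' @export
tracked_path <- function(detections, fps, scale = identity_scale(),
                         video_id = "path", threshold = NULL,
                         gap_policy = c("bridge", "skip")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(is.data.frame(detections), fps > 0,
            inherits(scale, "scale_calibration"))
  for (col in .det_cols) {
    if (!col %in% names(detections)) {
      if (col %in% c("frame", "found", "centroid_x", "centroid_y")) {
        stop("detections must contain column '", col, "'")
      }
      detections[[col]] <- NA_real_
    }
  }
  detections <- detections[.det_cols]
  if (is.unsorted(detections$frame, strictly = TRUE)) {
    stop("detection frames must be strictly increasing with no duplicates")
  }
  structure(list(detections = detections, fps = fps, scale = scale,
                 video_id = video_id, threshold = threshold,
                 gap_policy = gap_policy),
            class = "tracked_path")
}

#' @export
print.tracked_path <- function(x, ...) {
  n <- nrow(x$detections)
  cat(sprintf(paste0("<tracked_path> %s\n  %d frames (%d detected), %g fps,",
                     " %g px/mm%s\n  total distance: %.2f %s\n"),
              x$video_id, n, sum(x$detections$found), x$fps,
              x$scale$pixels_per_mm,
              if (x$scale$calibrated) "" else " (uncalibrated)",
              total_distance(x),
              if (x$scale$calibrated) "mm" else "px"))
  invisible(x)
}

#' Track the target through a whole video
#'
#' Runs [detect_in_frame()] on every frame in order and assembles the
#' per-frame records into a `tracked_path`. Every frame yields a record:
#' frames where no object passes the threshold and area filter are kept as
#' not-found rows and skipped by all distance computations (never treated
#' as position zero). The pipeline contains no randomness, so identical
#' inputs give identical outputs.
#'
#' @inheritParams detect_in_frame
#' @param video A `video_source` from [open_video()].
#' @param scale A `scale_calibration`; defaults to [identity_scale()]
#'   (distances in pixels).
#' @param gap_policy How failed detections affect distances; see
#'   [total_distance()].
#' @param video_id Identifier for summaries; defaults to the file name.
#' @return A `tracked_path`.
#' @export
track <- function(video, range, crop = NULL, scale = identity_scale(),
                  min_area = 20, open_radius = 0,
                  gap_policy = c("bridge", "skip"),
                  video_id = basename(video$path)) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(video, "video_source"), inherits(range, "hsv_range"))
  rows <- video_apply(video, function(fr, i) {
    .detection_row(i, detect_in_frame(fr, range, crop = crop,
                                      min_area = min_area,
                                      open_radius = open_radius))
  })
  det <- do.call(rbind, rows)
  if (!any(det$found)) {
    warning("no frame of '", video_id, "' produced a detection; ",
            "check the HSV threshold", call. = FALSE)
  }
  tracked_path(det, fps = video$fps, scale = scale, video_id = video_id,
               threshold = range, gap_policy = gap_policy)
}

#' Track several colour targets over the same video
#'
#' Runs one independent single-target pass per named HSV window over the
#' same decoded frame stream, so body parts tagged with distinct colours
#' (or several uniquely marked animals) can each be followed without any
#' identity-assignment step.
#'
#' @inheritParams track
#' @param ranges Named list of [hsv_range()] objects; names must be unique.
#' @return A named list of `tracked_path` objects, one per range.
#' @export
track_multi <- function(video, ranges, crop = NULL, scale = identity_scale(),
                        min_area = 20, open_radius = 0,
                        gap_policy = c("bridge", "skip"),
                        video_id = basename(video$path)) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(ranges) >= 1L)
  nm <- names(ranges)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every range must be named")
  }
  if (anyDuplicated(nm)) stop("range names must be unique")

  rows <- lapply(ranges, function(r) vector("list", video$frame_count))
  video_apply(video, function(fr, i) {
    cropped <- if (is.null(crop)) fr else crop_frame(fr, crop)
    for (k in seq_along(ranges)) {
      rows[[k]][[i + 1L]] <<- .detection_row(
        i, detect_in_frame(cropped, ranges[[k]], crop = NULL,
                           min_area = min_area, open_radius = open_radius))
    }
    NULL
  })
  out <- lapply(seq_along(ranges), function(k) {
    tracked_path(do.call(rbind, rows[[k]]), fps = video$fps, scale = scale,
                 video_id = paste0(video_id, ":", nm[k]),
                 threshold = ranges[[k]], gap_policy = gap_policy)
  })
  names(out) <- nm
  out
}

# Steps between successive found detections. Under "bridge" a run of failed
# frames is crossed by one straight-line step (a lower bound on the true
# distance); under "skip" only adjacent-frame pairs count.
path_steps <- function(path, gap_policy = path$gap_policy) {
  det <- path$detections[path$detections$found, , drop = FALSE]
  if (nrow(det) < 2L) {
    return(data.frame(from = integer(0), to = integer(0),
                      dist_px = numeric(0)))
  }
  from <- det$frame[-nrow(det)]
  to <- det$frame[-1L]
  d <- sqrt(diff(det$centroid_x)^2 + diff(det$centroid_y)^2)
  steps <- data.frame(from = from, to = to, dist_px = d)
  if (identical(gap_policy, "skip")) {
    steps <- steps[steps$to - steps$from == 1L, , drop = FALSE]
  }
  steps
}

#' Total distance travelled along a path
#'
#' Sums the Euclidean step distances between successive detected centroids
#' and converts to millimetres with the path's scale calibration. When
#' detection fails for a run of frames, `gap_policy = "bridge"` (default)
#' crosses the gap with a single straight-line step — a lower bound on the
#' true distance — while `"skip"` drops gap-crossing steps entirely. The
#' number of detected frames is reported alongside so detection quality can
#' be judged.
#'
#' @param path A `tracked_path`.
#' @param gap_policy `"bridge"` or `"skip"`; defaults to the path's own
#'   policy.
#' @return Total distance in mm (pixels when uncalibrated).
#' @export
total_distance <- function(path, gap_policy = path$gap_policy) {
  stopifnot(inherits(path, "tracked_path"))
  sum(path_steps(path, gap_policy)$dist_px) / path$scale$pixels_per_mm
}

#' One-row summary of a tracking run
#'
#' @param path A `tracked_path`.
#' @return A data frame with `video_id`, `n_frames`, `n_detected`,
#'   `total_distance_mm`, `scaling_factor` (pixels per mm) and `calibrated`.
#' @export
path_summary <- function(path) {
  stopifnot(inherits(path, "tracked_path"))
  data.frame(video_id = path$video_id,
             n_frames = nrow(path$detections),
             n_detected = sum(path$detections$found),
             total_distance_mm = total_distance(path),
             scaling_factor = path$scale$pixels_per_mm,
             calibrated = path$scale$calibrated)
}

#' Read and write per-frame path CSV files
#'
#' The per-video record of the run: one row per frame with the detection
#' flag, the contour centroid, and the minimum rotated rectangle's centre,
#' width, length (`rect_l >= rect_w`) and angle, plus the object area.
#' Written with a fixed dialect (comma delimiter, `.` decimal, LF endings,
#' header row) so outputs are diffable across platforms; rerunning the same
#' job reproduces the file byte for byte.
#'
#' @param path A `tracked_path`.
#' @param file Output CSV path.
#' @return `write_path_csv` returns `file` invisibly; `read_path_csv`
#'   returns a `tracked_path` (geometry only; `fps` and `scale` must be
#'   re-supplied).
#' @export
write_path_csv <- function(path, file) {
  stopifnot(inherits(path, "tracked_path"))
  det <- path$detections
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6,
                                                    format = "f"))
  lines <- paste(det$frame,
                 ifelse(det$found, "TRUE", "FALSE"),
                 fmt(det$centroid_x), fmt(det$centroid_y),
                 fmt(det$rect_cx), fmt(det$rect_cy),
                 fmt(det$rect_w), fmt(det$rect_l), fmt(det$rect_angle),
                 ifelse(is.na(det$area), "NA", format(det$area)),
                 sep = ",")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(c(paste(.det_cols, collapse = ","), lines), con, sep = "\n")
  invisible(file)
}

#' @rdname write_path_csv
#' @param fps,scale,video_id,gap_policy Passed to [tracked_path()] when
#'   reconstructing the object from the CSV.
#' @export
read_path_csv <- function(file, fps, scale = identity_scale(),
                          video_id = basename(file),
                          gap_policy = "bridge") {
  det <- utils::read.csv(file, stringsAsFactors = FALSE)
  det$found <- as.logical(det$found)
  tracked_path(det, fps = fps, scale = scale, video_id = video_id,
               gap_policy = gap_policy)
}

#' Write or read the settings log of a tracking run
#'
#' Records every parameter needed to reproduce a run bit for bit: the HSV
#' threshold, crop rectangle, scale calibration, minimum area, opening
#' radius, gap policy and package version, as a plain-text `key=value`
#' file next to the path CSV.
#'
#' @param path A `tracked_path` (as returned by [track()]).
#' @param file Settings file path.
#' @param video_path Path of the source video, recorded for re-runs.
#' @param crop The [crop_rect()] used, or `NULL`.
#' @param min_area,open_radius Detection parameters of the run.
#' @return `write_settings` returns `file` invisibly; `read_settings`
#'   returns a named list of the parsed parameters (numeric where numeric,
#'   with `range`, `crop` and `scale` reassembled into their objects).
#' @export
write_settings <- function(path, file, video_path, crop = NULL,
                           min_area = 20, open_radius = 0) {
  stopifnot(inherits(path, "tracked_path"))
  r <- path$threshold
  kv <- list(video = video_path,
             video_id = path$video_id,
             fps = path$fps,
             h_low = r$h_low, h_high = r$h_high,
             s_low = r$s_low, s_high = r$s_high,
             v_low = r$v_low, v_high = r$v_high,
             min_area = min_area,
             open_radius = open_radius,
             crop = if (is.null(crop)) "none" else
               paste(crop$x, crop$y, crop$w, crop$h, sep = ","),
             scale_px = path$scale$reference_pixels,
             scale_mm = path$scale$reference_mm,
             calibrated = path$scale$calibrated,
             gap_policy = path$gap_policy,
             version = as.character(utils::packageVersion("animtrack")))
  write_keyvalue(kv, file)
  invisible(file)
}

#' @rdname write_settings
#' @export
read_settings <- function(file) {
  kv <- read_keyvalue(file)
  num <- function(k) as.numeric(kv[[k]])
  out <- list(
    video = kv$video,
    video_id = kv$video_id,
    fps = num("fps"),
    range = hsv_range(num("h_low"), num("h_high"), num("s_low"),
                      num("s_high"), num("v_low"), num("v_high")),
    min_area = num("min_area"),
    open_radius = num("open_radius"),
    crop = if (identical(kv$crop, "none")) NULL else {
      v <- as.integer(strsplit(kv$crop, ",")[[1L]])
      crop_rect(v[1L], v[2L], v[3L], v[4L])
    },
    scale = if (identical(kv$calibrated, "TRUE")) {
      calibrate_scale(num("scale_px"), num("scale_mm"))
    } else {
      identity_scale()
    },
    gap_policy = kv$gap_policy
  )
  out
}

#' Re-run a tracking job from its settings file
#'
#' @param settings_file A settings file written by [write_settings()].
#' @param video_path Optional override of the recorded video path.
#' @return A `tracked_path`, identical to the original run's.
#' @export
track_from_settings <- function(settings_file, video_path = NULL) {
  s <- read_settings(settings_file)
  vp <- if (is.null(video_path)) s$video else video_path
  v <- open_video(vp, fps = s$fps)
  track(v, s$range, crop = s$crop, scale = s$scale, min_area = s$min_area,
        open_radius = s$open_radius, gap_policy = s$gap_policy,
        video_id = s$video_id)
}

#' Append a run summary row to the cumulative summary CSV
#'
#' The summary file is a log of every analysis: one row per run with frame
#' counts, total distance and the scaling factor applied. Rows are appended,
#' never overwritten, so the file accumulates across sessions.
#'
#' @param path A `tracked_path`.
#' @param file Summary CSV path (created with a header if absent).
#' @return The summary row, invisibly.
#' @export
append_summary <- function(path, file) {
  row <- path_summary(path)
  new <- !file.exists(file)
  utils::write.table(row, file, sep = ",", dec = ".", qmethod = "double",
                     row.names = FALSE, col.names = new, append = !new)
  invisible(row)
}
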