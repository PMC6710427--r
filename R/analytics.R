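#' Named rectangular region of interest
#'
#' Axis-aligned rectangle in cropped-frame pixel coordinates, used for
#' occupancy analysis (e.g. the "centre of the cage" zone).
#'
#' @param x,y Left/top edge in pixels.
#' @param w,h Width and height in pixels (> 0).
#' @param name Region label used in outputs.
#' @return A `region_spec`.
#' @export
region_spec <- function(x, y, w, h, name = "region") {
  if (w <= 0 || h <= 0) stop("region width and height must be positive")
  structure(list(x = x, y = y, w = w, h = h, name = name),
            class = "region_spec")
}

#' Instantaneous velocity over fixed frame windows
#'
#' Velocity is the distance travelled across a window of `window_frames`
#' consecutive inter-frame steps divided by the window's duration
#' (`window_frames / fps` seconds; the default 10-step window spans 333 ms
#' at 30 fps). Windows tile the video without overlap; any window touching
#' a not-found frame is omitted rather than zero-filled.
#'
#' @param path A `tracked_path`.
#' @param window_frames Number of consecutive steps per window (>= 2).
#' @return A data frame with `frame` (window start) and
#'   `velocity_mm_per_s`, with attributes `window_frames` and
#'   `window_seconds`. Empty when the path is shorter than one window.
#' @export
instantaneous_velocity <- function(path, window_frames = 10) {
  stopifnot(inherits(path, "tracked_path"))
  if (window_frames < 2) stop("window_frames must be at least 2")
  w <- as.integer(window_frames)
  det <- path$detections
  n <- nrow(det)
  found <- det$found
  x <- det$centroid_x
  y <- det$centroid_y

  starts <- seq.int(1L, by = w, length.out = max(0L, (n - 1L) %/% w))
  keep <- logical(length(starts))
  vel <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + w)   # w + 1 positions = w steps
    if (all(found[idx])) {
      d <- sum(sqrt(diff(x[idx])^2 + diff(y[idx])^2))
      vel[k] <- d / path$scale$pixels_per_mm / (w / path$fps)
      keep[k] <- TRUE
    }
  }
  out <- data.frame(frame = det$frame[starts[keep]],
                    velocity_mm_per_s = vel[keep])
  attr(out, "window_frames") <- w
  attr(out, "window_seconds") <- w / path$fps
  out
}

#' Bin step distances and travel per time interval
#'
#' Builds a histogram of per-step travel distances over half-open bins
#' `[k*w, (k+1)*w)` of width `bin_width_mm`, conserving total distance: the
#' binned distances always sum to [total_distance()] under the same gap
#' policy. Optionally also totals distance per fixed time interval.
#'
#' @param path A `tracked_path`.
#' @param bin_width_mm Distance bin width in mm (> 0).
#' @param time_bin_seconds Optional width of time bins for per-interval
#'   distance totals; `NULL` disables them.
#' @return A list with `bins` (data frame `bin_lo_mm`, `bin_hi_mm`,
#'   `n_steps`, `distance_mm`), `total_distance_mm`, and `time_bins` when
#'   requested (`t_lo_s`, `t_hi_s`, `distance_mm`, binned by each step's
#'   end-frame time).
#' @export
bin_distances <- function(path, bin_width_mm, time_bin_seconds = NULL) {
  stopifnot(inherits(path, "tracked_path"))
  if (!is.finite(bin_width_mm) || bin_width_mm <= 0) {
    stop("bin_width_mm must be positive")
  }
  steps <- path_steps(path)
  d_mm <- steps$dist_px / path$scale$pixels_per_mm
  idx <- floor(d_mm / bin_width_mm)
  nb <- if (length(idx)) max(idx) + 1L else 0L
  bins <- data.frame(
    bin_lo_mm = bin_width_mm * (seq_len(nb) - 1L),
    bin_hi_mm = bin_width_mm * seq_len(nb),
    n_steps = if (nb) tabulate(idx + 1L, nbins = nb) else integer(0),
    distance_mm = vapply(seq_len(nb),
                         function(k) sum(d_mm[idx == k - 1L]), numeric(1))
  )
  out <- list(bins = bins, total_distance_mm = sum(d_mm),
              bin_width_mm = bin_width_mm)
  if (!is.null(time_bin_seconds)) {
    if (time_bin_seconds <= 0) stop("time_bin_seconds must be positive")
    t_end <- steps$to / path$fps
    tb <- floor(t_end / time_bin_seconds)
    ntb <- if (length(tb)) max(tb) + 1L else 0L
    out$time_bins <- data.frame(
      t_lo_s = time_bin_seconds * (seq_len(ntb) - 1L),
      t_hi_s = time_bin_seconds * seq_len(ntb),
      distance_mm = vapply(seq_len(ntb),
                           function(k) sum(d_mm[tb == k - 1L]), numeric(1))
    )
  }
  out
}

#' Fraction of detected time spent inside a region
#'
#' The number of found frames whose centroid lies inside the rectangle
#' (boundary counted as inside) divided by the number of found frames.
#' A path with no detections has no defined occupancy and returns `NA`
#' with a warning — deliberately distinct from an occupancy of 0.
#'
#' @param path A `tracked_path`.
#' @param region A [region_spec()].
#' @return Fraction in `[0, 1]`, or `NA` when no frame was detected.
#' @export
region_occupancy <- function(path, region) {
  stopifnot(inherits(path, "tracked_path"), inherits(region, "region_spec"))
  det <- path$detections[path$detections$found, , drop = FALSE]
  if (nrow(det) == 0L) {
    warning("path has no detected frames; occupancy is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  inside <- det$centroid_x >= region$x & det$centroid_x <= region$x + region$w &
    det$centroid_y >= region$y & det$centroid_y <= region$y + region$h
  mean(inside)
}

#' Coefficient of variation of travel distance across video segments
#'
#' Quantifies how reliably a shorter recording estimates an animal's
#' activity: the video is split into consecutive non-overlapping segments
#' of each requested duration, the distance travelled in each segment is
#' computed, and the coefficient of variation (sd/mean, as a percent) of
#' the segment distances is reported. Since every segment distance is
#' normalised by the same whole-video mean rate, the normalisation cancels
#' in the CV and the raw segment distances are used directly.
#'
#' @param path A `tracked_path`.
#' @param segment_seconds Vector of segment durations in seconds; durations
#'   that do not fit at least twice into the video are skipped with a
#'   warning.
#' @return A data frame with `duration_s`, `n_segments` and `cv_pct`
#'   (`NA` when the segment mean distance is zero).
#' @export
segment_cv <- function(path, segment_seconds) {
  stopifnot(inherits(path, "tracked_path"))
  n <- nrow(path$detections)
  steps <- path_steps(path)
  rows <- lapply(segment_seconds, function(dur) {
    f <- as.integer(round(dur * path$fps))
    nseg <- n %/% f
    if (f < 1L || nseg < 2L) {
      warning("segment duration ", dur, " s does not fit at least twice ",
              "into the video; skipped", call. = FALSE)
      return(NULL)
    }
    seg_d <- vapply(seq_len(nseg), function(s) {
      lo <- (s - 1L) * f
      hi <- s * f - 1L
      sum(steps$dist_px[steps$from >= lo & steps$to <= hi])
    }, numeric(1)) / path$scale$pixels_per_mm
    m <- mean(seg_d)
    cv <- if (m > 0) 100 * stats::sd(seg_d) / m else NA_real_
    data.frame(duration_s = dur, n_segments = nseg, cv_pct = cv)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(duration_s = numeric(0), n_segments = integer(0),
                      cv_pct = numeric(0))
  }
  out
}

#' Translate a path so it starts at the origin
#'
#' Shifts all coordinates by minus the first detected centroid, so paths
#' from different videos can be overlaid from a common starting point.
#' Distances are unchanged (pure translation) and applying the operation
#' twice is a no-op.
#'
#' @param path A `tracked_path` with at least one detected frame.
#' @return The translated `tracked_path`.
#' @export
normalise_path <- function(path) {
  stopifnot(inherits(path, "tracked_path"))
  det <- path$detections
  first <- which(det$found)[1L]
  if (is.na(first)) stop("cannot normalise a path with no detected frames")
  dx <- det$centroid_x[first]
  dy <- det$centroid_y[first]
  det$centroid_x <- det$centroid_x - dx
  det$centroid_y <- det$centroid_y - dy
  det$rect_cx <- det$rect_cx - dx
  det$rect_cy <- det$rect_cy - dy
  path$detections <- det
  path
}

# Direction-change extrema of a numeric series (plateau-aware): returns
# indices and type (+1 max, -1 min), alternating by construction.
.zigzag_extrema <- function(v) {
  ds <- sign(diff(v))
  # propagate direction through plateaus
  for (i in seq_along(ds)) {
    if (ds[i] == 0 && i > 1L) ds[i] <- ds[i - 1L]
  }
  nz <- which(ds != 0)
  if (length(nz) == 0L) {
    return(data.frame(idx = integer(0), type = integer(0)))
  }
  turns <- which(diff(ds[nz]) != 0)
  idx <- nz[turns] + 1L
  type <- ifelse(ds[nz[turns]] > 0, 1L, -1L)
  data.frame(idx = idx, type = type)
}

# Collapse consecutive same-type extrema (keep the more extreme), then
# repeatedly remove the adjacent extremum pair of smallest amplitude while
# it is below the prominence threshold.
.filter_extrema <- function(ext, v, prominence) {
  collapse <- function(e) {
    if (nrow(e) < 2L) return(e)
    keep <- rep(TRUE, nrow(e))
    i <- 1L
    while (i < nrow(e)) {
      j <- i + 1L
      if (e$type[i] == e$type[j]) {
        vi <- v[e$idx[i]]; vj <- v[e$idx[j]]
        drop <- if (e$type[i] > 0) {
          if (vi >= vj) j else i
        } else {
          if (vi <= vj) j else i
        }
        e <- e[-drop, , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    e
  }
  ext <- collapse(ext)
  repeat {
    if (nrow(ext) < 2L) break
    amps <- abs(diff(v[ext$idx]))
    k <- which.min(amps)
    if (amps[k] >= prominence) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
    ext <- collapse(ext)
  }
  ext
}

#' Larval stride and turn analysis of a body-length trace
#'
#' A crawling larva alternately extends and contracts; each extension-
#' contraction cycle (a stride) shows up as one oscillation of its body
#' length, taken per frame as the longer side of the minimum rotated
#' rectangle. During a turn the larva curls, so its length:width aspect
#' ratio drops well below its typical elongation.
#'
#' The classifier proceeds in three steps. (1) Turn flagging: a frame is a
#' turn when its aspect ratio falls below `ratio_turn_threshold` times the
#' median aspect ratio over all detected frames. (2) The length trace is
#' smoothed with a centred moving average of `smooth_window` frames.
#' (3) Alternating local maxima/minima of the smoothed trace are extracted,
#' oscillations smaller than `min_prominence_px` are discarded, extrema on
#' turn frames are dropped, and each remaining peak is paired with the
#' following trough to give one stride event with amplitude
#' `peak - trough` (in pixels; the mean amplitude is also converted to mm
#' via the path's scale). Events overlapping a turn frame are excluded.
#'
#' @param path A `tracked_path` from a single-larva run.
#' @param smooth_window Centred moving-average window in frames; odd,
#'   >= 1. Default 5.
#' @param ratio_turn_threshold Fraction of the median aspect ratio below
#'   which a frame counts as a turn. Default 0.6.
#' @param min_prominence_px Minimum peak-to-trough oscillation amplitude
#'   retained as a stride, in pixels. Default 2.
#' @return A `stride_profile`: list with `frames` (per-frame `frame`,
#'   `length_px`, `width_px`, `aspect_ratio`, `smoothed_length_px`,
#'   `turn`), `events` (`peak_frame`, `trough_frame`, `amplitude_px`),
#'   `turn_frames`, `mean_amplitude_px`, `mean_amplitude_mm` (`NA` when no
#'   stride was found) and the parameters used.
#' @export
stride_analysis <- function(path, smooth_window = 5,
                            ratio_turn_threshold = 0.6,
                            min_prominence_px = 2) {
  stopifnot(inherits(path, "tracked_path"))
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 1")
  }
  det <- path$detections
  len <- ifelse(det$found, det$rect_l, NA_real_)
  wid <- ifelse(det$found, det$rect_w, NA_real_)
  aspect <- ifelse(!is.na(wid) & wid > 0, len / wid, NA_real_)

  med_aspect <- stats::median(aspect, na.rm = TRUE)
  turn <- !is.na(aspect) & aspect < ratio_turn_threshold * med_aspect

  k <- as.integer(smooth_window)
  smoothed <- if (k == 1L) len else {
    as.numeric(stats::filter(len, rep(1 / k, k), sides = 2))
  }

  frames <- data.frame(frame = det$frame, length_px = len, width_px = wid,
                       aspect_ratio = aspect, smoothed_length_px = smoothed,
                       turn = turn)

  ok <- which(!is.na(smoothed))
  events <- data.frame(peak_frame = integer(0), trough_frame = integer(0),
                       amplitude_px = numeric(0))
  if (length(ok) >= 3L) {
    v <- smoothed[ok]
    ext <- .zigzag_extrema(v)
    if (nrow(ext) > 0L) {
      # map back to detection rows, drop extrema sitting on turn frames
      ext$row <- ok[ext$idx]
      ext <- ext[!turn[ext$row], , drop = FALSE]
      ext2 <- data.frame(idx = ext$row, type = ext$type)
      ext2 <- .filter_extrema(ext2, smoothed, min_prominence_px)
      if (nrow(ext2) >= 2L) {
        ev <- list()
        for (i in seq_len(nrow(ext2) - 1L)) {
          if (ext2$type[i] == 1L && ext2$type[i + 1L] == -1L) {
            pr <- ext2$idx[i]; tr <- ext2$idx[i + 1L]
            if (any(turn[pr:tr])) next
            amp <- smoothed[pr] - smoothed[tr]
            if (amp >= min_prominence_px) {
              ev[[length(ev) + 1L]] <- data.frame(
                peak_frame = det$frame[pr], trough_frame = det$frame[tr],
                amplitude_px = amp)
            }
          }
        }
        if (length(ev)) events <- do.call(rbind, ev)
      }
    }
  }

  mean_amp_px <- if (nrow(events)) mean(events$amplitude_px) else NA_real_
  structure(list(
    frames = frames,
    events = events,
    turn_frames = det$frame[turn],
    mean_amplitude_px = mean_amp_px,
    mean_amplitude_mm = mean_amp_px / path$scale$pixels_per_mm,
    params = list(smooth_window = k,
                  ratio_turn_threshold = ratio_turn_threshold,
                  min_prominence_px = min_prominence_px,
                  median_aspect_ratio = med_aspect)
  ), class = "stride_profile")
}

#' @export
print.stride_profile <- function(x, ...) {
  cat(sprintf(paste0("<stride_profile> %d frames, %d stride events, ",
                     "%d turn frames\n  mean amplitude: %s px\n"),
              nrow(x$frames), nrow(x$events), length(x$turn_frames),
              if (is.na(x$mean_amplitude_px)) "NA" else
                sprintf("%.2f", x$mean_amplitude_px)))
  invisible(x)
}
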