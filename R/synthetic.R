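# Synthetic-video generator: moving coloured shapes rendered with exact,
# analytically known geometry, so detection and analytics can be validated
# against ground truth without any animal footage.

#' Shape programs for synthetic videos
#'
#' Shapes are rendered without anti-aliasing (a pixel is inside iff its
#' centre satisfies the shape inequality), so mask geometry is exact.
#' Ellipse parameters may be per-frame vectors, which is how pulsating
#' larva-like fixtures are built.
#'
#' @param radius Disc radius in pixels.
#' @param a,b Ellipse semi-axes in pixels (scalar or one value per frame).
#' @param angle Ellipse rotation in degrees (scalar or per frame).
#' @param w,h Rectangle width and height in pixels.
#' @return A shape program used by [trajectory_spec()].
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_disc <- function(radius) {
  stopifnot(radius > 0)
  structure(list(type = "disc", radius = radius), class = "shape_spec")
}

#' @rdname shapes
#' @export
shape_ellipse <- function(a, b, angle = 0) {
  stopifnot(all(a > 0), all(b > 0))
  structure(list(type = "ellipse", a = a, b = b, angle = angle),
            class = "shape_spec")
}

#' @rdname shapes
#' @export
shape_rectangle <- function(w, h) {
  stopifnot(w > 0, h > 0)
  structure(list(type = "rectangle", w = w, h = h), class = "shape_spec")
}

#' Per-frame centre trajectories
#'
#' Convenience constructors for the `centres` matrix of a
#' [trajectory_spec()]: a constant-velocity line and a line with a
#' sinusoidal transverse component.
#'
#' @param start Length-2 start position `(x, y)` in pixels.
#' @param velocity Length-2 per-frame displacement in pixels.
#' @param n Number of frames.
#' @param amplitude,period Amplitude (px) and period (frames) of the
#'   transverse sinusoid.
#' @return An `n x 2` matrix of per-frame centres.
#' @export
linear_trajectory <- function(start, velocity, n) {
  t <- seq_len(n) - 1L
  cbind(x = start[1L] + velocity[1L] * t,
        y = start[2L] + velocity[2L] * t)
}

#' @rdname linear_trajectory
#' @export
sinusoid_trajectory <- function(start, velocity, amplitude, period, n) {
  base <- linear_trajectory(start, velocity, n)
  t <- seq_len(n) - 1L
  v <- sqrt(sum(velocity^2))
  perp <- if (v > 0) c(-velocity[2L], velocity[1L]) / v else c(0, 1)
  off <- amplitude * sin(2 * pi * t / period)
  cbind(x = base[, 1L] + perp[1L] * off,
        y = base[, 2L] + perp[2L] * off)
}

.shape_bound <- function(shape, i) {
  switch(shape$type,
    disc = shape$radius,
    ellipse = max(.per_frame(shape$a, i), .per_frame(shape$b, i)),
    rectangle = sqrt((shape$w / 2)^2 + (shape$h / 2)^2)
  )
}

.per_frame <- function(x, i) if (length(x) == 1L) x else x[i]

#' Specification of a synthetic video
#'
#' Describes a single coloured shape moving over a uniform background, with
#' everything needed to render frames and to know the exact ground truth:
#' per-frame centres, a shape program, target and background colours (HSV),
#' frame geometry and rate. The shape must stay fully inside the frame at
#' every frame unless `allow_exit = TRUE`.
#'
#' @param centres `n_frames x 2` matrix of per-frame shape centres (pixels).
#' @param shape A shape program ([shape_disc()], [shape_ellipse()],
#'   [shape_rectangle()]).
#' @param n_frames,fps,width,height Video geometry and rate.
#' @param colour,background HSV triples `c(h, s, v)` with hue in degrees;
#'   must be well separated for thresholding to make sense.
#' @param regions Optional list of [region_spec()]s; ground truth then
#'   records a per-frame inside flag for each.
#' @param turn_flags Optional logical vector marking frames that emulate
#'   turns (recorded in ground truth; used by [make_larva_spec()]).
#' @param allow_exit Permit the shape to leave the frame.
#' @return A `trajectory_spec`.
#' @export
trajectory_spec <- function(centres, shape, n_frames, fps, width, height,
                            colour = c(0, 1, 1),
                            background = c(0, 0, 1),
                            regions = list(), turn_flags = NULL,
                            allow_exit = FALSE) {
  stopifnot(inherits(shape, "shape_spec"), n_frames >= 1, fps > 0,
            width >= 8, height >= 8)
  centres <- as.matrix(centres)
  if (nrow(centres) != n_frames || ncol(centres) != 2L) {
    stop("centres must be an n_frames x 2 matrix")
  }
  if (!allow_exit) {
    for (i in seq_len(n_frames)) {
      b <- .shape_bound(shape, i)
      if (centres[i, 1L] - b < 0 || centres[i, 1L] + b > width - 1 ||
          centres[i, 2L] - b < 0 || centres[i, 2L] + b > height - 1) {
        stop("shape leaves the frame at frame ", i - 1L,
             "; set allow_exit = TRUE if intended")
      }
    }
  }
  if (is.null(turn_flags)) turn_flags <- rep(FALSE, n_frames)
  stopifnot(length(turn_flags) == n_frames)
  structure(list(centres = centres, shape = shape, n_frames = n_frames,
                 fps = fps, width = width, height = height,
                 colour = colour, background = background,
                 regions = regions, turn_flags = turn_flags,
                 noise = NULL),
            class = "trajectory_spec")
}

#' Add seeded salt noise to a synthetic-video spec
#'
#' Sprinkles isolated single-pixel distractors of the target colour over
#' each frame, reproducibly for a given seed, to stress-test the
#' minimum-area rejection of the detector. Noise pixels never touch the
#' shape or each other, so each remains a 1-pixel component.
#'
#' @param spec A [trajectory_spec()].
#' @param salt_density Fraction of frame pixels turned into distractors,
#'   in `[0, 0.001]`.
#' @param seed Integer seed for the noise placement.
#' @return The spec with noise configured.
#' @export
make_noise <- function(spec, salt_density, seed) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (salt_density < 0 || salt_density > 0.001) {
    stop("salt_density must lie in [0, 0.001]")
  }
  spec$noise <- if (salt_density > 0) {
    list(salt_density = salt_density, seed = as.integer(seed))
  } else {
    NULL
  }
  spec
}

#' Pulsating-ellipse spec emulating a crawling larva
#'
#' Builds a fixture whose body length oscillates like a striding larva:
#' an ellipse with major-axis length `base_length + stride_amp *
#' sin(2 * pi * t / period)` and a fixed width chosen from `base_aspect`,
#' except during declared turn windows where the aspect ratio drops to
#' `turn_aspect` (the larva curls). Ground truth records the analytic
#' length trace and the turn flags.
#'
#' @param base_length Mean body length in pixels.
#' @param stride_amp Sinusoid amplitude of the length in pixels
#'   (`< base_length / 2`).
#' @param period Stride period in frames (>= 4).
#' @param turns List of `c(start_frame, duration)` turn windows (0-based,
#'   non-overlapping).
#' @param n_frames,fps,width,height Video geometry and rate.
#' @param base_aspect Length:width ratio outside turns. Default 4.
#' @param turn_aspect Length:width ratio during turns. Default 1.5.
#' @param centre Fixed shape centre; defaults to the frame centre.
#' @return A `trajectory_spec`.
#' @export
make_larva_spec <- function(base_length = 40, stride_amp = 6, period = 20,
                            turns = list(), n_frames = 200, fps = 15,
                            width = 160, height = 120,
                            base_aspect = 4, turn_aspect = 1.5,
                            centre = NULL) {
  if (stride_amp >= base_length / 2) {
    stop("stride_amp must be smaller than base_length / 2")
  }
  if (period < 4) stop("period must be at least 4 frames")
  turn_flags <- rep(FALSE, n_frames)
  if (length(turns)) {
    covered <- integer(0)
    for (tw in turns) {
      win <- tw[1L]:(tw[1L] + tw[2L] - 1L)
      if (any(win %in% covered)) stop("turn windows overlap")
      if (any(win < 0 | win >= n_frames)) {
        stop("turn window [", tw[1L], ", ", tw[1L] + tw[2L] - 1L,
             "] exceeds the video")
      }
      covered <- c(covered, win)
      turn_flags[win + 1L] <- TRUE
    }
  }
  t <- seq_len(n_frames) - 1L
  a <- (base_length + stride_amp * sin(2 * pi * t / period)) / 2
  b <- ifelse(turn_flags, a / turn_aspect, rep(base_length / (2 * base_aspect),
                                               n_frames))
  if (is.null(centre)) centre <- c((width - 1) / 2, (height - 1) / 2)
  centres <- cbind(rep(centre[1L], n_frames), rep(centre[2L], n_frames))
  trajectory_spec(centres, shape_ellipse(a, b, angle = 0),
                  n_frames = n_frames, fps = fps,
                  width = width, height = height,
                  turn_flags = turn_flags)
}

.hsv_to_rgb_int <- function(hsv3) {
  col <- grDevices::hsv(hsv3[1L] %% 360 / 360, hsv3[2L], hsv3[3L])
  as.integer(grDevices::col2rgb(col))
}

.shape_mask <- function(spec, i, X, Y) {
  cx <- spec$centres[i, 1L]; cy <- spec$centres[i, 2L]
  s <- spec$shape
  switch(s$type,
    disc = (X - cx)^2 + (Y - cy)^2 <= s$radius^2,
    ellipse = {
      a <- .per_frame(s$a, i); b <- .per_frame(s$b, i)
      th <- .per_frame(s$angle, i) * pi / 180
      u <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      v <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      (u / a)^2 + (v / b)^2 <= 1
    },
    rectangle = abs(X - cx) <= s$w / 2 & abs(Y - cy) <= s$h / 2
  )
}

.true_dims <- function(spec, i) {
  s <- spec$shape
  switch(s$type,
    disc = c(2 * s$radius, 2 * s$radius),
    ellipse = {
      a <- .per_frame(s$a, i); b <- .per_frame(s$b, i)
      c(2 * max(a, b), 2 * min(a, b))
    },
    rectangle = c(max(s$w, s$h), min(s$w, s$h))
  )
}

# run with a local RNG state so rendering never disturbs the session RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.salt_positions <- function(spec, i, mask) {
  w <- spec$width; h <- spec$height
  k <- round(spec$noise$salt_density * w * h)
  if (k == 0L) return(NULL)
  # forbid pixels touching the shape (8-neighbourhood) so noise stays a
  # separate 1-px component
  forbidden <- mask
  forbidden <- forbidden | rbind(FALSE, mask[-h, ]) | rbind(mask[-1, ], FALSE)
  forbidden <- forbidden | cbind(FALSE, forbidden[, -w]) |
    cbind(forbidden[, -1], FALSE)
  free <- which(!forbidden)
  if (length(free) == 0L) return(NULL)
  cand <- sample(free, min(k * 4L, length(free)))
  rows <- (cand - 1L) %% h
  cols <- (cand - 1L) %/% h
  keep <- integer(0)
  for (j in seq_along(cand)) {
    if (length(keep) == k) break
    if (length(keep) == 0L ||
        all(pmax(abs(rows[keep] - rows[j]), abs(cols[keep] - cols[j])) > 1L)) {
      keep <- c(keep, j)
    }
  }
  cand[keep]
}

#' Render a synthetic video with ground truth
#'
#' Rasterises the spec frame by frame (uniform background, one filled
#' shape, optional seeded salt noise) and writes an uncompressed RGB24 AVI
#' plus a ground-truth CSV (`<out>.ground_truth.csv`) with the true centre,
#' length, width and turn flag per frame, and inside flags for any declared
#' regions. Rendering is fully deterministic for a given spec.
#'
#' @param spec A [trajectory_spec()].
#' @param out Output video path.
#' @return A list with `video` (the path), `ground_truth` (data frame),
#'   `ground_truth_csv` (its path) and `total_path_px` (sum of Euclidean
#'   steps over the true centres).
#' @export
render_video <- function(spec, out) {
  stopifnot(inherits(spec, "trajectory_spec"))
  w <- spec$width; h <- spec$height
  X <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1L), h, w)
  fg <- .hsv_to_rgb_int(spec$colour)
  bg <- .hsv_to_rgb_int(spec$background)

  do_render <- function() {
    frames <- vector("list", spec$n_frames)
    for (i in seq_len(spec$n_frames)) {
      mask <- .shape_mask(spec, i, X, Y)
      if (!is.null(spec$noise)) {
        salt <- .salt_positions(spec, i, mask)
        if (length(salt)) mask[salt] <- TRUE
      }
      fr <- array(0L, dim = c(h, w, 3L))
      for (ch in 1:3) {
        plane <- matrix(bg[ch], h, w)
        plane[mask] <- fg[ch]
        fr[, , ch] <- plane
      }
      frames[[i]] <- fr
    }
    frames
  }
  frames <- if (is.null(spec$noise)) do_render() else {
    .with_seed(spec$noise$seed, do_render())
  }
  write_avi(frames, out, spec$fps)

  dims <- t(vapply(seq_len(spec$n_frames), function(i) .true_dims(spec, i),
                   numeric(2)))
  gt <- data.frame(frame = seq_len(spec$n_frames) - 1L,
                   cx = spec$centres[, 1L], cy = spec$centres[, 2L],
                   length_px = dims[, 1L], width_px = dims[, 2L],
                   turn = spec$turn_flags)
  for (rg in spec$regions) {
    gt[[paste0("inside_", rg$name)]] <-
      gt$cx >= rg$x & gt$cx <= rg$x + rg$w &
      gt$cy >= rg$y & gt$cy <= rg$y + rg$h
  }
  total <- if (spec$n_frames > 1L) {
    sum(sqrt(diff(gt$cx)^2 + diff(gt$cy)^2))
  } else {
    0
  }
  gt_path <- paste0(out, ".ground_truth.csv")
  utils::write.csv(gt, gt_path, row.names = FALSE)
  list(video = out, ground_truth = gt, ground_truth_csv = gt_path,
       total_path_px = total)
}

#' Read a synthetic-video spec from a YAML file
#'
#' The YAML schema mirrors [trajectory_spec()]: top-level `width`,
#' `height`, `n_frames`, `fps`, `colour`/`background` (3-element HSV),
#' `shape` (`type` plus its parameters), `trajectory` (`type: linear` with
#' `start`/`velocity`, `type: sinusoid` adding `amplitude`/`period`, or
#' `type: points` with `x`/`y` vectors) and optional `noise`
#' (`salt_density`, `seed`).
#'
#' @param path YAML file path.
#' @return A `trajectory_spec`.
#' @export
read_trajectory_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("width", "height", "n_frames", "fps", "shape", "trajectory")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("spec YAML is missing fields: ", paste(miss, collapse = ", "))
  }
  n <- y$n_frames
  shape <- switch(y$shape$type,
    disc = shape_disc(y$shape$radius),
    ellipse = shape_ellipse(unlist(y$shape$a), unlist(y$shape$b),
                            if (is.null(y$shape$angle)) 0 else
                              unlist(y$shape$angle)),
    rectangle = shape_rectangle(y$shape$w, y$shape$h),
    stop("unknown shape type '", y$shape$type, "'")
  )
  tr <- y$trajectory
  centres <- switch(tr$type,
    linear = linear_trajectory(unlist(tr$start), unlist(tr$velocity), n),
    sinusoid = sinusoid_trajectory(unlist(tr$start), unlist(tr$velocity),
                                   tr$amplitude, tr$period, n),
    points = cbind(unlist(tr$x), unlist(tr$y)),
    stop("unknown trajectory type '", tr$type, "'")
  )
  spec <- trajectory_spec(
    centres, shape, n_frames = n, fps = y$fps,
    width = y$width, height = y$height,
    colour = if (is.null(y$colour)) c(0, 1, 1) else unlist(y$colour),
    background = if (is.null(y$background)) c(0, 0, 1) else
      unlist(y$background)
  )
  if (!is.null(y$noise)) {
    spec <- make_noise(spec, y$noise$salt_density, y$noise$seed)
  }
  spec
}
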