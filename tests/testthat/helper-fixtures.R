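# Shared synthetic fixtures, rendered once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# red target on white background, the package's main use case
red_range <- function() hsv_range(350, 10, 0.5, 1, 0.5, 1)
blue_range <- function() hsv_range(200, 280, 0.5, 1, 0.5, 1)

# 60-frame disc, constant velocity 2 px/frame along x
disc_fixture <- function() {
  fixture("disc", function() {
    spec <- trajectory_spec(
      centres = linear_trajectory(c(20, 120), c(2, 0), 60),
      shape = shape_disc(8), n_frames = 60, fps = 30,
      width = 320, height = 240
    )
    out <- render_video(spec, file.path(tempdir(), "fix_disc.avi"))
    out$spec <- spec
    out
  })
}

disc_path <- function() {
  fixture("disc_path", function() {
    fx <- disc_fixture()
    track(open_video(fx$video), red_range())
  })
}

larva_fixture <- function() {
  fixture("larva", function() {
    spec <- make_larva_spec(base_length = 40, stride_amp = 6, period = 20,
                            n_frames = 200, fps = 15)
    out <- render_video(spec, file.path(tempdir(), "fix_larva.avi"))
    out$spec <- spec
    out
  })
}

larva_turn_fixture <- function() {
  fixture("larva_turn", function() {
    spec <- make_larva_spec(base_length = 40, stride_amp = 6, period = 20,
                            turns = list(c(100, 15)), n_frames = 200,
                            fps = 15)
    out <- render_video(spec, file.path(tempdir(), "fix_larva_turn.avi"))
    out$spec <- spec
    out
  })
}

# tracked_path built directly from coordinates (no video involved)
path_from_xy <- function(x, y, fps = 30, scale = identity_scale(),
                         found = NULL) {
  n <- length(x)
  if (is.null(found)) found <- rep(TRUE, n)
  det <- data.frame(frame = seq_len(n) - 1L, found = found,
                    centroid_x = ifelse(found, x, NA_real_),
                    centroid_y = ifelse(found, y, NA_real_))
  tracked_path(det, fps = fps, scale = scale, video_id = "inline")
}

# random disc spec with a linear + sinusoidal trajectory kept inside the
# frame (draws from the current RNG state; resamples until in-bounds)
random_disc_spec <- function(n_frames = 60, width = 320, height = 240) {
  repeat {
    r <- runif(1, 5, 9)
    speed <- runif(1, 1.5, 3)
    th <- runif(1, 0, 2 * pi)
    vel <- speed * c(cos(th), sin(th))
    start <- c(runif(1, 20, width - 20), runif(1, 20, height - 20))
    amp <- runif(1, 0, 8)
    period <- runif(1, 15, 40)
    centres <- sinusoid_trajectory(start, vel, amp, period, n_frames)
    spec <- try(trajectory_spec(centres, shape_disc(r), n_frames, 30,
                                width, height), silent = TRUE)
    if (!inherits(spec, "try-error")) return(spec)
  }
}

# independent 8-connected component labelling by BFS flood fill, used as
# the oracle for largest-object selection
brute_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- cur
      while (nrow(queue) > 0L) {
        p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1L] + di; nj <- p[2L] + dj
          if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- rbind(queue, c(ni, nj))
          }
        }
      }
    }
  }
  lab
}

# independent extrema-pair counter: complete peak -> following-trough pairs
# of a clean series, by direct neighbour comparison
brute_stride_pairs <- function(v) {
  idx <- which(!is.na(v))
  v <- v[idx]
  n <- length(v)
  maxima <- integer(0); minima <- integer(0)
  for (i in 2:(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) maxima <- c(maxima, i)
    if (v[i] < v[i - 1L] && v[i] <= v[i + 1L]) minima <- c(minima, i)
  }
  pairs <- 0L
  for (m in maxima) {
    if (any(minima > m)) pairs <- pairs + 1L
  }
  pairs
}
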