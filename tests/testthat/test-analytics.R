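test_that("velocity of constant motion equals speed x frame rate", {
  # 2 px/frame at 30 fps, 1 px/mm -> 60 mm/s in every window
  p <- path_from_xy(2 * (0:59), rep(0, 60), fps = 30)
  v <- instantaneous_velocity(p, window_frames = 10)
  expect_equal(nrow(v), 5)
  expect_true(all(abs(v$velocity_mm_per_s - 60) < 1e-9))
  expect_equal(attr(v, "window_seconds"), 10 / 30)  # the 333 ms window

  # tracked from video rather than ground truth: within 2%
  vp <- instantaneous_velocity(disc_path(), window_frames = 10)
  expect_true(all(abs(vp$velocity_mm_per_s - 60) / 60 < 0.02))
})

test_that("velocity edge cases: stationary path, short path, lost windows", {
  p0 <- path_from_xy(rep(5, 30), rep(5, 30), fps = 30)
  v0 <- instantaneous_velocity(p0, 10)
  expect_true(all(v0$velocity_mm_per_s == 0))

  expect_equal(nrow(instantaneous_velocity(path_from_xy(1:5, 1:5), 10)), 0)
  expect_error(instantaneous_velocity(path_from_xy(1:30, 1:30), 1),
               "at least 2")

  # a not-found frame poisons exactly the window containing it
  found <- rep(TRUE, 60); found[25] <- FALSE
  p <- path_from_xy(2 * (0:59), rep(0, 60), fps = 30, found = found)
  v <- instantaneous_velocity(p, 10)
  expect_equal(nrow(v), 4)
  expect_false(20 %in% v$frame)
})

test_that("binned distances conserve the total and refine by aggregation", {
  p <- path_from_xy(2 * (0:59), rep(0, 60))  # 59 steps of exactly 2
  b <- bin_distances(p, 10)
  expect_equal(nrow(b$bins), 1)
  expect_equal(b$bins$n_steps, 59)
  expect_equal(b$bins$distance_mm, total_distance(p), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    q <- path_from_xy(cumsum(runif(40, 0, 8)), cumsum(runif(40, 0, 8)))
    bb <- bin_distances(q, 3.7)
    expect_equal(sum(bb$bins$distance_mm), total_distance(q),
                 tolerance = 1e-9, info = paste("path", i))
  }

  # width-5 histogram aggregates exactly to the width-10 histogram
  q <- path_from_xy(cumsum(runif(60, 0, 20)), rep(0, 60))
  b5 <- bin_distances(q, 5)$bins
  b10 <- bin_distances(q, 10)$bins
  agg <- vapply(seq_len(nrow(b10)), function(k) {
    sum(b5$distance_mm[b5$bin_lo_mm >= (k - 1) * 10 & b5$bin_hi_mm <= k * 10])
  }, numeric(1))
  expect_equal(agg, b10$distance_mm, tolerance = 1e-9)

  expect_error(bin_distances(p, 0), "positive")
})

test_that("time-binned distance totals also conserve the total", {
  set.seed(6)
  p <- path_from_xy(cumsum(runif(90, 0, 4)), cumsum(runif(90, 0, 4)),
                    fps = 30)
  b <- bin_distances(p, 10, time_bin_seconds = 1)
  expect_equal(sum(b$time_bins$distance_mm), total_distance(p),
               tolerance = 1e-9)
})

test_that("region occupancy counts boundary as inside and handles edge cases", {
  p <- path_from_xy(seq(0, 99, length.out = 50), rep(10, 50))
  whole <- region_spec(0, 0, 99, 20, "all")
  expect_equal(region_occupancy(p, whole), 1.0)

  # single found frame inside the region
  p1 <- path_from_xy(5, 5)
  expect_equal(region_occupancy(p1, region_spec(0, 0, 10, 10)), 1.0)

  # centroid exactly on the boundary counts as inside
  pb <- path_from_xy(c(10, 30), c(10, 10))
  expect_equal(region_occupancy(pb, region_spec(10, 0, 10, 20)), 0.5)

  none <- path_from_xy(c(1, 2), c(1, 2), found = c(FALSE, FALSE))
  expect_warning(o <- region_occupancy(none, whole), "undefined")
  expect_true(is.na(o))

  expect_error(region_spec(0, 0, 0, 5), "positive")
})

test_that("occupancy is monotone under region inclusion", {
  set.seed(9)
  p <- path_from_xy(runif(80, 0, 100), runif(80, 0, 100))
  for (i in 1:20) {
    x <- runif(1, 0, 50); y <- runif(1, 0, 50)
    w <- runif(1, 5, 40); h <- runif(1, 5, 40)
    inner <- region_spec(x, y, w, h)
    outer <- region_spec(x - runif(1, 0, 10), y - runif(1, 0, 10),
                         w + runif(1, 0, 20), h + runif(1, 0, 20))
    expect_lte(region_occupancy(p, inner), region_occupancy(p, outer))
  }
})

test_that("segment CV is zero for uniform motion and matches the closed form", {
  fps <- 30
  p <- path_from_xy(0.5 * (0:(360 * fps - 1)), rep(0, 360 * fps), fps = fps)
  cv <- segment_cv(p, c(30, 60, 120))
  expect_equal(cv$cv_pct, rep(0, 3), tolerance = 1e-9)

  # 6 minutes alternating 1 min active (2 px/frame) / 1 min stationary
  step_px <- rep(rep(c(2, 0), 3), each = 60 * fps)[- (360 * fps)]
  x <- cumsum(c(0, step_px))
  pa <- path_from_xy(x, rep(0, length(x)), fps = fps)
  got <- segment_cv(pa, 60)
  seg <- vapply(1:6, function(s) {
    sum(step_px[((s - 1) * 60 * fps + 1):(s * 60 * fps - 1)])
  }, numeric(1))
  expect_equal(got$n_segments, 6)
  expect_equal(got$cv_pct, 100 * sd(seg) / mean(seg), tolerance = 1e-9)
  expect_warning(segment_cv(pa, c(60, 720)), "skipped")
})

test_that("segment CV decreases with duration on homogeneous random walks", {
  set.seed(21)
  fps <- 10
  n <- 240 * fps
  wins <- c(15, 30, 60, 120)
  deltas <- replicate(50, {
    steps <- rexp(n - 1, rate = 1)
    p <- path_from_xy(cumsum(c(0, steps)), rep(0, n), fps = fps)
    cv <- segment_cv(p, wins)$cv_pct
    mean(diff(cv))
  })
  # trend test: on average CV falls as the segment duration grows
  expect_lt(mean(deltas), 0)
  expect_gt(mean(deltas < 0), 0.8)
})

test_that("path normalisation starts at the origin and preserves distance", {
  p <- disc_path()
  q <- normalise_path(p)
  first <- which(q$detections$found)[1]
  expect_equal(q$detections$centroid_x[first], 0)
  expect_equal(q$detections$centroid_y[first], 0)
  expect_equal(total_distance(q), total_distance(p), tolerance = 1e-12)
  expect_equal(normalise_path(q)$detections, q$detections)  # idempotent

  none <- path_from_xy(1, 1, found = FALSE)
  expect_error(normalise_path(none), "no detected frames")
})

test_that("stride count matches a brute-force extrema oracle on the larva fixture", {
  fx <- larva_fixture()
  p <- track(open_video(fx$video), red_range())
  sp <- stride_analysis(p)

  # oracle: the analytic ground-truth length trace, same smoothing, then
  # direct neighbour-comparison extrema pairing
  k <- sp$params$smooth_window
  smoothed <- as.numeric(stats::filter(fx$ground_truth$length_px,
                                       rep(1 / k, k), sides = 2))
  expect_equal(nrow(sp$events), brute_stride_pairs(smoothed))
  expect_lt(abs(sp$mean_amplitude_px - 12), 0.1 * 12)
  expect_true(all(sp$events$amplitude_px > 0))
  # events are time-ordered and non-overlapping
  expect_true(all(diff(sp$events$peak_frame) > 0))
  expect_true(all(sp$events$peak_frame < sp$events$trough_frame))
  expect_true(all(head(sp$events$trough_frame, -1) <=
                  tail(sp$events$peak_frame, -1)))
})

test_that("a constant-length object yields no stride events", {
  n <- 100
  det <- data.frame(frame = 0:(n - 1), found = TRUE,
                    centroid_x = 0, centroid_y = 0,
                    rect_l = 40, rect_w = 10)
  p <- tracked_path(det, fps = 15)
  sp <- stride_analysis(p)
  expect_equal(nrow(sp$events), 0)
  expect_true(is.na(sp$mean_amplitude_px))
})

test_that("turn windows are flagged and host no stride events", {
  fx <- larva_turn_fixture()
  p <- track(open_video(fx$video), red_range())
  sp <- stride_analysis(p)
  declared <- fx$ground_truth$frame[fx$ground_truth$turn]
  expect_gte(mean(declared %in% sp$turn_frames), 0.9)
  for (i in seq_len(nrow(sp$events))) {
    expect_false(any(declared >= sp$events$peak_frame[i] &
                     declared <= sp$events$trough_frame[i]))
  }
})

test_that("mean amplitude is recovered within 10% across amplitudes under noise", {
  set.seed(33)
  for (amp in c(3, 6, 12)) {
    n <- 400
    t <- 0:(n - 1)
    len <- 40 + amp * sin(2 * pi * t / 40) + runif(n, -0.5, 0.5)
    det <- data.frame(frame = t, found = TRUE, centroid_x = 0,
                      centroid_y = 0, rect_l = len, rect_w = 10)
    p <- tracked_path(det, fps = 15)
    sp <- stride_analysis(p, min_prominence_px = amp)
    expect_lt(abs(sp$mean_amplitude_px - 2 * amp), 0.1 * 2 * amp)
  }
})

test_that("stride count on noiseless sinusoids matches the analytic pair count", {
  for (period in c(12, 20, 40)) {
    n <- 10 * period
    t <- 0:(n - 1)
    len <- 40 + 6 * sin(2 * pi * t / period)
    det <- data.frame(frame = t, found = TRUE, centroid_x = 0,
                      centroid_y = 0, rect_l = len, rect_w = 10)
    p <- tracked_path(det, fps = 15)
    sp <- stride_analysis(p, smooth_window = 5)
    k <- 5
    smoothed <- as.numeric(stats::filter(len, rep(1 / k, k), sides = 2))
    expect_equal(nrow(sp$events), brute_stride_pairs(smoothed),
                 info = paste("period", period))
  }
})
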