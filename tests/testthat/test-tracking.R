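test_that("step distance is the Euclidean norm", {
  expect_equal(step_distance(c(0, 0), c(3, 4)), 5.0)
  expect_equal(step_distance(c(7, 7), c(7, 7)), 0.0)
  expect_equal(step_distance(c(1, 1), c(2, 2)), sqrt(2))
})

test_that("tracking the linear-motion fixture recovers the ground truth", {
  fx <- disc_fixture()
  p <- disc_path()
  det <- p$detections
  expect_equal(nrow(det), 60)
  expect_true(all(det$found))
  err <- sqrt((det$centroid_x - fx$ground_truth$cx)^2 +
              (det$centroid_y - fx$ground_truth$cy)^2)
  expect_lt(sqrt(mean(err^2)), 1)
  expect_lt(abs(total_distance(p) - 118), 2)
})

test_that("an absurd threshold yields 60 not-found frames and zero distance", {
  fx <- disc_fixture()
  v <- open_video(fx$video)
  expect_warning(p <- track(v, hsv_range(90, 150, 0.9, 1, 0.9, 1)),
                 "no frame")
  expect_equal(nrow(p$detections), 60)
  expect_false(any(p$detections$found))
  expect_equal(total_distance(p), 0)
  expect_equal(path_summary(p)$n_detected, 0)
})

test_that("re-running the same job writes a byte-identical path CSV", {
  fx <- disc_fixture()
  v <- open_video(fx$video)
  f1 <- file.path(tempdir(), "det1.csv")
  f2 <- file.path(tempdir(), "det2.csv")
  write_path_csv(track(v, red_range()), f1)
  write_path_csv(track(v, red_range()), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("distance skips not-found frames and bridges or skips gaps", {
  # frames 0,1,2 found at x=0,3,6; frames 3,4 lost; frame 5 found at x=12
  det <- data.frame(frame = 0:5,
                    found = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                    centroid_x = c(0, 3, 6, NA, NA, 12),
                    centroid_y = 0)
  p <- tracked_path(det, fps = 30)
  expect_equal(total_distance(p, gap_policy = "bridge"), 3 + 3 + 6)
  expect_equal(total_distance(p, gap_policy = "skip"), 3 + 3)

  single <- tracked_path(det[3, ], fps = 30)
  expect_equal(total_distance(single), 0)
})

test_that("doubling pixels_per_mm halves the reported distance exactly", {
  p1 <- path_from_xy(c(0, 3, 6, 9), rep(0, 4),
                     scale = calibrate_scale(100, 100))
  p2 <- path_from_xy(c(0, 3, 6, 9), rep(0, 4),
                     scale = calibrate_scale(200, 100))
  expect_equal(total_distance(p1), 2 * total_distance(p2))
})

test_that("total distance is translation-invariant and obeys the triangle inequality", {
  set.seed(3)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  p <- path_from_xy(x, y)
  q <- path_from_xy(x + 137.5, y - 42.25)
  expect_equal(total_distance(p), total_distance(q), tolerance = 1e-12)
  straight <- step_distance(c(x[1], y[1]), c(x[50], y[50]))
  expect_gte(total_distance(p), straight)
})

test_that("a time-reversed video gives the same total distance", {
  fx <- disc_fixture()
  spec <- fx$spec
  rev_spec <- trajectory_spec(spec$centres[60:1, ], spec$shape,
                              n_frames = 60, fps = 30,
                              width = 320, height = 240)
  out <- render_video(rev_spec, file.path(tempdir(), "rev.avi"))
  p_rev <- track(open_video(out$video), red_range())
  expect_equal(total_distance(p_rev), total_distance(disc_path()),
               tolerance = 0.01)
})

test_that("multi-colour tracking follows each disc through a crossing", {
  n <- 40
  # diagonals that cross in space but at different times, so neither disc
  # ever occludes the other
  red_c <- linear_trajectory(c(30, 30), c(2, 2), n)
  blue_c <- linear_trajectory(c(108, 56), c(-2, 2), n)
  sp_r <- trajectory_spec(red_c, shape_disc(6), n, 30, 160, 160,
                          colour = c(0, 1, 1))
  sp_b <- trajectory_spec(blue_c, shape_disc(6), n, 30, 160, 160,
                          colour = c(240, 1, 1))
  # compose the two-disc video: render each and merge masks by overpainting
  f_r <- file.path(tempdir(), "multi_r.avi")
  f_b <- file.path(tempdir(), "multi_b.avi")
  render_video(sp_r, f_r)
  render_video(sp_b, f_b)
  vr <- open_video(f_r); vb <- open_video(f_b)
  frames <- lapply(0:(n - 1), function(i) {
    fr <- read_frame(vr, i); fb <- read_frame(vb, i)
    blue_px <- fb[, , 3] == 255L & fb[, , 1] == 0L
    for (ch in 1:3) {
      plane <- fr[, , ch]
      plane[blue_px] <- fb[, , ch][blue_px]
      fr[, , ch] <- plane
    }
    fr
  })
  f2 <- file.path(tempdir(), "multi.avi")
  animtrack:::write_avi(frames, f2, 30)

  paths <- track_multi(open_video(f2),
                       list(red = red_range(), blue = blue_range()))
  expect_named(paths, c("red", "blue"))
  for (i in seq_len(n)) {
    expect_lt(abs(paths$red$detections$centroid_x[i] - red_c[i, 1]), 1.5)
    expect_lt(abs(paths$red$detections$centroid_y[i] - red_c[i, 2]), 1.5)
    expect_lt(abs(paths$blue$detections$centroid_x[i] - blue_c[i, 1]), 1.5)
    expect_lt(abs(paths$blue$detections$centroid_y[i] - blue_c[i, 2]), 1.5)
  }

  # a single range reproduces track(); duplicate names are rejected
  solo <- track_multi(open_video(f2), list(red = red_range()))
  expect_equal(solo$red$detections,
               track(open_video(f2), red_range())$detections)
  expect_error(track_multi(open_video(f2),
                           setNames(list(red_range(), red_range()),
                                    c("a", "a"))),
               "unique")
  expect_error(track_multi(open_video(f2),
                           list(red_range())), "named")
})

test_that("two ranges matching the same object give identical paths", {
  fx <- disc_fixture()
  v <- open_video(fx$video)
  paths <- track_multi(v, list(a = red_range(),
                               b = hsv_range(340, 20, 0.4, 1, 0.4, 1)))
  expect_equal(paths$a$detections, paths$b$detections)
})

test_that("settings files reproduce a run bit for bit", {
  fx <- disc_fixture()
  v <- open_video(fx$video)
  p <- track(v, red_range(), scale = calibrate_scale(600, 300),
             min_area = 25)
  sfile <- file.path(tempdir(), "run.settings.txt")
  write_settings(p, sfile, video_path = fx$video, min_area = 25)

  p2 <- track_from_settings(sfile)
  f1 <- file.path(tempdir(), "orig.csv"); f2 <- file.path(tempdir(), "redo.csv")
  write_path_csv(p, f1); write_path_csv(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(p2$scale$pixels_per_mm, 2)
})

test_that("summary rows carry frame counts, distance and scaling factor", {
  p <- path_from_xy(c(0, 3, 6), c(0, 4, 8), scale = calibrate_scale(2, 1))
  s <- path_summary(p)
  expect_equal(s$n_frames, 3)
  expect_equal(s$n_detected, 3)
  expect_equal(s$total_distance_mm, 5)      # two 5-px steps at 2 px/mm
  expect_equal(s$scaling_factor, 2)

  f <- file.path(tempdir(), "sum_append.csv")
  if (file.exists(f)) file.remove(f)
  append_summary(p, f)
  append_summary(p, f)
  got <- read.csv(f)
  expect_equal(nrow(got), 2)               # appended, not overwritten
})

test_that("path CSVs round-trip through read_path_csv", {
  p <- disc_path()
  f <- file.path(tempdir(), "roundtrip.csv")
  write_path_csv(p, f)
  q <- read_path_csv(f, fps = 30)
  expect_equal(q$detections$found, p$detections$found)
  expect_equal(q$detections$centroid_x, p$detections$centroid_x,
               tolerance = 1e-5)
  expect_equal(total_distance(q), total_distance(p), tolerance = 1e-4)
})
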