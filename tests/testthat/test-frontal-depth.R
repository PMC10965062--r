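# track with prescribed torso keypoints (gait coordinates)
torso_track <- function(neck_y, midhip_y, lsh_x = NULL, rsh_x = NULL, fps = 30) {
  n <- length(neck_y)
  manual_track(n, fps = fps, view = "frontal",
               neck = list(y = neck_y), mid_hip = list(y = midhip_y),
               l_shoulder = list(x = lsh_x %||% rep(0, n)),
               r_shoulder = list(x = rsh_x %||% rep(0, n)))
}

test_that("torso size follows the stated height/width/area definitions", {
  tr <- torso_track(neck_y = rep(400, 4), midhip_y = rep(100, 4),
                    lsh_x = rep(147, 4), rsh_x = rep(0, 4))
  expect_equal(torso_size_series(tr, "height")$size_px, rep(300, 4))
  expect_equal(torso_size_series(tr, "width")$size_px, rep(147, 4))
  expect_equal(torso_size_series(tr, "area")$size_px,
               rep(sqrt(300 * 147), 4))
  expect_equal(sqrt(300 * 147), 210)
})

test_that("size ratio is the identity at constant size and scales linearly", {
  tr <- torso_track(rep(310, 20), rep(100, 20))
  sz <- size_ratio(torso_size_series(tr, "height"), ref_frames = 0:9,
                   cutoff_hz = NULL)
  expect_equal(sz$s_ratio, rep(1, 20))
  expect_equal(attr(sz, "s_ref"), 210)

  tr2 <- torso_track(c(rep(310, 10), rep(205, 10)), rep(100, 20))
  sz2 <- size_ratio(torso_size_series(tr2, "height"), ref_frames = 0:9,
                    cutoff_hz = NULL)
  expect_equal(sz2$s_ratio[15], 0.5)

  empty_ref <- torso_track(c(NA, NA, 300), c(NA, NA, 100))
  expect_error(size_ratio(torso_size_series(empty_ref, "height"), 0:1),
               class = "videogait_data_error")
})

test_that("depth change inverts the pinhole size ratio", {
  sz <- torso_track(rep(300, 5), rep(0, 5)) |>
    torso_size_series("height") |>
    size_ratio(ref_frames = 0:4, cutoff_hz = NULL)
  expect_equal(depth_change(sz, d_ref = 4.88)$delta_d, rep(0, 5))

  # halved apparent size doubles the distance: delta d equals d_ref
  sz$s_ratio <- rep(0.5, 5)
  expect_equal(depth_change(sz, 4.88)$delta_d, rep(4.88, 5))

  sz$s_ratio[3] <- -0.1
  expect_error(depth_change(sz, 4.88), class = "videogait_data_error")
  sz$s_ratio[3] <- 0.5
  expect_error(depth_change(sz, -1), class = "videogait_config_error")
})

test_that("depth recovery is exact over the validated range of depth-changes", {
  # rigid subject at reference depth 4.88 m moved out to +20 m (covers the
  # validated 18.29 m), projected by an ideal pinhole and inverted
  d_ref <- 4.88
  f <- 1400; s_true <- 0.5
  dd <- seq(0, 20, by = 0.25)
  sizes <- f * s_true / (d_ref + dd)
  n <- length(sizes)
  tr <- torso_track(neck_y = sizes, midhip_y = rep(0, n))
  sz <- size_ratio(torso_size_series(tr, "height"),
                   ref_frames = 0L, cutoff_hz = NULL)
  est <- depth_change(sz, d_ref)$delta_d
  expect_lt(max(abs(est - dd)), 1e-9)
})

test_that("neither the focal length nor the subject's true size matters", {
  d_ref <- 3.2
  dd <- seq(0, 12, by = 0.5)
  est <- lapply(list(c(900, 0.45), c(2100, 0.61)), function(p) {
    sizes <- p[1] * p[2] / (d_ref + dd)
    tr <- torso_track(sizes, rep(0, length(sizes)))
    sz <- size_ratio(torso_size_series(tr, "height"), 0L, cutoff_hz = NULL)
    depth_change(sz, d_ref)$delta_d
  })
  expect_equal(est[[1]], est[[2]], tolerance = 1e-12)
})

test_that("frontal step table applies the stated definitions", {
  fps <- 10
  n <- 31
  depth <- structure(
    tibble::tibble(frame = 0:(n - 1), time = (0:(n - 1)) / fps,
                   delta_d = seq(0, 3, length.out = n)),
    d_ref = 4.88, fps = fps, class = c("depth_series", "tbl_df", "tbl", "data.frame"))
  depth$delta_d[depth$time == 1.0] <- 1.0
  depth$delta_d[depth$time == 1.5] <- 1.6
  ev <- gait_events(tibble::tibble(time_s = c(1.0, 1.5), side = c("right", "left"),
                                   event = "heel_strike", source = "frontal"))
  st <- frontal_step_table(depth, ev)
  expect_identical(nrow(st), 1L)
  expect_equal(st$step_time_s, 0.5)
  expect_equal(st$step_length_m, 0.6)
  expect_equal(st$speed_mps, 1.2)
  expect_identical(st$side, "left")

  # fewer than two heel-strikes: empty table
  ev1 <- gait_events(ev[1, ])
  expect_identical(nrow(frontal_step_table(depth, ev1)), 0L)
})

test_that("marching in place yields zero step lengths", {
  fps <- 30
  n <- 61
  depth <- structure(
    tibble::tibble(frame = 0:(n - 1), time = (0:(n - 1)) / fps, delta_d = 0),
    d_ref = 2.5, fps = fps, class = c("depth_series", "tbl_df", "tbl", "data.frame"))
  ev <- gait_events(tibble::tibble(
    time_s = seq(0.3, 1.8, by = 0.3), side = rep(c("left", "right"), 3),
    event = "heel_strike", source = "frontal"))
  st <- frontal_step_table(depth, ev)
  expect_true(all(st$step_length_m == 0))
})

test_that("end-to-end frontal recovery matches the commanded walk", {
  sim <- quick_sim(duration = 6, step_length = 0.60)
  track <- project_walk(sim, frontal_camera(2.5, "away"))
  res <- analyze_frontal(track, d_ref = 2.5)
  expect_identical(res$params$direction, "away")   # inferred from size trend
  expect_lt(abs(mean(res$steps$speed_mps) / sim$truth$speed_mps - 1), 0.03)
  expect_lt(abs(mean(res$steps$step_length_m) -
                  mean(sim$truth$steps$torso_travel_m)), 0.03)
})

test_that("walking toward the camera mirrors the depth series of walking away", {
  sim <- quick_sim(duration = 3)
  total_walk <- max(sim$truth$pelvis$z)
  away <- analyze_frontal(project_walk(sim, frontal_camera(2.5, "away")),
                          d_ref = 2.5)
  toward <- analyze_frontal(project_walk(sim, frontal_camera(total_walk + 2.5, "toward")),
                            d_ref = total_walk + 2.5)
  expect_identical(toward$params$direction, "toward")
  # the same physical walk: both depth magnitudes track the pelvis advance
  expect_equal(max(away$depth$delta_d), max(-toward$depth$delta_d),
               tolerance = 0.05)
  expect_lt(mean(abs(away$depth$delta_d - (-toward$depth$delta_d))), 0.05)
})

test_that("tracking-method grid evaluation ranks the truthful method first", {
  sim <- quick_sim(duration = 4)
  track <- to_gait_coordinates(project_walk(sim, frontal_camera(2.5, "away")))
  ev <- detect_events_frontal(track)
  truth <- sim$truth$steps
  truth$step_length_m <- truth$torso_travel_m
  rank <- evaluate_tracking_methods(track, ev, truth, d_ref = 2.5,
                                    methods = c("height", "width", "area"),
                                    cutoffs = c(0.4))
  expect_identical(nrow(rank), 3L)
  # per-step MAE of the best combination is on the scale the method achieves
  expect_lt(rank$mae_m[1], 0.08)
  expect_true(all(diff(rank$mae_m) >= 0))

  # single-cell grid
  r1 <- evaluate_tracking_methods(track, ev, truth, d_ref = 2.5,
                                  methods = "height", cutoffs = 0.4)
  expect_identical(nrow(r1), 1L)

  # duplicated methods tie and keep declaration order
  r2 <- evaluate_tracking_methods(track, ev, truth, d_ref = 2.5,
                                  methods = c("height", "height"), cutoffs = 0.4)
  expect_equal(r2$mae_m[1], r2$mae_m[2])

  expect_error(evaluate_tracking_methods(track, ev, truth, 2.5,
                                         methods = character(0)),
               class = "videogait_config_error")
})
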