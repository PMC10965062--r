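# a sagittal-style track whose ankle-relative-to-midhip signals are known
relative_signal_track <- function(left, right = -left, fps = 30) {
  n <- length(left)
  manual_track(n, fps = fps, l_ankle = list(x = left),
               r_ankle = list(x = right), mid_hip = list(x = rep(0, n)))
}

test_that("sagittal events sit at the analytic peaks of the relative signal", {
  fps <- 30
  t <- seq(0, 5, by = 1 / fps)
  rel <- 0.3 * sin(2 * pi * 0.9 * t)
  ev <- detect_events_sagittal(relative_signal_track(rel, fps = fps))
  hs <- ev$time_s[ev$event == "heel_strike" & ev$side == "left"]
  analytic <- (0.25 + 0:4) / 0.9
  expect_equal(length(hs), length(analytic))
  expect_lt(max(abs(hs - analytic)), 1 / fps)
  # toe-offs at the negative peaks
  to <- ev$time_s[ev$event == "toe_off" & ev$side == "left"]
  expect_lt(max(abs(to - (0.75 + 0:3) / 0.9)), 1 / fps)
})

test_that("a constant relative signal yields no events", {
  ev <- suppressWarnings(detect_events_sagittal(relative_signal_track(rep(0.2, 90))))
  expect_identical(nrow(ev), 0L)
  # and a signal too short for any peak warns (once per side) and is empty
  expect_warning(
    expect_warning(detect_events_sagittal(relative_signal_track(c(0, 1))),
                   regexp = "too short"),
    regexp = "too short")
})

test_that("frontal side rule maps peaks by walking direction", {
  fps <- 30
  t <- seq(0, 2.5, by = 1 / fps)
  # +A at t = 1.0, -A at t = 1.5
  sig <- 40 * sin(2 * pi * 1 * (t - 0.75)) * (t >= 0.75 & t <= 1.75)
  tr <- manual_track(length(t), fps = fps, view = "frontal",
                     l_ankle = list(y = sig), r_ankle = list(y = rep(0, length(t))))
  away <- detect_events_frontal(tr, "away")
  expect_equal(away$side[which.min(abs(away$time_s - 1.0))], "left")
  expect_equal(away$side[which.min(abs(away$time_s - 1.5))], "right")
  expect_true(all(away$event == "heel_strike"))

  toward <- detect_events_frontal(tr, "toward")
  expect_equal(toward$side[which.min(abs(toward$time_s - 1.0))], "right")
  expect_equal(toward$side[which.min(abs(toward$time_s - 1.5))], "left")

  # reversing direction permutes the labels and nothing else
  flipped <- toward
  expect_identical(away$time_s, flipped$time_s)
  expect_identical(away$side, ifelse(flipped$side == "left", "right", "left"))
})

test_that("an entirely missing ankle is a detection error", {
  tr <- manual_track(60, view = "frontal", l_ankle = list(y = sin(1:60 / 3)))
  xm <- tr
  xm$x[xm$keypoint == "r_ankle"] <- NA
  xm$y[xm$keypoint == "r_ankle"] <- NA
  expect_error(detect_events_frontal(xm, "away"), class = "videogait_data_error")
})

test_that("mocap detector recovers sinusoidal peaks and degenerates cleanly", {
  fps <- 100
  t <- seq(0, 4, by = 1 / fps)
  la <- 0.3 * sin(2 * pi * 1 * t); ra <- -la
  torso <- rep(0, length(t))
  ev <- detect_events_mocap(la, ra, torso, fps)
  hs <- ev$time_s[ev$side == "left" & ev$event == "heel_strike"]
  expect_lt(max(abs(hs - (0.25 + 0:3))), 1 / fps)

  # equal ankle and torso trajectories give a zero signal and no events
  ev0 <- suppressWarnings(detect_events_mocap(torso, torso, torso, fps))
  expect_identical(nrow(ev0), 0L)
})

test_that("all three detectors agree with ground truth on a noiseless walk", {
  # commanded step time is a whole number of frames so the true footfalls lie
  # on the sampling grid; the initiation footfall (labeled by the generator)
  # is excluded as a transient
  fps <- 25
  sim <- quick_sim(duration = 4, fps = fps, step_time = 0.56)
  truth_all <- truth_hs(sim)
  truth <- truth_all[-1]

  sag <- detect_events_sagittal(
    lowpass_zero_lag(to_gait_coordinates(project_walk(sim, sagittal_camera("left"))),
                     cutoff_hz = 5))
  expect_lte(max_event_error_frames(sag, truth, fps), 1)

  fro <- detect_events_frontal(
    to_gait_coordinates(project_walk(sim, frontal_camera(2.5, "away"))))
  expect_lte(max_event_error_frames(fro, truth, fps), 1)

  ank_l <- sim$traj$z[sim$traj$keypoint == "l_ankle"]
  ank_r <- sim$traj$z[sim$traj$keypoint == "r_ankle"]
  torso <- sim$truth$pelvis$z
  moc <- detect_events_mocap(ank_l, ank_r, torso, fps)
  expect_lte(max_event_error_frames(moc, truth, fps), 1)

  # identical step counts across detectors
  expect_identical(length(hs_times(sag)), length(truth_all))
  expect_identical(length(hs_times(fro)), length(truth_all))
  expect_identical(length(hs_times(moc)), length(truth_all))
})

test_that("event detection is invariant to uniform keypoint translation", {
  sim <- quick_sim(duration = 3)
  tr <- to_gait_coordinates(project_walk(sim, sagittal_camera("left")))
  shifted <- tr
  shifted$x <- shifted$x + 123.4
  shifted$y <- shifted$y - 55.5
  expect_equal(detect_events_sagittal(shifted)$time_s,
               detect_events_sagittal(tr)$time_s)
})

test_that("alternation violations are flagged, not dropped", {
  ev <- gait_events(tibble::tibble(
    time_s = c(1, 1.5, 2.0), side = c("left", "left", "right"),
    event = "heel_strike", source = "mocap"))
  expect_identical(nrow(ev), 3L)
  expect_identical(event_flags(ev)$time_s, 1.5)
})

test_that("cross-referencing matches same cycles and isolates spurious events", {
  a <- gait_events(tibble::tibble(
    time_s = seq(1, 4, by = 0.5), side = rep(c("left", "right"), 4)[1:7],
    event = "heel_strike", source = "mocap"))

  m_id <- cross_reference_events(a, a)
  expect_identical(nrow(m_id$matched), 7L)
  expect_identical(nrow(m_id$unmatched_a), 0L)

  b <- a
  b$time_s <- b$time_s + 0.125   # half the tolerance
  m_sh <- cross_reference_events(a, gait_events(b), tol_s = 0.25)
  expect_identical(nrow(m_sh$matched), 7L)

  spur <- gait_events(dplyr::bind_rows(
    tibble::as_tibble(a),
    tibble::tibble(time_s = 10, side = "left", event = "heel_strike",
                   source = "mocap")))
  m_sp <- cross_reference_events(a, spur)
  expect_identical(nrow(m_sp$matched), 7L)
  expect_identical(m_sp$unmatched_b$time_s, 10)
  # each event participates in at most one pair
  expect_false(any(duplicated(m_sp$matched$time_b)))
})

test_that("events survive a CSV round trip", {
  sim <- quick_sim(duration = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(sim$truth$events, path)
  back <- read_events_csv(path)
  expect_equal(back$time_s, sim$truth$events$time_s)
  expect_identical(back$side, sim$truth$events$side)
})
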