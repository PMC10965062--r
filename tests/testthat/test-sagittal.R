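test_that("scale factor is the known distance over its pixel length", {
  expect_equal(scale_factor(1.0, 100), 0.01)
  expect_equal(scale_factor(4.83, 966), 0.005)
  expect_error(scale_factor(-1, 100), class = "videogait_config_error")
  expect_error(scale_factor(1, 0), class = "videogait_config_error")

  # simulator geometry: a known distance at the walking plane spans
  # f * known / depth pixels, so the recovered scale is depth / f
  cam <- sagittal_camera("left", distance_m = 3.89, f_px = 1100)
  known_px <- cam$f_px * 4.83 / 3.89
  expect_equal(scale_factor(4.83, known_px), 3.89 / 1100, tolerance = 1e-12)
})

test_that("sagittal step lengths follow the chosen definition", {
  # ankles 120 px apart at the heel-strike instant, scale 0.005 m/px
  fps <- 10
  n <- 21
  lx <- rep(160, n); rx <- rep(40, n)
  tr <- manual_track(n, fps = fps, l_ankle = list(x = lx),
                     r_ankle = list(x = rx),
                     mid_hip = list(x = seq(0, 200, length.out = n)))
  ev <- gait_events(tibble::tibble(time_s = c(0.5, 1.0),
                                   side = c("right", "left"),
                                   event = "heel_strike", source = "sagittal"))
  st <- sagittal_step_table(tr, ev, scale = 0.005, method = "ankle_distance")
  expect_equal(st$step_length_m, 0.60)
  expect_identical(st$side, "left")

  # torso travel: mid-hip advances 100 px/s, i.e. 50 px over the 0.5 s step
  st2 <- sagittal_step_table(tr, ev, scale = 0.005, method = "torso_travel")
  expect_equal(st2$step_length_m, 0.005 * 50)

  expect_identical(nrow(sagittal_step_table(tr, gait_events(ev[1, ]), 0.005)), 0L)
})

test_that("noiseless in-plane walker recovers the commanded step length", {
  # in-plane: zero hip width puts both legs on the calibration plane; event
  # times supplied externally (the workflow's motion-capture-events mode)
  sim <- quick_sim(duration = 4, fps = 25, step_time = 0.56, hip_width_m = 0,
                   step_length = 0.65)
  track <- project_walk(sim, sagittal_camera("left"))
  res <- analyze_sagittal(track, scale = 3.89 / 1100,
                          events = sim$truth$events)
  expect_lt(abs(mean(res$steps$step_length_m) - 0.65), 0.01)
  expect_lt(max(abs(res$steps$step_time_s - 0.56)), 1 / 25)
  # same step count under both step-length definitions
  res2 <- analyze_sagittal(track, scale = 3.89 / 1100,
                           events = sim$truth$events,
                           step_method = "torso_travel")
  expect_identical(nrow(res2$steps), nrow(res$steps))
})

test_that("torso travel exceeds ankle distance when heels rise in late stance", {
  sim <- quick_sim(duration = 4, hip_width_m = 0, heel_rise_m = 0.06)
  track <- project_walk(sim, sagittal_camera("left"))
  ank <- analyze_sagittal(track, scale = 3.89 / 1100,
                          events = sim$truth$events)$steps
  tor <- analyze_sagittal(track, scale = 3.89 / 1100,
                          events = sim$truth$events,
                          step_method = "torso_travel")$steps
  # sign of the mean difference only, as the effect size is gait-dependent
  expect_gt(mean(tor$step_length_m) - mean(ank$step_length_m), 0)
})

test_that("joint angle conventions anchor at zero", {
  # vertical thigh and shank, horizontal foot: all three angles are zero
  n <- 3
  tr <- manual_track(n,
    l_hip = list(x = rep(0, n), y = rep(0.9, n)),
    l_knee = list(x = rep(0, n), y = rep(0.5, n)),
    l_ankle = list(x = rep(0, n), y = rep(0.1, n)),
    l_big_toe = list(x = rep(0.2, n), y = rep(0.1, n)))
  ang <- joint_angles(tr)
  left <- ang[ang$side == "left", ]
  expect_equal(left$angle_deg[left$joint == "hip"], rep(0, n), tolerance = 1e-12)
  expect_equal(left$angle_deg[left$joint == "knee"], rep(0, n), tolerance = 1e-12)
  expect_equal(left$angle_deg[left$joint == "ankle"], rep(0, n), tolerance = 1e-12)

  # thigh-shank interior angle of 150 degrees means 30 degrees knee flexion
  # (ankle displaced backwards relative to the thigh line)
  tr2 <- manual_track(n,
    l_hip = list(x = rep(0, n), y = rep(0.9, n)),
    l_knee = list(x = rep(0, n), y = rep(0.5, n)),
    l_ankle = list(x = rep(-0.4 * sin(pi / 6), n),
                   y = rep(0.5 - 0.4 * cos(pi / 6), n)),
    l_big_toe = list(x = rep(0.2, n), y = rep(0.2, n)))
  ang2 <- joint_angles(tr2)
  knee2 <- ang2$angle_deg[ang2$side == "left" & ang2$joint == "knee"]
  expect_equal(knee2, rep(30, n), tolerance = 1e-9)
})

test_that("keypoint joint angles match the walker's true curves", {
  sim <- quick_sim(duration = 4, hip_width_m = 0)
  res <- analyze_sagittal(project_walk(sim, sagittal_camera("left")),
                          scale = 3.89 / 1100, events = sim$truth$events)
  mae <- kinematic_mae(res$angles, sim$truth$angles, sim$truth$events)
  expect_identical(nrow(mae), 6L)
  expect_lt(max(mae$mae_deg), 1)
})

test_that("joint angles are invariant to translation and scale, and mirror", {
  sim <- quick_sim(duration = 3)
  tr <- to_gait_coordinates(project_walk(sim, sagittal_camera("left")))
  base <- joint_angles(tr)

  moved <- tr
  moved$x <- 2.2 * moved$x + 77
  moved$y <- 2.2 * moved$y - 13
  expect_equal(joint_angles(moved)$angle_deg, base$angle_deg, tolerance = 1e-9)

  # mirroring the horizontal axis flips flexion signs; the ankle convention
  # measures from a 90-degree neutral, so its reflection is -angle - 180
  mirrored <- tr
  mirrored$x <- -mirrored$x
  mang <- joint_angles(mirrored)
  hip_knee <- base$joint %in% c("hip", "knee")
  expect_equal(mang$angle_deg[hip_knee], -base$angle_deg[hip_knee],
               tolerance = 1e-9)
  ankle <- base$joint == "ankle"
  expect_equal(mang$angle_deg[ankle], -base$angle_deg[ankle] - 180,
               tolerance = 1e-9)
})

test_that("trunk inclination applies the fixed keypoint-vs-marker offset", {
  n <- 5
  ev <- gait_events(tibble::tibble(time_s = 0.1, side = "left",
                                   event = "heel_strike", source = "sagittal"))
  # neck directly above the mid-hip: raw 0, corrected -12
  tr <- manual_track(n, neck = list(x = rep(0, n), y = rep(1.4, n)),
                     mid_hip = list(x = rep(0, n), y = rep(0.9, n)))
  ti <- trunk_inclination(tr, ev)
  expect_equal(ti$raw_deg, 0)
  expect_equal(ti$inclination_deg, -12)

  # neck 20 degrees forward of vertical: raw 20, corrected 8
  tr2 <- manual_track(n, neck = list(x = rep(0.5 * tan(20 * pi / 180), n),
                                     y = rep(1.4, n)),
                      mid_hip = list(x = rep(0, n), y = rep(0.9, n)))
  ti2 <- trunk_inclination(tr2, ev)
  expect_equal(ti2$raw_deg, 20, tolerance = 1e-9)
  expect_equal(ti2$inclination_deg, 8, tolerance = 1e-9)

  # missing neck at the event yields a missing value
  tr3 <- tr
  tr3$x[tr3$keypoint == "neck"] <- NA
  tr3$y[tr3$keypoint == "neck"] <- NA
  expect_true(is.na(trunk_inclination(tr3, ev)$inclination_deg))
})

test_that("commanded trunk lean is recovered at heel-strikes", {
  sim <- quick_sim(duration = 4, trunk_lean_deg = 15, hip_width_m = 0)
  res <- analyze_sagittal(project_walk(sim, sagittal_camera("left")),
                          scale = 3.89 / 1100, events = sim$truth$events)
  expect_equal(mean(res$trunk$inclination_deg, na.rm = TRUE), 15 - 12,
               tolerance = 1)
})

test_that("marker tables round-trip through the long CSV format", {
  sim <- quick_sim(duration = 2)
  markers <- dplyr::rename(sim$traj, marker = "keypoint", time_s = "time")
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(markers, path)
  back <- read_marker_csv(path)
  expect_equal(back$x, markers$x)
  expect_identical(unique(back$marker), body25_keypoints)
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1), bad)
  expect_error(read_marker_csv(bad), class = "videogait_format_error")
})
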