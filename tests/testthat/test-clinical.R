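test_that("asymmetry index follows the difference-over-sum definition", {
  expect_equal(asymmetry(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(asymmetry(0.6, 0.4), 0.2)
  # antisymmetric under side exchange and bounded for positive values
  set.seed(2)
  for (i in 1:25) {
    a <- runif(5, 0.1, 1.5); b <- runif(5, 0.1, 1.5)
    expect_equal(asymmetry(a, b), -asymmetry(b, a), tolerance = 1e-12)
    expect_lt(abs(asymmetry(a, b)), 1)
  }
  expect_error(asymmetry(numeric(0), 1), class = "videogait_data_error")
  expect_error(asymmetry(-2, 1), class = "videogait_data_error")
})

test_that("steps take the side of their terminating heel-strike", {
  ev <- gait_events(tibble::tibble(
    time_s = c(1.0, 1.5, 2.1), side = c("right", "left", "right"),
    event = "heel_strike", source = "sagittal"))
  st <- assign_step_sides(ev)
  expect_equal(st$step_time_s[st$side == "left"], 0.5)
  expect_equal(st$step_time_s[st$side == "right"], 0.6)
  expect_true(all(st$valid))

  # a single heel-strike defines no step
  st1 <- assign_step_sides(gait_events(ev[1, ]))
  expect_identical(nrow(st1), 0L)

  # two consecutive same-side heel-strikes flag an invalid step
  ev2 <- gait_events(tibble::tibble(
    time_s = c(1.0, 1.5, 2.0), side = c("right", "right", "left"),
    event = "heel_strike", source = "sagittal"))
  st2 <- assign_step_sides(ev2)
  expect_identical(st2$valid, c(FALSE, TRUE))
})

test_that("simulator footfall sides are assigned with full agreement", {
  sim <- quick_sim(duration = 5)
  st <- assign_step_sides(sim$truth$events)
  truth <- sim$truth$steps
  expect_identical(st$side, truth$side)
  expect_equal(st$step_time_s, truth$step_time_s)
})

test_that("commanded step-length asymmetry is recovered from sagittal video", {
  asym_cmd <- 0.10
  L <- 0.65
  sim <- quick_sim(duration = 5, hip_width_m = 0,
                   step_length = c(left = L * (1 + asym_cmd),
                                   right = L * (1 - asym_cmd)))
  res <- analyze_sagittal(project_walk(sim, sagittal_camera("left")),
                          scale = 3.89 / 1100, events = sim$truth$events)
  est <- asymmetry(res$steps$step_length_m[res$steps$side == "left"],
                   res$steps$step_length_m[res$steps$side == "right"])
  expect_lt(abs(est - asym_cmd), 0.02)

  # symmetric gait: zero asymmetry
  sim0 <- quick_sim(duration = 5, hip_width_m = 0)
  res0 <- analyze_sagittal(project_walk(sim0, sagittal_camera("left")),
                           scale = 3.89 / 1100, events = sim0$truth$events)
  est0 <- asymmetry(res0$steps$step_length_m[res0$steps$side == "left"],
                    res0$steps$step_length_m[res0$steps$side == "right"])
  expect_lt(abs(est0), 0.02)
})

make_steps <- function(trial_id, times, lengths, sides = NULL) {
  n <- length(times)
  sides <- sides %||% rep(c("left", "right"), length.out = n)
  tibble::tibble(trial_id = trial_id, condition = "preferred", side = sides,
                 t_start = seq_len(n) - 1, t_end = seq_len(n),
                 step_time_s = times, step_length_m = lengths,
                 speed_mps = lengths / times, method = "ankle_distance")
}

test_that("session summaries average trial means, not pooled steps", {
  one <- make_steps("t1", rep(0.5, 4), rep(0.6, 4))
  s1 <- session_summary(one)
  expect_equal(s1$speed_mps, 1.2)
  expect_identical(s1$n_trials, 1L)

  # trial means 1.0 and 1.2 m/s -> session 1.1, regardless of step counts
  two <- dplyr::bind_rows(
    make_steps("t1", rep(0.5, 2), rep(0.5, 2)),
    make_steps("t2", rep(0.5, 8), rep(0.6, 8)))
  s2 <- session_summary(two)
  expect_equal(s2$speed_mps, 1.1)
  expect_identical(s2$n_steps, 10L)
  # pooled mode weights every step equally instead
  s2p <- session_summary(two, pooled = TRUE)
  expect_equal(s2p$speed_mps, (2 * 1.0 + 8 * 1.2) / 10)

  expect_error(session_summary(make_steps("x", numeric(0), numeric(0))),
               class = "videogait_data_error")
})

test_that("session averaging is permutation-invariant over trials", {
  trials <- list(make_steps("a", rep(0.6, 3), rep(0.7, 3)),
                 make_steps("b", rep(0.5, 5), rep(0.6, 5)),
                 make_steps("c", rep(0.55, 4), rep(0.62, 4)))
  s_fwd <- session_summary(dplyr::bind_rows(trials))
  s_rev <- session_summary(dplyr::bind_rows(rev(trials)))
  expect_equal(s_fwd$speed_mps, s_rev$speed_mps)
  expect_equal(s_fwd$step_length_asym, s_rev$step_length_asym)
})

test_that("speed change is the elementwise fast-minus-preferred difference", {
  pref <- session_summary(make_steps("t1", rep(0.6, 4), rep(0.48, 4)))
  fast <- session_summary(make_steps("t1", rep(0.5, 4), rep(0.55, 4)))
  delta <- speed_change(pref, fast)
  expect_equal(delta$speed_mps, 1.1 - 0.8)
  expect_equal(delta$step_time_s, -0.1)
  # identical sessions: all-zero deltas
  zero <- speed_change(pref, pref)
  expect_equal(zero$speed_mps, 0)
  expect_equal(zero$step_length_m, 0)
  # a parameter missing in one condition stays missing
  expect_true(is.na(delta$trunk_inclination_deg))
})

test_that("speed-change equals the difference of session means by construction", {
  sim_p <- quick_sim(duration = 4, step_length = 0.55, step_time = 0.6)
  sim_f <- quick_sim(duration = 4, step_length = 0.68, step_time = 0.52)
  mk <- function(sim, cond) {
    res <- analyze_sagittal(project_walk(sim, sagittal_camera("left")),
                            scale = 3.89 / 1100, events = sim$truth$events,
                            condition = cond)
    session_summary(res$steps, condition = cond)
  }
  sp <- mk(sim_p, "preferred"); sf <- mk(sim_f, "fast")
  d <- speed_change(sp, sf)
  expect_equal(d$speed_mps, sf$speed_mps - sp$speed_mps, tolerance = 1e-12)
  true_d <- sim_f$truth$speed_mps - sim_p$truth$speed_mps
  expect_lt(abs(d$speed_mps - true_d), 0.05)
})

test_that("step tables round-trip through CSV", {
  st <- make_steps("t1", rep(0.5, 4), rep(0.6, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_steps_csv(st, path)
  expect_equal(read_steps_csv(path)$step_length_m, st$step_length_m)
})
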