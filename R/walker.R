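#' Specify a synthetic walker
#'
#' Parameters of the kinematic 3D walker used to generate ground-truthed
#' walking trials. The walker is a prescribed-trajectory puppet, not a
#' dynamic model: the pelvis advances at the speed implied by the commanded
#' step lengths and times, feet alternate stance (fixed on the ground at
#' footfall targets spaced by the commanded step lengths) and swing (a
#' smooth lift-and-carry profile), knees follow from two-link inverse
#' kinematics, and the torso, shoulders and head ride rigidly on the pelvis
#' with a commanded forward lean. Segment dimensions default to standard
#' anthropometric fractions of stature.
#'
#' World coordinates: x lateral, y up (ground at 0), z the direction of
#' travel; the walker starts over z = 0 and walks in +z.
#'
#' @param stature Body height (m); segment defaults scale with it.
#' @param step_length Commanded step length (m): a scalar, or
#'   `c(left = , right = )` for asymmetric gait.
#' @param step_time Commanded step time (s): scalar or per-side like
#'   `step_length`.
#' @param duration Walking time (s), excluding the standing lead-in/out.
#' @param fps Sampling rate (Hz).
#' @param lead_in_s,lead_out_s Standing time before gait initiation and
#'   after termination (s); the initiation/termination steps themselves are
#'   part of `duration` and are labeled in the ground truth.
#' @param trunk_lean_deg Constant forward trunk lean (degrees).
#' @param first_side Side that takes the first step.
#' @param thigh_m,shank_m,ankle_height_m,foot_length_m,hip_width_m,
#'   shoulder_width_m,trunk_length_m Segment dimensions (m); `NULL` uses
#'   anthropometric fractions of stature.
#' @param hip_height_frac Hip-joint height as a fraction of leg length
#'   (thigh + shank) above the ankle; < 1 keeps the knees slightly flexed
#'   and the inverse kinematics feasible.
#' @param clearance_m Peak foot lift during swing (m).
#' @param bob_amp_m Amplitude of the pelvis vertical oscillation (m).
#' @param landing_speed_mps Residual forward speed of the ankle at foot
#'   contact (m/s). Real feet are decelerated late in swing but still touch
#'   down with a small forward speed that impact removes; this keeps the
#'   heel-strike near the exact maximum of the ankle's excursion relative to
#'   the pelvis while leaving the trajectory smooth enough that low-pass
#'   filtering does not blunt it.
#' @param speed_dip_frac Fractional dip of the pelvis forward speed at each
#'   heel-strike (double support) relative to the step average; the pelvis
#'   position at every heel-strike is unaffected.
#' @param heel_rise_m Forward travel of the trailing ankle during terminal
#'   stance (heel rise before toe-off), m. Zero keeps ankle-to-ankle
#'   distance at heel-strike exactly equal to the commanded step length; a
#'   positive value reproduces the real-gait effect that torso-travel step
#'   lengths exceed ankle-distance step lengths.
#' @param noise_px,dropout_p,swap_rate Corruption defaults passed to
#'   [corrupt_track()] by convenience wrappers; the pure kinematics are
#'   always noiseless.
#' @param seed Random seed for any corruption applied downstream.
#' @return A validated list of class `walker_spec`.
#' @export
walker_spec <- function(stature = 1.72,
                        step_length = 0.65, step_time = 0.55,
                        duration = 8, fps = 30,
                        lead_in_s = 1, lead_out_s = 1,
                        trunk_lean_deg = 5,
                        first_side = c("left", "right"),
                        thigh_m = NULL, shank_m = NULL,
                        ankle_height_m = NULL, foot_length_m = NULL,
                        hip_width_m = NULL, shoulder_width_m = NULL,
                        trunk_length_m = NULL,
                        hip_height_frac = 0.86,
                        clearance_m = 0.05, bob_amp_m = 0.015,
                        landing_speed_mps = 0.25, speed_dip_frac = 0.2,
                        heel_rise_m = 0,
                        noise_px = 0, dropout_p = 0, swap_rate = 0,
                        seed = 1L) {
  first_side <- match.arg(first_side)
  per_side <- function(x, what) {
    if (length(x) == 1L) x <- c(left = unname(x), right = unname(x))
    if (!all(c("left", "right") %in% names(x))) {
      abort(sprintf("`%s` must be a scalar or named c(left=, right=).", what),
            class = "videogait_config_error")
    }
    if (any(x <= 0)) abort(sprintf("`%s` must be positive.", what),
                           class = "videogait_config_error")
    x[c("left", "right")]
  }
  spec <- list(
    stature = stature,
    step_length = per_side(step_length, "step_length"),
    step_time = per_side(step_time, "step_time"),
    duration = duration, fps = fps,
    lead_in_s = lead_in_s, lead_out_s = lead_out_s,
    trunk_lean_deg = trunk_lean_deg, first_side = first_side,
    thigh_m = thigh_m %||% (0.245 * stature),
    shank_m = shank_m %||% (0.246 * stature),
    ankle_height_m = ankle_height_m %||% (0.039 * stature),
    foot_length_m = foot_length_m %||% (0.152 * stature),
    hip_width_m = hip_width_m %||% (0.10 * stature),
    shoulder_width_m = shoulder_width_m %||% (0.21 * stature),
    trunk_length_m = trunk_length_m %||% (0.30 * stature),
    hip_height_frac = hip_height_frac,
    clearance_m = clearance_m, bob_amp_m = bob_amp_m,
    landing_speed_mps = landing_speed_mps, speed_dip_frac = speed_dip_frac,
    heel_rise_m = heel_rise_m,
    noise_px = noise_px, dropout_p = dropout_p, swap_rate = swap_rate,
    seed = as.integer(seed)
  )
  for (f in c("stature", "duration", "fps", "thigh_m", "shank_m",
              "ankle_height_m", "foot_length_m",
              "shoulder_width_m", "trunk_length_m", "clearance_m")) {
    if (spec[[f]] <= 0) abort(sprintf("`%s` must be positive.", f),
                              class = "videogait_config_error")
  }
  # zero hip width is allowed: it collapses both legs onto the sagittal
  # mid-plane (an "in-plane" walker, free of out-of-plane projection error)
  if (spec$hip_width_m < 0) abort("`hip_width_m` must be >= 0.",
                                  class = "videogait_config_error")
  structure(spec, class = "walker_spec")
}

# cubic Hermite segment; s in [0, 1]
hermite <- function(s, p0, p1, v0, v1, dt) {
  (2 * s^3 - 3 * s^2 + 1) * p0 + (s^3 - 2 * s^2 + s) * dt * v0 +
    (-2 * s^3 + 3 * s^2) * p1 + (s^3 - s^2) * dt * v1
}

# swing carry profile: 0 -> 1, zero velocity at toe-off, `v_end` residual
# velocity (in carry units) at contact
swing_profile <- function(tau, v_end = 0) {
  tau^2 * (3 - 2 * tau) + v_end * tau^2 * (tau - 1)
}

#' Generate a ground-truthed synthetic walking trial
#'
#' Builds the full 3D keypoint kinematics of the walker described by a
#' [walker_spec()], together with the ground truth needed to score any
#' downstream analysis: exact heel-strike and toe-off times, per-step
#' lengths (commanded, realized ankle separation, and torso travel), the
#' pelvis trajectory (hence the true depth-change for any camera), true
#' joint-angle curves, and the trunk lean. The output is deterministic:
#' identical specs give bit-identical results.
#'
#' @param spec A [walker_spec()].
#' @return A list of class `walker_sim`: `traj` (long tibble `time`,
#'   `keypoint`, `x`, `y`, `z` over all 25 keypoints), `truth` (list with
#'   `events`, `steps`, `pelvis`, `angles`, `speed_mps`), and `spec`.
#' @export
simulate_walk <- function(spec) {
  sL <- spec$step_length; sT <- spec$step_time
  lead_in <- spec$lead_in_s
  t_total <- lead_in + spec$duration + spec$lead_out_s
  nf <- floor(t_total * spec$fps) + 1L
  tt <- (seq_len(nf) - 1L) / spec$fps

  # heel-strike schedule: sides alternate, positions advance by the
  # commanded step length of the landing side
  sides <- character(0); t_hs <- numeric(0); z_hs <- numeric(0)
  side <- spec$first_side
  t_cur <- lead_in; z_cur <- 0
  repeat {
    t_next <- t_cur + sT[[side]]
    if (t_next > lead_in + spec$duration + 1e-9) break
    z_cur <- z_cur + sL[[side]]
    sides <- c(sides, side); t_hs <- c(t_hs, t_next); z_hs <- c(z_hs, z_cur)
    t_cur <- t_next
    side <- setdiff(c("left", "right"), side)
  }
  if (length(t_hs) < 2L) {
    abort("duration too short: fewer than two steps fit the trial.",
          class = "videogait_config_error")
  }
  n_hs <- length(t_hs)

  # gait termination: a closing step brings the trailing foot up next to the
  # lead foot while the pelvis decelerates over the feet (so the final
  # heel-strike remains a prominent extremum of the relative signals)
  trail_side <- sides[n_hs - 1L]
  park_gap <- 0.15
  t_close <- min(sT[[trail_side]], spec$lead_out_s)
  z_close <- z_hs[n_hs] - park_gap

  # foot (ankle) trajectories: piecewise stance / heel-rise / swing
  hr <- spec$heel_rise_m
  ank_h <- spec$ankle_height_m
  foot_fun <- function(s) {
    idx <- which(sides == s)
    ss <- vapply(idx, function(k) if (k == 1L) lead_in else t_hs[k - 1L],
                 numeric(1))                       # swing starts
    tf <- t_hs[idx]; zf <- z_hs[idx]
    z_from <- c(0, zf[-length(zf)])
    clear <- rep(spec$clearance_m, length(tf))
    if (s == trail_side) {
      # closing step (labeled termination, not a gait-cycle event); a low
      # shuffle, as people close to standing without a full swing
      ss <- c(ss, t_hs[n_hs])
      tf <- c(tf, t_hs[n_hs] + t_close)
      z_from <- c(z_from, zf[length(zf)])
      zf <- c(zf, z_close)
      clear <- c(clear, 0.3 * spec$clearance_m)
    }
    rise_dur <- 0.3 * min(sT)
    function(t) {
      z <- numeric(length(t)); y <- rep(ank_h, length(t))
      # default: stance at the most recent footfall position
      z[] <- 0
      for (j in seq_along(tf)) z[t >= tf[j]] <- zf[j]
      for (j in seq_along(tf)) {
        # heel rise at the end of the preceding stance
        if (hr > 0) {
          in_rise <- t >= (ss[j] - rise_dur) & t < ss[j]
          if (any(in_rise)) {
            xi <- (t[in_rise] - (ss[j] - rise_dur)) / rise_dur
            sm <- xi^2 * (3 - 2 * xi)
            z[in_rise] <- z_from[j] + hr * sm
            y[in_rise] <- ank_h + 0.4 * hr * sm
          }
        }
        in_sw <- t >= ss[j] & t < tf[j]
        if (any(in_sw)) {
          tau <- (t[in_sw] - ss[j]) / (tf[j] - ss[j])
          z0 <- z_from[j] + hr
          carry <- zf[j] - z0
          v_end <- if (carry > 1e-6) {
            spec$landing_speed_mps * (tf[j] - ss[j]) / carry
          } else 0
          z[in_sw] <- z0 + carry * swing_profile(tau, v_end)
          y[in_sw] <- ank_h + clear[j] * 0.5 * (1 - cos(2 * pi * tau)) +
            (if (hr > 0) 0.4 * hr * (1 - tau) else 0)
        }
      }
      list(z = z, y = y)
    }
  }
  foot_l <- foot_fun("left"); foot_r <- foot_fun("right")

  # pelvis: constant speed between heel-strikes, smooth start/stop ramps
  p_k <- z_hs - vapply(sides, function(s) sL[[s]], numeric(1)) / 2
  v1 <- (p_k[2] - p_k[1]) / (t_hs[2] - t_hs[1])
  v_last <- (p_k[n_hs] - p_k[n_hs - 1L]) / (t_hs[n_hs] - t_hs[n_hs - 1L])
  # the pelvis decelerates over the closing step and stops centred above the
  # parked feet
  stop_dur <- t_close
  p_stop <- z_hs[n_hs] - park_gap / 2
  pelvis_z <- function(t) {
    z <- numeric(length(t))
    z[t <= lead_in] <- 0
    ramp <- t > lead_in & t < t_hs[1]
    if (any(ramp)) {
      s <- (t[ramp] - lead_in) / (t_hs[1] - lead_in)
      z[ramp] <- hermite(s, 0, p_k[1], 0, v1, t_hs[1] - lead_in)
    }
    a <- spec$speed_dip_frac
    for (k in seq_len(n_hs - 1L)) {
      seg <- t >= t_hs[k] & t < t_hs[k + 1L]
      if (any(seg)) {
        dt_k <- t_hs[k + 1L] - t_hs[k]
        tau <- (t[seg] - t_hs[k]) / dt_k
        v_k <- (p_k[k + 1L] - p_k[k]) / dt_k
        # forward speed dips by `a` at each heel-strike (double support) and
        # rises mid-step; zero net position offset at the heel-strikes
        z[seg] <- p_k[k] + v_k * dt_k * tau -
          a * v_k * dt_k / (2 * pi) * sin(2 * pi * tau)
      }
    }
    stop_end <- t_hs[n_hs] + stop_dur
    dec <- t >= t_hs[n_hs] & t < stop_end
    if (any(dec)) {
      s <- (t[dec] - t_hs[n_hs]) / stop_dur
      z[dec] <- hermite(s, p_k[n_hs], p_stop, v_last, 0, stop_dur)
    }
    z[t >= stop_end] <- p_stop
    z
  }

  # pelvis vertical bob: dips mid-step, zero at heel-strikes and at rest
  step_phase <- function(t) {
    tau <- numeric(length(t))
    knots <- c(lead_in, t_hs)
    for (k in seq_len(length(knots) - 1L)) {
      seg <- t >= knots[k] & t < knots[k + 1L]
      tau[seg] <- (t[seg] - knots[k]) / (knots[k + 1L] - knots[k])
    }
    tau
  }

  hip_h <- ank_h + spec$hip_height_frac * (spec$thigh_m + spec$shank_m)
  pz <- pelvis_z(tt)
  py <- hip_h - spec$bob_amp_m * sin(pi * step_phase(tt))
  fl <- foot_l(tt); fr <- foot_r(tt)

  # two-link inverse kinematics for the knees (per side, planar in y-z)
  knee_pos <- function(az, ay) {
    lt <- spec$thigh_m; ls <- spec$shank_m
    dz <- az - pz; dy <- ay - py
    d <- sqrt(dz^2 + dy^2)
    if (any(d > (lt + ls) * (1 - 1e-9))) {
      abort("commanded step length is infeasible for the leg geometry.",
            class = "videogait_infeasible")
    }
    gam <- acos(pmin(1, pmax(-1, (lt^2 + d^2 - ls^2) / (2 * lt * d))))
    uz <- dz / d; uy <- dy / d
    kz1 <- pz + lt * (uz * cos(gam) - uy * sin(gam))
    ky1 <- py + lt * (uz * sin(gam) + uy * cos(gam))
    kz2 <- pz + lt * (uz * cos(gam) + uy * sin(gam))
    ky2 <- py + lt * (uz * sin(-gam) + uy * cos(gam))
    fw <- kz1 >= kz2   # the anatomical knee points forward
    list(z = ifelse(fw, kz1, kz2), y = ifelse(fw, ky1, ky2))
  }
  kl <- knee_pos(fl$z, fl$y); kr <- knee_pos(fr$z, fr$y)

  lean <- spec$trunk_lean_deg * pi / 180
  neck_y <- py + spec$trunk_length_m * cos(lean)
  neck_z <- pz + spec$trunk_length_m * sin(lean)
  hw <- spec$hip_width_m / 2; sw <- spec$shoulder_width_m / 2
  flen_front <- spec$foot_length_m - 0.06

  kp <- function(x, y, z) list(x = rep_len(x, nf), y = rep_len(y, nf),
                               z = rep_len(z, nf))
  pts <- list(
    nose = kp(0, neck_y + 0.14, neck_z + 0.08),
    neck = kp(0, neck_y, neck_z),
    r_shoulder = kp(-sw, neck_y - 0.02, neck_z),
    r_elbow = kp(-sw - 0.01, neck_y - 0.32, neck_z),
    r_wrist = kp(-sw - 0.01, neck_y - 0.58, neck_z + 0.02),
    l_shoulder = kp(sw, neck_y - 0.02, neck_z),
    l_elbow = kp(sw + 0.01, neck_y - 0.32, neck_z),
    l_wrist = kp(sw + 0.01, neck_y - 0.58, neck_z + 0.02),
    mid_hip = kp(0, py, pz),
    r_hip = kp(-hw, py, pz),
    r_knee = kp(-hw, kr$y, kr$z),
    r_ankle = kp(-hw, fr$y, fr$z),
    l_hip = kp(hw, py, pz),
    l_knee = kp(hw, kl$y, kl$z),
    l_ankle = kp(hw, fl$y, fl$z),
    r_eye = kp(-0.035, neck_y + 0.16, neck_z + 0.07),
    l_eye = kp(0.035, neck_y + 0.16, neck_z + 0.07),
    r_ear = kp(-0.07, neck_y + 0.13, neck_z + 0.01),
    l_ear = kp(0.07, neck_y + 0.13, neck_z + 0.01),
    l_big_toe = kp(hw, fl$y - ank_h + 0.01, fl$z + flen_front),
    l_small_toe = kp(hw + 0.04, fl$y - ank_h + 0.01, fl$z + flen_front - 0.03),
    l_heel = kp(hw, fl$y - ank_h + 0.01, fl$z - 0.06),
    r_big_toe = kp(-hw, fr$y - ank_h + 0.01, fr$z + flen_front),
    r_small_toe = kp(-hw - 0.04, fr$y - ank_h + 0.01, fr$z + flen_front - 0.03),
    r_heel = kp(-hw, fr$y - ank_h + 0.01, fr$z - 0.06)
  )
  traj <- tibble(
    time = rep(tt, times = 25L),
    keypoint = rep(body25_keypoints, each = nf),
    x = unlist(lapply(body25_keypoints, function(k) pts[[k]]$x), use.names = FALSE),
    y = unlist(lapply(body25_keypoints, function(k) pts[[k]]$y), use.names = FALSE),
    z = unlist(lapply(body25_keypoints, function(k) pts[[k]]$z), use.names = FALSE)
  )

  # ---- ground truth ----
  to_times <- vapply(seq_len(n_hs), function(k) {
    if (k <= 2L && sides[k] == spec$first_side && k == 1L) lead_in
    else if (k == 2L) t_hs[1] else t_hs[k - 1L]
  }, numeric(1))
  events <- gait_events(tibble(
    time_s = c(t_hs, to_times),
    side = c(sides, sides),
    event = rep(c("heel_strike", "toe_off"), each = n_hs),
    source = "truth"
  ))
  # realized ankle separation at each heel-strike (exact, from the model)
  p_at <- pelvis_z(t_hs)
  steps <- NULL
  if (n_hs >= 2L) {
    al <- foot_l(t_hs); ar <- foot_r(t_hs)
    sep <- abs(al$z - ar$z)
    n_steps <- n_hs - 1L
    phase <- rep("steady", n_steps)
    phase[1] <- "initiation"; phase[n_steps] <- "termination"
    steps <- tibble(
      side = sides[-1],
      t_start = t_hs[-n_hs], t_end = t_hs[-1],
      step_time_s = diff(t_hs),
      commanded_length_m = unname(vapply(sides[-1], function(s) sL[[s]], numeric(1))),
      ankle_length_m = sep[-1],
      torso_travel_m = diff(p_at),
      phase = phase
    )
    steps$speed_mps <- steps$torso_travel_m / steps$step_time_s
  }
  ang_l <- limb_angles(pz, py, kl$z, kl$y, fl$z, fl$y,
                       fl$z + flen_front, fl$y - ank_h + 0.01)
  ang_r <- limb_angles(pz, py, kr$z, kr$y, fr$z, fr$y,
                       fr$z + flen_front, fr$y - ank_h + 0.01)
  angles <- tibble(
    time = rep(tt, 6L),
    side = rep(c("left", "right"), each = 3L * nf),
    joint = rep(rep(c("hip", "knee", "ankle"), each = nf), 2L),
    angle_deg = c(ang_l$hip, ang_l$knee, ang_l$ankle,
                  ang_r$hip, ang_r$knee, ang_r$ankle)
  )
  structure(list(
    traj = traj,
    truth = list(
      events = events,
      steps = steps,
      pelvis = tibble(time = tt, x = 0, y = py, z = pz),
      angles = structure(angles, class = c("joint_angles", class(angles))),
      speed_mps = sum(sL) / sum(sT),
      trunk_lean_deg = spec$trunk_lean_deg
    ),
    spec = spec
  ), class = "walker_sim")
}
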