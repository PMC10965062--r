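#' Pixel-to-meter scale factor for sagittal videos
#'
#' Sagittal distances are dimensionalized with a single scale factor: the
#' ratio of a known physical distance along the line of progression (e.g.
#' between strips of tape on the walkway) to its length in pixels.
#'
#' @param known_m Known distance (m), > 0.
#' @param known_px The same distance in pixels, > 0.
#' @return Meters per pixel (scalar).
#' @export
scale_factor <- function(known_m, known_px) {
  if (!is.numeric(known_m) || !is.numeric(known_px) ||
      known_m <= 0 || known_px <= 0) {
    abort("calibration distances must be positive.", class = "videogait_config_error")
  }
  known_m / known_px
}

#' Sagittal-plane step table
#'
#' Computes per-step spatiotemporal parameters from a calibrated sagittal
#' track. Two step-length definitions are supported: `"ankle_distance"`, the
#' horizontal distance between the two ankle keypoints at the instant of the
#' terminating heel-strike; and `"torso_travel"`, the horizontal distance
#' travelled by the mid-hip keypoint between the bounding heel-strikes (the
#' definition that frontal videos can also provide). Step time is the
#' interval between consecutive bilateral heel-strikes, speed is length over
#' time, and each step takes the side of its terminating heel-strike.
#'
#' @param track A preprocessed sagittal `gait_track` in gait coordinates.
#' @param events A [gait_events()] table.
#' @param scale Meters per pixel (see [scale_factor()]).
#' @param method `"ankle_distance"` or `"torso_travel"`.
#' @param trial_id,condition Labels copied into the table.
#' @return A step-table tibble (same columns as [frontal_step_table()]).
#' @export
sagittal_step_table <- function(track, events, scale,
                                method = c("ankle_distance", "torso_travel"),
                                trial_id = "trial", condition = "preferred") {
  method <- match.arg(method)
  stopifnot_gait_coords(track)
  steps <- assign_step_sides(events)
  steps <- steps[steps$valid, ]
  if (nrow(steps) == 0L) return(empty_step_table())
  fps <- track_meta(track)$fps
  lx <- track_series(track, "l_ankle", "x")
  rx <- track_series(track, "r_ankle", "x")
  mh <- track_series(track, "mid_hip", "x")
  fidx <- function(t) pmin(pmax(round(t * fps) + 1L, 1L), length(mh))
  len_px <- switch(method,
    ankle_distance = abs(lx[fidx(steps$t_end)] - rx[fidx(steps$t_end)]),
    torso_travel = abs(mh[fidx(steps$t_end)] - mh[fidx(steps$t_start)])
  )
  len <- len_px * scale
  tibble(trial_id = trial_id, condition = condition, side = steps$side,
         t_start = steps$t_start, t_end = steps$t_end,
         step_time_s = steps$step_time_s, step_length_m = len,
         speed_mps = len / steps$step_time_s, method = method)
}

# signed angle (degrees) from the downward vertical to a segment vector,
# positive when the segment points forward (+x)
seg_angle_from_down <- function(dx, dy) {
  atan2(dx, -dy) * 180 / pi
}

# hip/knee/ankle angles from planar joint coordinates (forward, up); shared
# by the video pipeline and the simulator's ground truth so both state the
# same convention
limb_angles <- function(hx, hy, kx, ky, ax, ay, tx, ty) {
  th <- seg_angle_from_down(kx - hx, ky - hy)
  sh <- seg_angle_from_down(ax - kx, ay - ky)
  sxv <- ax - kx; syv <- ay - ky
  fxv <- tx - ax; fyv <- ty - ay
  ank <- atan2(sxv * fyv - syv * fxv, sxv * fxv + syv * fyv) * 180 / pi - 90
  list(hip = th, knee = th - sh, ankle = ank)
}

#' Sagittal lower-limb joint angles
#'
#' Computes hip, knee, and ankle angle time series per side from keypoint
#' triplets. Conventions: the hip angle is the thigh segment's (hip to knee)
#' angle from the downward vertical, flexion (knee forward) positive; the
#' knee angle is the angle between thigh and shank, zero at full extension,
#' flexion positive; the ankle angle is the angle between the shank and the
#' foot segment (ankle to hallux) minus 90 degrees, dorsiflexion positive.
#'
#' @param track A preprocessed sagittal `gait_track` in gait coordinates
#'   (forward positive, up positive).
#' @return A tibble of class `joint_angles`, long over `time`, `side`,
#'   `joint` (`hip`/`knee`/`ankle`), `angle_deg`. Frames with a missing
#'   keypoint yield `NA` angles.
#' @export
joint_angles <- function(track) {
  stopifnot_gait_coords(track)
  t <- track_times(track)
  one_side <- function(side) {
    p <- function(kp) list(x = track_series(track, paste0(side, "_", kp), "x"),
                           y = track_series(track, paste0(side, "_", kp), "y"))
    hip <- p("hip"); knee <- p("knee"); ankle <- p("ankle"); toe <- p("big_toe")
    ang <- limb_angles(hip$x, hip$y, knee$x, knee$y,
                       ankle$x, ankle$y, toe$x, toe$y)
    side_lab <- if (side == "l") "left" else "right"
    tibble(time = rep(t, 3L), side = side_lab,
           joint = rep(c("hip", "knee", "ankle"), each = length(t)),
           angle_deg = c(ang$hip, ang$knee, ang$ankle))
  }
  out <- dplyr::bind_rows(one_side("l"), one_side("r"))
  structure(out, fps = track_meta(track)$fps,
            class = c("joint_angles", class(out)))
}

#' Trunk inclination at heel-strikes
#'
#' Forward lean of the trunk — the angle from vertical of the segment from
#' the mid-hip to the neck keypoint — evaluated at each heel-strike, minus a
#' fixed offset. The offset (default 12 degrees) compensates for the
#' systematic difference between the keypoint-defined trunk segment and the
#' marker-defined one on the back; it is configuration, not anatomy, and can
#' be set to zero.
#'
#' @param track A preprocessed sagittal `gait_track` in gait coordinates.
#' @param events A [gait_events()] table.
#' @param offset_deg Fixed offset subtracted from the raw angle (degrees).
#' @return A tibble with one row per heel-strike: `time_s`, `side`,
#'   `raw_deg`, `inclination_deg` (forward lean positive). Events where the
#'   neck or mid-hip keypoint is missing yield `NA`.
#' @export
trunk_inclination <- function(track, events, offset_deg = 12) {
  stopifnot_gait_coords(track)
  fps <- track_meta(track)$fps
  nx <- track_series(track, "neck", "x"); ny <- track_series(track, "neck", "y")
  hx <- track_series(track, "mid_hip", "x"); hy <- track_series(track, "mid_hip", "y")
  hs <- events[events$event == "heel_strike", ]
  idx <- pmin(pmax(round(hs$time_s * fps) + 1L, 1L), length(nx))
  raw <- atan2(nx[idx] - hx[idx], ny[idx] - hy[idx]) * 180 / pi
  tibble(time_s = hs$time_s, side = hs$side, raw_deg = raw,
         inclination_deg = raw - offset_deg)
}

#' Read a long-format marker trajectory file
#'
#' Reads motion-capture marker trajectories stored as long CSV with columns
#' `time_s`, `marker`, `x`, `y`, `z` (meters), the interchange format used
#' for mocap comparisons.
#'
#' @param path CSV file path.
#' @return A tibble with those columns.
#' @export
read_marker_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "marker", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort("marker CSV must have columns time_s, marker, x, y, z.",
          class = "videogait_format_error")
  }
  df[need]
}

#' @rdname read_marker_csv
#' @param markers Tibble with columns `time_s`, `marker`, `x`, `y`, `z`.
#' @export
write_marker_csv <- function(markers, path) {
  readr::write_csv(markers, path)
  invisible(path)
}
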