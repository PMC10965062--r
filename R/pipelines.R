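#' Frontal-plane gait analysis pipeline
#'
#' Runs the complete frontal workflow on a tracked participant: coordinate
#' conversion, left-right label correction, gap filling, heel-strike
#' detection from the inter-ankle vertical distance, torso pixel-size
#' tracking, size-ratio filtering, depth-change estimation from the
#' reference depth, and the per-step spatiotemporal table. The walking
#' direction is inferred from the torso size trend when not given.
#'
#' @param track A `gait_track` (raw image coordinates are fine) of the
#'   tracked participant, or a directory of per-frame JSON (then `fps`,
#'   `seed_frame`, `seed_xy` select the person; see [read_openpose_dir()]
#'   and [select_person()]).
#' @param d_ref Reference depth at the trial start (m).
#' @param direction `"away"`, `"toward"`, or `NULL` to infer.
#' @param size_method Torso size representation (see [torso_size_series()]).
#' @param sizeratio_cutoff_hz Low-pass cutoff for the size ratio (Hz).
#' @param events Optional externally supplied [gait_events()] (e.g. event
#'   times from motion capture); detected from the video when `NULL`.
#' @param max_gap_s Gap-filling limit (s).
#' @param interpolate Sub-frame depth interpolation at events.
#' @param trial_id,condition Labels for the step table.
#' @param fps,seed_frame,seed_xy Only used when `track` is a directory.
#' @return A list of class `frontal_analysis`: `steps`, `events`, `depth`,
#'   `size`, `track`, `params`.
#' @export
analyze_frontal <- function(track, d_ref, direction = NULL,
                            size_method = "height",
                            sizeratio_cutoff_hz = 0.4,
                            events = NULL, max_gap_s = 0.12,
                            interpolate = FALSE,
                            trial_id = "trial", condition = "preferred",
                            fps = NULL, seed_frame = 0L, seed_xy = NULL) {
  if (is.character(track)) {
    frames <- read_openpose_dir(track, fps = fps %||% 30)
    if (is.null(seed_xy)) {
      first <- frames[frames$frame == seed_frame & frames$person == 0L, ]
      seed_xy <- c(mean(first$x[first$confidence > 0]),
                   mean(first$y[first$confidence > 0]))
    }
    track <- select_person(frames, seed_frame, seed_xy, view = "frontal")
  }
  if (is.null(direction)) {
    direction <- infer_frontal_direction(torso_size_series(track, size_method))
  }
  track <- set_track_meta(track, direction = direction)
  track <- to_gait_coordinates(track)
  track <- correct_left_right(track)
  track <- fill_gaps(track, max_gap_s = max_gap_s)
  if (is.null(events)) events <- detect_events_frontal(track, direction)
  size <- torso_size_series(track, size_method)
  ref <- reference_window(events, track_meta(track)$fps)
  size <- size_ratio(size, ref, cutoff_hz = sizeratio_cutoff_hz)
  depth <- depth_change(size, d_ref)
  steps <- frontal_step_table(depth, events, trial_id = trial_id,
                              condition = condition,
                              interpolate = interpolate)
  structure(list(steps = steps, events = events, depth = depth, size = size,
                 track = track,
                 params = list(d_ref = d_ref, direction = direction,
                               size_method = size_method,
                               sizeratio_cutoff_hz = sizeratio_cutoff_hz,
                               max_gap_s = max_gap_s)),
            class = "frontal_analysis")
}

#' Sagittal-plane gait analysis pipeline
#'
#' Runs the complete sagittal workflow: coordinate conversion, left-right
#' correction, gap filling, zero-lag low-pass filtering of the keypoint
#' trajectories, event detection from the ankle-relative-to-mid-hip
#' excursions, pixel-to-meter calibration, per-step parameters (both
#' step-length definitions available), lower-limb joint kinematics, and
#' trunk inclination at heel-strikes.
#'
#' @param track A sagittal `gait_track`, or a JSON directory (as in
#'   [analyze_frontal()]).
#' @param known_m,known_px Calibration distance along the walkway and its
#'   pixel length (see [scale_factor()]); alternatively pass `scale`.
#' @param scale Meters per pixel (overrides `known_m`/`known_px`).
#' @param direction `"left-to-right"` or `"right-to-left"`; `NULL` infers it
#'   from the mid-hip drift.
#' @param cutoff_hz Trajectory low-pass cutoff (Hz).
#' @param step_method Step-length definition for the step table.
#' @param events Optional externally supplied events.
#' @param trunk_offset_deg Offset subtracted from trunk inclination (deg).
#' @param max_gap_s Gap-filling limit (s).
#' @param trial_id,condition Labels for the step table.
#' @param fps,seed_frame,seed_xy Only used when `track` is a directory.
#' @return A list of class `sagittal_analysis`: `steps`, `events`,
#'   `angles`, `trunk`, `track`, `params`.
#' @export
analyze_sagittal <- function(track, known_m = NULL, known_px = NULL,
                             scale = NULL, direction = NULL,
                             cutoff_hz = 5,
                             step_method = c("ankle_distance", "torso_travel"),
                             events = NULL, trunk_offset_deg = 12,
                             max_gap_s = 0.12,
                             trial_id = "trial", condition = "preferred",
                             fps = NULL, seed_frame = 0L, seed_xy = NULL) {
  step_method <- match.arg(step_method)
  if (is.character(track)) {
    frames <- read_openpose_dir(track, fps = fps %||% 30)
    if (is.null(seed_xy)) {
      first <- frames[frames$frame == seed_frame & frames$person == 0L, ]
      seed_xy <- c(mean(first$x[first$confidence > 0]),
                   mean(first$y[first$confidence > 0]))
    }
    track <- select_person(frames, seed_frame, seed_xy, view = "sagittal")
  }
  if (is.null(scale)) {
    if (is.null(known_m) || is.null(known_px)) {
      abort("supply `scale` or both `known_m` and `known_px`.",
            class = "videogait_config_error")
    }
    scale <- scale_factor(known_m, known_px)
  }
  if (is.null(direction)) {
    mh <- track_series(track, "mid_hip", "x")
    mh <- mh[!is.na(mh)]
    direction <- if (mh[length(mh)] >= mh[1]) "left-to-right" else "right-to-left"
  }
  track <- set_track_meta(track, direction = direction)
  track <- to_gait_coordinates(track)
  track <- correct_left_right(track)
  track <- fill_gaps(track, max_gap_s = max_gap_s)
  track <- lowpass_zero_lag(track, cutoff_hz = cutoff_hz)
  if (is.null(events)) events <- detect_events_sagittal(track)
  steps <- sagittal_step_table(track, events, scale, method = step_method,
                               trial_id = trial_id, condition = condition)
  angles <- joint_angles(track)
  trunk <- trunk_inclination(track, events, offset_deg = trunk_offset_deg)
  structure(list(steps = steps, events = events, angles = angles,
                 trunk = trunk, track = track,
                 params = list(scale = scale, direction = direction,
                               cutoff_hz = cutoff_hz,
                               step_method = step_method,
                               trunk_offset_deg = trunk_offset_deg,
                               max_gap_s = max_gap_s)),
            class = "sagittal_analysis")
}

#' @exportS3Method generics::glance
glance.frontal_analysis <- function(x, ...) {
  step_glance(x$steps)
}

#' @exportS3Method generics::glance
glance.sagittal_analysis <- function(x, ...) {
  step_glance(x$steps)
}

step_glance <- function(steps) {
  tibble(n_steps = nrow(steps),
         step_time_s = mean_or_na(steps$step_time_s),
         step_length_m = mean_or_na(steps$step_length_m),
         speed_mps = mean_or_na(steps$speed_mps))
}

#' Compare step tables from two measurement systems
#'
#' Cross-references the steps of two systems measuring the same walking
#' bout(s) and computes agreement statistics for each spatiotemporal
#' parameter at the requested level: `"step"` pairs individual steps by side
#' and terminating heel-strike time; `"trial"` pairs trial averages by
#' `trial_id`; `"session"` pairs session averages by (`trial_id` group —
#' supply one row per session via trial tables). Unmatched steps are
#' excluded.
#'
#' @param a,b Step tables (system A and B).
#' @param level Pairing level.
#' @param tol_s Step matching window (s) for `level = "step"`.
#' @return A list of class `system_comparison` with one [agreement()] per
#'   parameter; `glance()` binds them into a table.
#' @export
compare_step_tables <- function(a, b, level = c("step", "trial", "session"),
                                tol_s = 0.25) {
  level <- match.arg(level)
  params <- c("step_time_s", "step_length_m", "speed_mps")
  if (level == "step") {
    j <- vapply(seq_len(nrow(a)), function(i) {
      cand <- which(b$side == a$side[i] & abs(b$t_end - a$t_end[i]) <= tol_s)
      if (length(cand) == 0L) NA_integer_ else
        cand[which.min(abs(b$t_end[cand] - a$t_end[i]))]
    }, integer(1))
    ok <- !is.na(j)
    if (sum(ok) < 2L) {
      abort("fewer than two matched steps between the systems.",
            class = "videogait_data_error")
    }
    pa <- a[ok, ]; pb <- b[j[ok], ]
  } else {
    ta <- trial_means(a); tb <- trial_means(b)
    common <- intersect(ta$trial_id, tb$trial_id)
    if (length(common) < 2L) {
      abort("fewer than two matched trials between the systems.",
            class = "videogait_data_error")
    }
    pa <- ta[match(common, ta$trial_id), ]
    pb <- tb[match(common, tb$trial_id), ]
  }
  reports <- lapply(params, function(p) {
    agreement(pa[[p]], pb[[p]], level = level, parameter = p)
  })
  names(reports) <- params
  structure(list(reports = reports, level = level, n = nrow(pa)),
            class = "system_comparison")
}

#' @exportS3Method generics::glance
glance.system_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, glance))
}

#' @export
print.system_comparison <- function(x, ...) {
  cat(sprintf("System comparison (%s level, n = %d)\n", x$level, x$n))
  print(glance(x))
  invisible(x)
}
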