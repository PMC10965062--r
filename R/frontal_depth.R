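#' Torso pixel-size time series
#'
#' Tracks the apparent size of the torso in pixels, frame by frame. The torso
#' is used because it rotates little in the transverse plane during gait, so
#' its apparent size depends essentially only on depth. Three size
#' representations are supported: torso height (vertical distance between the
#' neck and mid-hip keypoints), shoulder width (horizontal distance between
#' the shoulder keypoints), and torso area (the square root of height times
#' width, so that the measure still scales linearly with inverse depth).
#'
#' @param track A gap-filled `gait_track`.
#' @param method `"height"`, `"width"`, or `"area"`.
#' @return A tibble of class `torso_size` with columns `frame`, `time`,
#'   `size_px` (`NA` where a required keypoint is missing beyond fillable
#'   gaps), carrying the frame rate and method as attributes.
#' @export
torso_size_series <- function(track, method = c("height", "width", "area")) {
  method <- match.arg(method)
  h <- abs(track_series(track, "neck", "y") - track_series(track, "mid_hip", "y"))
  w <- abs(track_series(track, "l_shoulder", "x") - track_series(track, "r_shoulder", "x"))
  size <- switch(method, height = h, width = w, area = sqrt(h * w))
  out <- tibble(frame = seq_along(size) - 1L, time = track_times(track),
                size_px = size)
  structure(out, fps = track_meta(track)$fps, method = method,
            class = c("torso_size", class(out)))
}

#' Reference window for the size ratio
#'
#' The reference pixel size must be measured at the epoch when the person
#' stands at the known reference depth — the start of the trial. The window
#' runs from the first frame until 0.3 s before the first heel-strike, with a
#' minimum of 5 frames.
#'
#' @param events A [gait_events()] table (used for the first heel-strike).
#' @param fps Frame rate (Hz).
#' @param pre_event_s Margin before the first heel-strike (s).
#' @param min_frames Minimum window length (frames).
#' @return Integer vector of 0-based frame indices.
#' @export
reference_window <- function(events, fps, pre_event_s = 0.3, min_frames = 5L) {
  hs <- events$time_s[events$event == "heel_strike"]
  end <- if (length(hs)) floor((min(hs) - pre_event_s) * fps) else min_frames - 1L
  end <- max(end, min_frames - 1L)
  seq(0L, end)
}

#' Torso size ratio relative to the reference depth
#'
#' Divides the torso pixel-size series by its reference value — the median
#' size over the window when the person stands at the known reference depth —
#' and low-pass filters the ratio (default cutoff 0.4 Hz) to remove
#' within-cycle oscillation, leaving the slow depth-driven trend. Under a
#' pinhole camera the filtered ratio equals `d_ref / (d_ref + depth_change)`.
#'
#' @param size A `torso_size` series.
#' @param ref_frames 0-based frame indices of the reference window (see
#'   [reference_window()]).
#' @param cutoff_hz Low-pass cutoff for the ratio (Hz); `NULL` skips
#'   filtering.
#' @return The `torso_size` tibble with columns `s_ratio` (filtered) and
#'   `s_ratio_raw` added, and the reference size `s_ref` as an attribute.
#' @export
size_ratio <- function(size, ref_frames, cutoff_hz = 0.4) {
  in_ref <- size$frame %in% ref_frames
  s_ref <- median(size$size_px[in_ref], na.rm = TRUE)
  if (!is.finite(s_ref)) {
    abort("reference window contains no observed torso sizes.",
          class = "videogait_data_error")
  }
  raw <- size$size_px / s_ref
  fps <- attr(size, "fps")
  filt <- if (is.null(cutoff_hz)) raw else lowpass_zero_lag(raw, fps, cutoff_hz)
  size$s_ratio_raw <- raw
  size$s_ratio <- filt
  attr(size, "s_ref") <- s_ref
  attr(size, "cutoff_hz") <- cutoff_hz
  size
}

#' Depth-change from the torso size ratio
#'
#' The heart of the frontal workflow: under a fixed pinhole camera the
#' apparent size of a rigid body is inversely proportional to its depth, so
#' the ratio `s_ratio = s_i / s_ref` at depth `d_ref + delta_d` satisfies
#' `s_ratio = d_ref / (d_ref + delta_d)`. Inverting gives the per-frame
#' depth-change
#' \deqn{\Delta d_i = d_{ref} / s_{ratio,i} - d_{ref}.}
#' Neither the camera's focal length nor the person's true size enters: both
#' cancel in the ratio, so the method needs only the reference depth.
#'
#' @param size A `torso_size` series with an `s_ratio` column (see
#'   [size_ratio()]).
#' @param d_ref The initial reference depth of the person from the camera (m).
#' @return A tibble of class `depth_series` with columns `frame`, `time`,
#'   `delta_d` (m, relative to the reference epoch).
#' @export
depth_change <- function(size, d_ref) {
  if (!"s_ratio" %in% names(size)) {
    abort("run size_ratio() before depth_change().", class = "videogait_config_error")
  }
  if (d_ref <= 0) abort("`d_ref` must be > 0.", class = "videogait_config_error")
  bad <- which(!is.na(size$s_ratio) & size$s_ratio <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive size ratio at frame %d.", size$frame[bad[1]]),
          class = "videogait_data_error")
  }
  out <- tibble(frame = size$frame, time = size$time,
                delta_d = d_ref / size$s_ratio - d_ref)
  structure(out, d_ref = d_ref, fps = attr(size, "fps"),
            class = c("depth_series", class(out)))
}

#' Frontal-plane step table from a depth series
#'
#' For each pair of consecutive bilateral heel-strikes, the step time is the
#' interval between them, the step length is the magnitude of the torso's
#' depth-change over that interval (distance travelled along the line of
#' progression), and the step speed is length over time. Each step is
#' labeled with the side of its terminating heel-strike. Steps bounded by two
#' same-side heel-strikes are flagged invalid and excluded.
#'
#' @param depth A `depth_series` from [depth_change()].
#' @param events A [gait_events()] table — either detected from the frontal
#'   video or supplied externally (e.g. motion-capture event times).
#' @param trial_id,condition Labels copied into the table.
#' @param interpolate Linearly interpolate depth between frames at event
#'   times (default: nearest frame, matching the discrete workflow).
#' @return A step-table tibble: `trial_id`, `condition`, `side`,
#'   `t_start`, `t_end`, `step_time_s`, `step_length_m`, `speed_mps`,
#'   `method = "torso_travel"`. Empty when fewer than two heel-strikes exist.
#' @export
frontal_step_table <- function(depth, events, trial_id = "trial",
                               condition = "preferred", interpolate = FALSE) {
  steps <- assign_step_sides(events)
  steps <- steps[steps$valid, ]
  if (nrow(steps) == 0L) return(empty_step_table())
  fps <- attr(depth, "fps")
  at <- function(t) {
    if (interpolate) approx(depth$time, depth$delta_d, xout = t, rule = 2)$y
    else depth$delta_d[pmin(pmax(round(t * fps) + 1L, 1L), nrow(depth))]
  }
  len <- abs(at(steps$t_end) - at(steps$t_start))
  tibble(trial_id = trial_id, condition = condition, side = steps$side,
         t_start = steps$t_start, t_end = steps$t_end,
         step_time_s = steps$step_time_s, step_length_m = len,
         speed_mps = len / steps$step_time_s, method = "torso_travel")
}

empty_step_table <- function() {
  tibble(trial_id = character(), condition = character(), side = character(),
         t_start = double(), t_end = double(), step_time_s = double(),
         step_length_m = double(), speed_mps = double(), method = character())
}

#' Grid evaluation of torso tracking methods and smoothing cutoffs
#'
#' Runs the frontal depth workflow over every combination of torso size
#' representation and size-ratio low-pass cutoff, scores each against a
#' ground-truth step table (simulator truth, or motion-capture-derived), and
#' ranks combinations by mean absolute step-length error, then by the SD of
#' the step-length differences. Ties keep declaration order.
#'
#' @param track A gap-filled frontal `gait_track` in gait coordinates.
#' @param events A [gait_events()] table for the trial.
#' @param truth Step table with ground-truth `step_length_m`, matched to
#'   measured steps by terminating heel-strike time (within `match_tol_s`).
#' @param d_ref Reference depth (m).
#' @param methods Torso size representations to try.
#' @param cutoffs Size-ratio cutoff frequencies to try (Hz).
#' @param match_tol_s Step matching tolerance (s).
#' @return A tibble (`method`, `cutoff_hz`, `mae_m`, `sd_diff_m`, `n`),
#'   sorted best first.
#' @export
evaluate_tracking_methods <- function(track, events, truth, d_ref,
                                      methods = c("height", "width", "area"),
                                      cutoffs = c(0.2, 0.4, 0.6, 1),
                                      match_tol_s = 0.25) {
  if (length(methods) == 0L || length(cutoffs) == 0L) {
    abort("empty evaluation grid.", class = "videogait_config_error")
  }
  fps <- track_meta(track)$fps
  ref <- reference_window(events, fps)
  grid <- expand.grid(method = methods, cutoff_hz = cutoffs,
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(method, cutoff_hz) {
    sz <- torso_size_series(track, method)
    dd <- depth_change(size_ratio(sz, ref, cutoff_hz), d_ref)
    st <- frontal_step_table(dd, events)
    j <- vapply(st$t_end, function(t) {
      k <- which.min(abs(truth$t_end - t))
      if (length(k) && abs(truth$t_end[k] - t) <= match_tol_s) k else NA_integer_
    }, integer(1))
    d <- st$step_length_m - truth$step_length_m[j]
    d <- d[!is.na(d)]
    tibble(method = method, cutoff_hz = cutoff_hz,
           mae_m = mean(abs(d)), sd_diff_m = if (length(d) > 1) sd(d) else NA_real_,
           n = length(d))
  })
  out <- dplyr::bind_rows(res)
  out[order(out$mae_m, out$sd_diff_m), ]
}

#' Infer frontal walking direction from the torso size trend
#'
#' A person walking away from the camera shrinks in the image (size ratio
#' trends down); walking toward the camera they grow.
#'
#' @param size A `torso_size` series.
#' @return `"away"` or `"toward"`.
#' @export
infer_frontal_direction <- function(size) {
  s <- size$size_px[!is.na(size$size_px)]
  n <- length(s)
  if (n < 4L) abort("size series too short to infer direction.",
                    class = "videogait_data_error")
  first <- median(s[seq_len(ceiling(n / 4))])
  last <- median(s[seq(n - ceiling(n / 4) + 1L, n)])
  if (last < first) "away" else "toward"
}
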