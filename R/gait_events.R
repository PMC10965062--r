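#' Construct a gait-event table
#'
#' Normalizes a set of detected gait events (heel-strikes, toe-offs) into the
#' package's event table: one row per event with its time, body side, event
#' type, and the measurement source it came from. Events are sorted by time;
#' consecutive same-side heel-strikes (an alternation violation, usually a
#' missed or spurious detection) are flagged in the `"event_flags"` attribute
#' rather than dropped.
#'
#' @param df Data frame with columns `time_s`, `side` (`"left"`/`"right"`),
#'   `event` (`"heel_strike"`/`"toe_off"`), `source`.
#' @return A tibble of class `gait_events`.
#' @export
gait_events <- function(df) {
  df <- as_tibble(df)[c("time_s", "side", "event", "source")]
  df <- df[order(df$time_s), ]
  hs <- df[df$event == "heel_strike", ]
  flags <- tibble(time_s = double(), side = character(), issue = character())
  if (nrow(hs) > 1L) {
    same <- which(hs$side[-1] == hs$side[-nrow(hs)]) + 1L
    if (length(same)) {
      flags <- tibble(time_s = hs$time_s[same], side = hs$side[same],
                      issue = "consecutive_same_side_heel_strike")
    }
  }
  for (s in unique(df$side)) for (ev in unique(df$event)) {
    t <- df$time_s[df$side == s & df$event == ev]
    if (length(t) > 1L && any(diff(t) <= 0)) {
      abort("event times must be strictly increasing within side and type.",
            class = "videogait_format_error")
    }
  }
  structure(df, event_flags = flags,
            class = c("gait_events", class(df)))
}

#' @rdname gait_events
#' @export
event_flags <- function(events) {
  attr(events, "event_flags") %||%
    tibble(time_s = double(), side = character(), issue = character())
}

# local maxima indices of x with prominence- and separation-based selection.
# Defaults are scale-free: minimum separation 0.4x the dominant period,
# minimum prominence 20% of the interquartile range in a window of about two
# periods around the candidate (local, because perspective modulates the
# amplitude of frontal signals along the trial)
find_signal_peaks <- function(x, fps, min_sep_s = NULL, min_prom = NULL) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # peaks are located on a lightly smoothed copy (3 Hz zero-lag, far above
  # any stepping cadence, so peak times are preserved); the removed residual
  # measures the pixel-noise scale
  smoothed <- fps > 8 && n > 30L
  xs <- if (smoothed) lowpass_zero_lag(x, fps, cutoff_hz = 3) else x
  noise <- if (smoothed) stats::mad(x - xs) else 0
  cand <- which(xs[2:(n - 1)] > xs[1:(n - 2)] & xs[2:(n - 1)] >= xs[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  f_dom <- dominant_frequency(xs, fps)
  if (is.null(min_sep_s)) {
    min_sep_s <- if (is.na(f_dom)) 0.25 else 0.4 / f_dom
  }
  prom <- vapply(cand, function(i) peak_prominence(xs, i), numeric(1))
  if (is.null(min_prom)) {
    half_win <- max(3L, round((if (is.na(f_dom)) 0.5 else 1 / f_dom) * fps))
    thr <- vapply(cand, function(i) {
      w <- xs[max(1L, i - half_win):min(n, i + half_win)]
      0.2 * stats::IQR(w, na.rm = TRUE)
    }, numeric(1))
    # a window containing only noise (e.g. a standing phase) would approve
    # its own noise wiggles: floor the threshold at the noise scale
    thr <- pmax(thr, 4 * noise)
  } else {
    thr <- rep(min_prom, length(cand))
  }
  keep <- cand[prom >= thr - 1e-12]
  if (length(keep) == 0L) return(integer(0))
  ord <- keep[order(xs[keep], decreasing = TRUE)]
  sep <- max(1L, round(min_sep_s * fps))
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(accepted - i) >= sep)) accepted <- c(accepted, i)
  }
  # refine each peak to the raw signal's local maximum nearby (the smoothing
  # can pull a perspective-amplitude-modulated peak slightly off its frame)
  if (smoothed) {
    w <- max(2L, round(0.07 * fps))
    accepted <- vapply(accepted, function(i) {
      lo <- max(1L, i - w); hi <- min(n, i + w)
      as.integer(lo + which.max(x[lo:hi]) - 1L)
    }, integer(1))
    accepted <- unique(accepted)
  }
  sort(accepted)
}

peak_prominence <- function(x, i) {
  left <- if (i > 1L) x[1:(i - 1L)] else numeric(0)
  right <- if (i < length(x)) x[(i + 1L):length(x)] else numeric(0)
  base_side <- function(v) {
    # min between the peak and the nearest higher point (or the edge)
    higher <- which(v > x[i])
    if (length(higher) == 0L) min(v) else min(v[seq(higher[1], length(v))])
  }
  lb <- if (length(left)) base_side(rev(left)) else x[i]
  rb <- if (length(right)) base_side(right) else x[i]
  x[i] - max(lb, rb)
}

# rate of median-crossings; robust to the amplitude modulation that
# perspective imposes on frontal signals (an FFT peak would sit on the
# envelope, not the stepping rhythm)
dominant_frequency <- function(x, fps, band = c(0.2, 5)) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) return(NA_real_)
  # crossing counts are fragile to pixel noise: estimate the rhythm on a
  # lightly smoothed copy (3 Hz is well above any stepping cadence)
  if (fps > 8 && n > 30L) x <- lowpass_zero_lag(x, fps, cutoff_hz = 3)
  c0 <- x - median(x)
  eps <- 1e-9 * max(1, stats::IQR(x))
  s <- sign(c0[abs(c0) > eps])
  if (length(s) < 2L) return(NA_real_)
  crossings <- sum(diff(s) != 0)
  f <- crossings / 2 / (n / fps)
  if (f < band[1] || f > band[2]) return(NA_real_)
  f
}

# detect HS (positive peaks) and TO (negative peaks) of a relative
# anterior-posterior signal, one side at a time
events_from_relative_signal <- function(rel, fps, side, source, t0 = 0,
                                        toe_offs = TRUE) {
  ok <- !is.na(rel)
  span <- longest_observed_span(ok)
  if (length(span) < 3L) {
    warn(sprintf("signal too short for event detection (%s/%s).", source, side))
    return(tibble(time_s = double(), side = character(), event = character(),
                  source = character()))
  }
  seg <- rel[span]
  hs <- find_signal_peaks(seg, fps)
  to <- if (toe_offs) find_signal_peaks(-seg, fps) else integer(0)
  idx0 <- span[1] - 1L
  tibble(
    time_s = t0 + (c(hs, to) + idx0 - 1L) / fps,
    side = side,
    event = rep(c("heel_strike", "toe_off"), c(length(hs), length(to))),
    source = source
  )
}

#' Detect gait events from sagittal keypoints
#'
#' Heel-strikes and toe-offs are the positive and negative peaks,
#' respectively, of each ankle keypoint's horizontal trajectory relative to
#' the mid-hip keypoint — at heel-strike the foot is at its most forward
#' excursion relative to the body, at toe-off its most backward.
#'
#' @param track A preprocessed `gait_track` in gait coordinates (forward
#'   positive).
#' @return A [gait_events()] tibble with `source = "sagittal"`.
#' @export
detect_events_sagittal <- function(track) {
  stopifnot_gait_coords(track)
  fps <- track_meta(track)$fps
  mh <- track_series(track, "mid_hip", "x")
  out <- dplyr::bind_rows(
    events_from_relative_signal(track_series(track, "l_ankle", "x") - mh,
                                fps, "left", "sagittal"),
    events_from_relative_signal(track_series(track, "r_ankle", "x") - mh,
                                fps, "right", "sagittal")
  )
  gait_events(out)
}

#' Detect gait events from frontal keypoints
#'
#' In a frontal view the forward foot appears higher in the image (nearer
#' the horizon) when walking away from the camera, and lower when walking
#' toward it. Events are therefore the extrema of the vertical distance
#' between the left and right ankle keypoints: walking away, positive peaks
#' of (left - right) mark left heel-strikes and negative peaks right
#' heel-strikes; the mapping reverses when walking toward the camera. Only
#' heel-strikes are emitted (the frontal signal does not separate toe-offs).
#'
#' @param track A preprocessed `gait_track` in gait coordinates.
#' @param direction `"away"` or `"toward"`; defaults to the track metadata.
#' @return A [gait_events()] tibble with `source = "frontal"`.
#' @export
detect_events_frontal <- function(track, direction = NULL) {
  stopifnot_gait_coords(track)
  m <- track_meta(track)
  direction <- direction %||% m$direction
  if (!isTRUE(direction %in% c("away", "toward"))) {
    abort("frontal `direction` must be 'away' or 'toward'.",
          class = "videogait_config_error")
  }
  ly <- track_series(track, "l_ankle", "y")
  ry <- track_series(track, "r_ankle", "y")
  if (all(is.na(ly)) || all(is.na(ry))) {
    abort("an ankle keypoint is missing throughout the trial.",
          class = "videogait_data_error")
  }
  rel <- ly - ry
  pos_side <- if (direction == "away") "left" else "right"
  neg_side <- if (direction == "away") "right" else "left"
  out <- dplyr::bind_rows(
    events_from_relative_signal(rel, m$fps, pos_side, "frontal", toe_offs = FALSE),
    events_from_relative_signal(-rel, m$fps, neg_side, "frontal", toe_offs = FALSE)
  )
  gait_events(out)
}

#' Detect gait events from motion-capture marker trajectories
#'
#' Heel-strikes and toe-offs are the positive and negative peaks of each
#' ankle marker's anterior-posterior position relative to the torso.
#'
#' @param ankle_left_ap,ankle_right_ap Anterior-posterior ankle marker
#'   trajectories (filtered), forward positive.
#' @param torso_ap Anterior-posterior torso trajectory on the same clock.
#' @param fps Marker sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @return A [gait_events()] tibble with `source = "mocap"`.
#' @export
detect_events_mocap <- function(ankle_left_ap, ankle_right_ap, torso_ap, fps,
                                t0 = 0) {
  out <- dplyr::bind_rows(
    events_from_relative_signal(ankle_left_ap - torso_ap, fps, "left", "mocap", t0),
    events_from_relative_signal(ankle_right_ap - torso_ap, fps, "right", "mocap", t0)
  )
  gait_events(out)
}

#' Cross-reference gait events between two measurement systems
#'
#' Matches same-side, same-type events of two detectors on a common clock by
#' greedy nearest-time pairing within a tolerance, so that downstream
#' comparisons use the same gait cycles in both systems. Each event joins at
#' most one pair; unmatched events are reported and excluded from
#' comparisons.
#'
#' @param a,b [gait_events()] tables from the same walking bout.
#' @param tol_s Matching window (s).
#' @return A list of class `matched_cycles`: `matched` (tibble with `side`,
#'   `event`, `time_a`, `time_b`), `unmatched_a`, `unmatched_b`.
#' @export
cross_reference_events <- function(a, b, tol_s = 0.25) {
  matched <- list()
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  for (s in c("left", "right")) for (ev in c("heel_strike", "toe_off")) {
    ia <- which(a$side == s & a$event == ev)
    ib <- which(b$side == s & b$event == ev)
    if (!length(ia) || !length(ib)) next
    dt <- abs(outer(a$time_s[ia], b$time_s[ib], "-"))
    cand <- which(dt <= tol_s, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(dt[cand]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- ia[cand[k, 1]]; j <- ib[cand[k, 2]]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      matched[[length(matched) + 1L]] <-
        tibble(side = s, event = ev, time_a = a$time_s[i], time_b = b$time_s[j])
    }
  }
  matched <- if (length(matched)) {
    m <- dplyr::bind_rows(matched)
    m[order(m$time_a), ]
  } else {
    tibble(side = character(), event = character(),
           time_a = double(), time_b = double())
  }
  structure(list(matched = matched,
                 unmatched_a = as_tibble(a[!used_a, ]),
                 unmatched_b = as_tibble(b[!used_b, ])),
            class = "matched_cycles")
}

#' Read and write gait-event CSV files
#'
#' Events export and import as CSV with columns `time_s`, `side`, `event`,
#' `source`, so that events identified in one system (e.g. motion capture)
#' can drive step computations in another.
#'
#' @param events A [gait_events()] table.
#' @param path File path.
#' @return `read_events_csv()` returns a [gait_events()] table;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  gait_events(readr::read_csv(path, show_col_types = FALSE))
}

stopifnot_gait_coords <- function(track) {
  if (track_meta(track)$coords != "gait") {
    abort("track must be in gait coordinates (see to_gait_coordinates()).",
          class = "videogait_config_error")
  }
  invisible(track)
}
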