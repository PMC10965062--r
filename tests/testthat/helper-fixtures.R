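# shared fixture builders: short ground-truthed walks and hand-built tracks

# a brief walking trial; arguments override the defaults
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(duration = 4, fps = 30)
  do.call(walker_spec, utils::modifyList(defaults, args))
}

quick_sim <- function(...) simulate_walk(quick_spec(...))

# gait_track with every keypoint parked at (0, 0) except the ones supplied;
# coordinates are interpreted as already being in gait coordinates
manual_track <- function(n_frames, fps = 30, view = "sagittal",
                         direction = NA_character_, coords = "gait", ...) {
  series <- list(...)
  df <- tibble::tibble(
    frame = rep(seq_len(n_frames) - 1L, each = 25L),
    keypoint = rep(body25_keypoints, n_frames),
    x = 0, y = 0, confidence = 1
  )
  for (kp in names(series)) {
    v <- series[[kp]]
    idx <- which(df$keypoint == kp)
    if (!is.null(v$x)) df$x[idx] <- v$x
    if (!is.null(v$y)) df$y[idx] <- v$y
  }
  tr <- gait_track(df, fps = fps, view = view, direction = direction,
                   coords = "image")
  set_track_meta(tr, coords = coords)
}

hs_times <- function(events) sort(events$time_s[events$event == "heel_strike"])

truth_hs <- function(sim) hs_times(sim$truth$events)

# largest |detected - truth| over true heel-strikes, in frames (rounded to
# clear floating-point fuzz from the frame-grid arithmetic)
max_event_error_frames <- function(detected, truth_times, fps) {
  det <- hs_times(detected)
  err <- max(vapply(truth_times, function(t) min(abs(det - t)), numeric(1)))
  round(err * fps, 6)
}
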