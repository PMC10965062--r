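#' Build a keypoint track
#'
#' A *gait track* is the tidy per-frame record of one tracked person: one row
#' per frame and keypoint, with pixel coordinates and the detector's
#' confidence. Missing keypoints carry `NA` coordinates and confidence 0.
#' Trial-level metadata (frame rate, camera view, image size, coordinate
#' convention) travels as attributes so the table pipes through dplyr verbs
#' and can be re-stamped with [set_track_meta()].
#'
#' @param df Data frame with columns `frame`, `keypoint`, `x`, `y`,
#'   `confidence`. Every frame must contain all 25 keypoints
#'   (see [body25_keypoints]); use `NA` coordinates for absent ones.
#' @param fps Frames per second (Hz), > 0.
#' @param view `"frontal"` or `"sagittal"`.
#' @param direction Walking direction. Frontal: `"away"` or `"toward"` the
#'   camera; sagittal: `"left-to-right"` or `"right-to-left"` across the
#'   image. May be `NA` if unknown (the frontal pipeline can infer it).
#' @param image_width,image_height Image size in pixels.
#' @param coords `"image"` (origin top-left, y down — what the pose estimator
#'   emits) or `"gait"` (y up, x per the analysis convention, see
#'   [to_gait_coordinates()]).
#'
#' @return A tibble of class `gait_track` ordered by frame then keypoint,
#'   with a `time` column (`frame / fps`, frame 0 at t = 0).
#' @export
gait_track <- function(df, fps, view = c("frontal", "sagittal"),
                       direction = NA_character_,
                       image_width = 1920L, image_height = 1080L,
                       coords = c("image", "gait")) {
  view <- match.arg(view)
  coords <- match.arg(coords)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("`fps` must be a single positive number.", class = "videogait_config_error")
  }
  need <- c("frame", "keypoint", "x", "y", "confidence")
  if (!all(need %in% names(df))) {
    abort(paste0("track data must have columns: ", paste(need, collapse = ", ")),
          class = "videogait_format_error")
  }
  df <- as_tibble(df)[need]
  df$keypoint <- as.character(df$keypoint)
  df <- df[order(df$frame, match(df$keypoint, body25_keypoints)), ]
  n_frame <- length(unique(df$frame))
  if (nrow(df) != 25L * n_frame ||
      !all(df$keypoint == rep(body25_keypoints, n_frame))) {
    abort("every frame must contain exactly the 25 BODY_25 keypoints.",
          class = "videogait_format_error")
  }
  frames <- unique(df$frame)
  if (n_frame > 1L && !all(diff(frames) == 1L)) {
    abort("frames must be consecutive.", class = "videogait_format_error")
  }
  miss <- is.na(df$x) | is.na(df$y) | df$confidence < missing_conf_threshold()
  df$x[miss] <- NA_real_
  df$y[miss] <- NA_real_
  df <- tibble(
    frame = as.integer(df$frame),
    time = as.integer(df$frame) / fps,
    keypoint = df$keypoint,
    x = df$x, y = df$y, confidence = df$confidence
  )
  set_track_meta(df, fps = fps, view = view, direction = direction,
                 image_width = image_width, image_height = image_height,
                 coords = coords)
}

# confidence below this (or exactly 0, the pose estimator's absent marker)
# means the keypoint was not detected
missing_conf_threshold <- function() 0.1

#' Read or stamp track metadata
#'
#' dplyr verbs drop bespoke attributes; `set_track_meta()` re-stamps them and
#' `track_meta()` reads them back as a list.
#'
#' @param track A `gait_track`.
#' @param ... Metadata fields (`fps`, `view`, `direction`, `image_width`,
#'   `image_height`, `coords`); omitted fields keep their current value.
#' @return `track_meta()`: a named list. `set_track_meta()`: the track.
#' @export
track_meta <- function(track) {
  m <- attr(track, "gait_meta")
  if (is.null(m)) abort("not a gait_track (no metadata).", class = "videogait_format_error")
  m
}

#' @rdname track_meta
#' @export
set_track_meta <- function(track, ...) {
  new <- list(...)
  old <- attr(track, "gait_meta") %||% list()
  old[names(new)] <- new
  attr(track, "gait_meta") <- old
  class(track) <- unique(c("gait_track", class(as_tibble(track))))
  track
}

#' @export
print.gait_track <- function(x, ...) {
  m <- track_meta(x)
  cat(sprintf("# gait_track: %d frames @ %g fps, %s view (%s coords)\n",
              length(unique(x$frame)), m$fps, m$view, m$coords))
  NextMethod()
}

# frames x 25 matrix of one coordinate, frame-major ordering assumed
track_matrix <- function(track, coord = c("x", "y", "confidence")) {
  coord <- match.arg(coord)
  n <- nrow(track) / 25L
  matrix(track[[coord]], nrow = n, ncol = 25L, byrow = TRUE,
         dimnames = list(NULL, body25_keypoints))
}

# rebuild coordinate columns from frames x 25 matrices (inverse of track_matrix)
track_set_matrix <- function(track, x = NULL, y = NULL, confidence = NULL) {
  if (!is.null(x)) track$x <- as.vector(t(x))
  if (!is.null(y)) track$y <- as.vector(t(y))
  if (!is.null(confidence)) track$confidence <- as.vector(t(confidence))
  track
}

# time series (length n_frames) of one keypoint's coordinate
track_series <- function(track, keypoint, coord = "x") {
  track[[coord]][track$keypoint == keypoint]
}

track_times <- function(track) unique(track$time)

#' Describe a camera recording setup
#'
#' Holds the metadata the analysis pipelines need about how a walking trial
#' was filmed: the view, the walking direction, frame rate, and the spatial
#' anchor — a reference depth for frontal recordings, or a known calibration
#' distance along the line of progression for sagittal recordings.
#'
#' @param view `"frontal"` or `"sagittal"`.
#' @param direction Frontal: `"away"`/`"toward"`; sagittal:
#'   `"left-to-right"`/`"right-to-left"` (travel direction in the image).
#' @param fps Video frame rate (Hz).
#' @param d_ref Frontal only: the person's initial reference depth from the
#'   camera (m), measured while they stand at the trial start.
#' @param calibration_distance_m,calibration_distance_px Sagittal only: a
#'   known distance along the walkway (m) and its length in pixels.
#' @param image_width,image_height Image size (px).
#' @return A list of class `camera_setup`.
#' @export
camera_setup <- function(view = c("frontal", "sagittal"),
                         direction = NA_character_, fps = 30,
                         d_ref = NULL,
                         calibration_distance_m = NULL,
                         calibration_distance_px = NULL,
                         image_width = 1920L, image_height = 1080L) {
  view <- match.arg(view)
  if (!is.na(direction)) {
    ok <- switch(view,
      frontal = direction %in% c("away", "toward"),
      sagittal = direction %in% c("left-to-right", "right-to-left")
    )
    if (!ok) {
      abort(sprintf("invalid direction '%s' for %s view.", direction, view),
            class = "videogait_config_error")
    }
  }
  if (view == "frontal" && !is.null(d_ref) && d_ref <= 0) {
    abort("`d_ref` must be > 0.", class = "videogait_config_error")
  }
  if (view == "sagittal") {
    for (v in list(calibration_distance_m, calibration_distance_px)) {
      if (!is.null(v) && v <= 0) {
        abort("calibration distances must be > 0.", class = "videogait_config_error")
      }
    }
  }
  structure(list(view = view, direction = direction, fps = fps, d_ref = d_ref,
                 calibration_distance_m = calibration_distance_m,
                 calibration_distance_px = calibration_distance_px,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height)),
            class = "camera_setup")
}
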