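#' Read per-frame pose-estimator JSON files
#'
#' Reads a directory of OpenPose-demo BODY_25 output: one JSON file per video
#' frame, each holding zero or more detected persons as flat
#' `[x0, y0, c0, ..., x24, y24, c24]` keypoint arrays. Lexicographic file
#' order is frame order (the demo's naming convention).
#'
#' @param path Directory containing `*.json` files.
#' @param fps Video frame rate (Hz).
#' @param image_width,image_height Image size in pixels (not stored in the
#'   JSON; needed later for coordinate conversion).
#' @return A tibble of class `openpose_frames` with columns `frame` (0-based),
#'   `person` (0-based index within the frame), `keypoint`, `x`, `y`,
#'   `confidence`. Frames with no detections contribute no rows but are
#'   counted in the metadata.
#' @seealso [select_person()], [write_openpose_dir()]
#' @export
read_openpose_dir <- function(path, fps, image_width = 1920L,
                              image_height = 1080L) {
  files <- sort(list.files(path, pattern = "_keypoints\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
  }
  if (length(files) == 0L) {
    abort(sprintf("no JSON files found in '%s'.", path),
          class = "videogait_data_error")
  }
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    dat <- tryCatch(
      jsonlite::fromJSON(files[[i]], simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("malformed JSON in '%s': %s", basename(files[[i]]),
                      conditionMessage(e)),
              class = "videogait_parse_error")
      }
    )
    people <- dat$people
    kp <- if (is.null(people) || length(people) == 0L) {
      list()
    } else if (is.data.frame(people)) {
      people$pose_keypoints_2d
    } else {
      lapply(people, function(p) p$pose_keypoints_2d)
    }
    if (length(kp) == 0L) next
    per <- lapply(seq_along(kp), function(j) {
      v <- as.numeric(kp[[j]])
      if (length(v) != 75L) {
        abort(sprintf("person %d in '%s' has %d values, expected 75 (25 keypoints).",
                      j - 1L, basename(files[[i]]), length(v)),
              class = "videogait_format_error")
      }
      m <- matrix(v, ncol = 3L, byrow = TRUE)
      tibble(frame = i - 1L, person = j - 1L, keypoint = body25_keypoints,
             x = m[, 1], y = m[, 2], confidence = m[, 3])
    })
    rows[[i]] <- dplyr::bind_rows(per)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), person = integer(), keypoint = character(),
                  x = double(), y = double(), confidence = double())
  }
  structure(out,
            op_meta = list(n_frames = length(files), fps = fps,
                           image_width = as.integer(image_width),
                           image_height = as.integer(image_height)),
            class = c("openpose_frames", class(out)))
}

#' Write a track as per-frame pose-estimator JSON
#'
#' Writes one JSON file per frame in the OpenPose demo dialect
#' (`{"people": [{"pose_keypoints_2d": [...]}]}`), so the files round-trip
#' through [read_openpose_dir()]. Missing keypoints are written as
#' `0, 0, 0` — the pose estimator's own marker for an undetected keypoint.
#' Coordinates are serialized at full precision so the round trip is
#' bit-exact.
#'
#' @param track A `gait_track` in image coordinates (or a list of such tracks
#'   to write several persons per frame).
#' @param path Output directory (created if needed).
#' @param prefix File name prefix; files are named
#'   `<prefix>_<frame %012d>_keypoints.json`.
#' @return Invisibly, the written file paths. An empty trial writes no frame
#'   files but does write a `manifest.json` noting zero frames.
#' @export
write_openpose_dir <- function(track, path, prefix = "frame") {
  tracks <- if (inherits(track, "gait_track")) list(track) else track
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  xs <- lapply(tracks, track_matrix, "x")
  ys <- lapply(tracks, track_matrix, "y")
  cs <- lapply(tracks, track_matrix, "confidence")
  n <- if (length(xs)) nrow(xs[[1]]) else 0L
  files <- character(n)
  for (i in seq_len(n)) {
    people <- lapply(seq_along(xs), function(j) {
      x <- xs[[j]][i, ]; y <- ys[[j]][i, ]; cf <- cs[[j]][i, ]
      miss <- is.na(x) | is.na(y)
      x[miss] <- 0; y[miss] <- 0; cf[miss] <- 0
      list(pose_keypoints_2d = as.numeric(rbind(x, y, cf)))
    })
    files[[i]] <- file.path(path, sprintf("%s_%012d_keypoints.json", prefix, i - 1L))
    # I(17) = 17 significant digits: enough for an exact double round trip
    json <- jsonlite::toJSON(list(version = 1.3, people = people),
                             auto_unbox = TRUE, digits = I(17))
    writeLines(json, files[[i]])
  }
  manifest <- file.path(path, "manifest.json")
  jsonlite::write_json(list(n_frames = n, n_persons = length(tracks)),
                       manifest, auto_unbox = TRUE)
  invisible(files)
}

# tracking anchor for one person: mid-hip, else confidence-weighted centroid
# of detected keypoints
person_anchor <- function(m) {
  # m: 25 x 3 matrix (x, y, confidence)
  thr <- missing_conf_threshold()
  mh <- which(body25_keypoints == "mid_hip")
  if (m[mh, 3] >= thr) return(m[mh, 1:2])
  ok <- m[, 3] >= thr
  if (!any(ok)) return(c(NA_real_, NA_real_))
  w <- m[ok, 3]
  c(sum(m[ok, 1] * w), sum(m[ok, 2] * w)) / sum(w)
}

#' Select and track one participant across frames
#'
#' The pose estimator may detect several persons per frame (bystanders, or
#' spurious detections on objects). Given a seed — a frame index and an
#' approximate pixel position of the participant in that frame — this picks
#' the nearest detection at the seed frame and tracks it forward and backward
#' by nearest mid-hip distance (falling back to a confidence-weighted keypoint
#' centroid when the mid-hip is missing). Frames where the nearest candidate
#' jumps farther than `jump_frac` of the image diagonal become all-missing.
#'
#' @param frames An `openpose_frames` tibble from [read_openpose_dir()].
#' @param seed_frame 0-based frame index containing the participant.
#' @param seed_xy Numeric length-2: approximate (x, y) pixel position of the
#'   participant at `seed_frame`.
#' @param view Camera view to stamp on the returned track.
#' @param direction Walking direction to stamp on the returned track.
#' @param jump_frac Maximum allowed anchor displacement per frame, as a
#'   fraction of the image diagonal.
#' @param override Optional data frame (`frame_index`, `person_index`) pinning
#'   the identity on specific frames (reproduces manual corrections).
#' @return A `gait_track` of the selected person. The attribute
#'   `"track_report"` (accessor [track_report()]) is a tibble listing frames
#'   that were missing, rejected as jumps, or had near-ties between
#'   candidates.
#' @export
select_person <- function(frames, seed_frame, seed_xy,
                          view = c("frontal", "sagittal"),
                          direction = NA_character_,
                          jump_frac = 0.25, override = NULL) {
  view <- match.arg(view)
  meta <- attr(frames, "op_meta")
  if (is.null(meta)) {
    abort("`frames` must come from read_openpose_dir().",
          class = "videogait_format_error")
  }
  n_frames <- meta$n_frames
  jump_px <- jump_frac * sqrt(meta$image_width^2 + meta$image_height^2)

  # per-frame list of 25x3 person matrices
  by_frame <- vector("list", n_frames)
  if (nrow(frames) > 0L) {
    sp <- split(seq_len(nrow(frames)), frames$frame)
    for (f in names(sp)) {
      idx <- sp[[f]]
      pp <- split(idx, frames$person[idx])
      by_frame[[as.integer(f) + 1L]] <- lapply(pp, function(ii) {
        cbind(frames$x[ii], frames$y[ii], frames$confidence[ii])
      })
    }
  }
  anchors <- lapply(by_frame, function(ps) {
    if (is.null(ps)) NULL else lapply(ps, person_anchor)
  })

  seed_ps <- by_frame[[seed_frame + 1L]]
  if (is.null(seed_ps) || length(seed_ps) == 0L) {
    abort(sprintf("no person detected at seed frame %d.", seed_frame),
          class = "videogait_seed_error")
  }
  report <- list()
  note <- function(frame, status) {
    report[[length(report) + 1L]] <<- tibble(frame = frame, status = status)
  }

  ov <- NULL
  if (!is.null(override)) {
    ov <- setNames(as.integer(override$person_index),
                   as.character(override$frame_index))
  }

  pick <- function(f, ref_xy, check_jump = TRUE) {
    # returns person index (1-based) or NA
    key <- as.character(f - 1L)
    if (!is.null(ov) && key %in% names(ov)) return(ov[[key]] + 1L)
    ps <- anchors[[f]]
    if (is.null(ps) || length(ps) == 0L) {
      note(f - 1L, "no_detection")
      return(NA_integer_)
    }
    d <- vapply(ps, function(a) sqrt(sum((a - ref_xy)^2)), numeric(1))
    d[is.na(d)] <- Inf
    if (all(!is.finite(d))) {
      note(f - 1L, "no_detection")
      return(NA_integer_)
    }
    best <- which(d <= min(d) + 1e-6)
    if (length(best) > 1L) {
      mc <- vapply(best, function(j) mean(by_frame[[f]][[j]][, 3]), numeric(1))
      best <- best[which.max(mc)]
      note(f - 1L, "tie_broken_by_confidence")
    }
    if (check_jump && d[best] > jump_px) {
      note(f - 1L, "jump_rejected")
      return(NA_integer_)
    }
    best
  }

  chosen <- rep(NA_integer_, n_frames)
  sf <- seed_frame + 1L
  chosen[sf] <- pick(sf, seed_xy, check_jump = FALSE)
  if (is.na(chosen[sf])) {
    abort("could not seed the participant track.", class = "videogait_seed_error")
  }
  ref <- anchors[[sf]][[chosen[sf]]]
  for (f in seq(sf + 1L, length.out = max(0L, n_frames - sf))) {
    chosen[f] <- pick(f, ref)
    if (!is.na(chosen[f])) ref <- anchors[[f]][[chosen[f]]]
  }
  ref <- anchors[[sf]][[chosen[sf]]]
  for (f in rev(seq_len(sf - 1L))) {
    chosen[f] <- pick(f, ref)
    if (!is.na(chosen[f])) ref <- anchors[[f]][[chosen[f]]]
  }

  xm <- matrix(NA_real_, n_frames, 25L)
  ym <- matrix(NA_real_, n_frames, 25L)
  cm <- matrix(0, n_frames, 25L)
  for (f in seq_len(n_frames)) {
    if (is.na(chosen[f])) next
    m <- by_frame[[f]][[chosen[f]]]
    xm[f, ] <- m[, 1]; ym[f, ] <- m[, 2]; cm[f, ] <- m[, 3]
  }
  df <- tibble(
    frame = rep(seq_len(n_frames) - 1L, each = 25L),
    keypoint = rep(body25_keypoints, n_frames),
    x = as.vector(t(xm)), y = as.vector(t(ym)),
    confidence = as.vector(t(cm))
  )
  out <- gait_track(df, fps = meta$fps, view = view, direction = direction,
                    image_width = meta$image_width,
                    image_height = meta$image_height, coords = "image")
  rep_tbl <- if (length(report)) dplyr::bind_rows(report) else
    tibble(frame = integer(), status = character())
  attr(out, "track_report") <- rep_tbl
  out
}

#' @rdname select_person
#' @export
track_report <- function(track) {
  attr(track, "track_report") %||% tibble(frame = integer(), status = character())
}

#' Convert between image and gait coordinate conventions
#'
#' Image coordinates have the origin at the top-left with y increasing
#' downward. The analysis convention flips the vertical axis so positive is
#' up, and orients the horizontal axis by view: frontal — positive toward the
#' participant's left side (a mirror flip when walking toward the camera);
#' sagittal — positive in the direction of travel. The transform is affine
#' and invertible; `to_image_coordinates()` undoes it. Confidences are
#' untouched.
#'
#' @param track A `gait_track`.
#' @param setup Optional [camera_setup()]; defaults to the track's own
#'   metadata.
#' @return The transformed `gait_track`.
#' @export
to_gait_coordinates <- function(track, setup = NULL) {
  m <- track_meta(track)
  if (m$coords == "gait") return(track)
  view <- if (is.null(setup)) m$view else setup$view
  direction <- if (is.null(setup)) m$direction else setup$direction
  W <- if (is.null(setup)) m$image_width else setup$image_width
  H <- if (is.null(setup)) m$image_height else setup$image_height
  # frontal: a person walking away shows their back, so their left side is on
  # the image left -> mirror; facing the camera their left is on the image
  # right -> keep
  flip_x <- switch(view,
    frontal = if (isTRUE(direction == "away")) TRUE
              else if (isTRUE(direction == "toward")) FALSE
              else abort("frontal direction must be 'away' or 'toward'.",
                         class = "videogait_config_error"),
    sagittal = if (isTRUE(direction == "left-to-right")) FALSE
               else if (isTRUE(direction == "right-to-left")) TRUE
               else abort("sagittal direction must be 'left-to-right' or 'right-to-left'.",
                          class = "videogait_config_error")
  )
  track$y <- (H - 1) - track$y
  if (flip_x) track$x <- (W - 1) - track$x
  set_track_meta(track, coords = "gait", view = view, direction = direction,
                 image_width = W, image_height = H)
}

#' @rdname to_gait_coordinates
#' @export
to_image_coordinates <- function(track, setup = NULL) {
  m <- track_meta(track)
  if (m$coords == "image") return(track)
  # the flip is an involution: applying the same affine map returns to image
  track2 <- set_track_meta(track, coords = "image")
  out <- to_gait_coordinates(track2, setup)
  set_track_meta(out, coords = "image")
}
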