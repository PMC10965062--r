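#' Define an ideal pinhole camera
#'
#' A fixed pinhole camera with no lens distortion: a world point at lateral
#' offset `l` and depth `d` along the optical axis projects to
#' `principal + f * l / d` pixels, so the apparent size of a rigid segment
#' of physical size `s` at depth `d` is `f * s / d`.
#'
#' @param position Camera position `c(x, y, z)` in walker world coordinates
#'   (x lateral, y up, z direction of travel).
#' @param view_axis Unit-ish vector the camera looks along (it is
#'   normalized); the image up direction is world +y.
#' @param f_px Focal length (px).
#' @param image_width,image_height Image size (px).
#' @param cx,cy Principal point (px); defaults to the image center.
#' @return A list of class `pinhole_camera`.
#' @export
pinhole_camera <- function(position, view_axis, f_px,
                           image_width = 1920L, image_height = 1080L,
                           cx = NULL, cy = NULL) {
  if (f_px <= 0) abort("`f_px` must be positive.", class = "videogait_config_error")
  v <- view_axis / sqrt(sum(view_axis^2))
  up <- c(0, 1, 0)
  right <- c(up[2] * v[3] - up[3] * v[2],
             up[3] * v[1] - up[1] * v[3],
             up[1] * v[2] - up[2] * v[1])   # up x view = camera right
  structure(list(position = position, view = v, right = right, up = up,
                 f_px = f_px,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 cx = cx %||% (image_width - 1) / 2,
                 cy = cy %||% (image_height - 1) / 2),
            class = "pinhole_camera")
}

#' Convenience cameras matching the walker's world
#'
#' `frontal_camera()` places the camera on the line of progression:
#' `direction = "away"` puts it `d_ref` meters behind the walker's start
#' looking forward (the person walks away from it), `"toward"` puts it ahead
#' looking back. `sagittal_camera()` places it to the side of the walkway at
#' right angles. Frontal video defaults mimic a portrait tablet
#' (1080 x 1920), sagittal a landscape one (1920 x 1080).
#'
#' @param d_ref Initial depth of the walker (standing over z = 0) from the
#'   frontal camera (m).
#' @param direction `"away"` or `"toward"` (frontal).
#' @param side Which side of the walker the sagittal camera films
#'   (`"left"`: at +x looking -x).
#' @param distance_m Sagittal camera distance from the walking plane (m).
#' @param center_z Walkway z the sagittal camera is centered on (m).
#' @param height_m Camera height (m).
#' @param f_px Focal length (px).
#' @param walkway_m For `direction = "toward"`: the walker must stay in
#'   front of the lens, so the camera sits `d_ref` ahead of the start; make
#'   sure `d_ref` exceeds the distance walked.
#' @return A `pinhole_camera`.
#' @export
frontal_camera <- function(d_ref = 2.5, direction = c("away", "toward"),
                           height_m = 0.9, f_px = 1400) {
  direction <- match.arg(direction)
  if (d_ref <= 0) abort("`d_ref` must be > 0.", class = "videogait_config_error")
  if (direction == "away") {
    cam <- pinhole_camera(c(0, height_m, -d_ref), c(0, 0, 1), f_px,
                          image_width = 1080L, image_height = 1920L)
  } else {
    cam <- pinhole_camera(c(0, height_m, d_ref), c(0, 0, -1), f_px,
                          image_width = 1080L, image_height = 1920L)
  }
  cam$frontal_direction <- direction
  cam$d_ref <- d_ref
  cam
}

#' @rdname frontal_camera
#' @export
sagittal_camera <- function(side = c("left", "right"), distance_m = 3.89,
                            center_z = 2.4, height_m = 1.18, f_px = 1100) {
  side <- match.arg(side)
  x <- if (side == "left") distance_m else -distance_m
  axis <- if (side == "left") c(-1, 0, 0) else c(1, 0, 0)
  cam <- pinhole_camera(c(x, height_m, center_z), axis, f_px,
                        image_width = 1920L, image_height = 1080L)
  # filming the left profile, the walker (moving +z) travels left-to-right
  cam$sagittal_direction <- if (side == "left") "left-to-right" else "right-to-left"
  cam
}

#' Project a synthetic walker through a pinhole camera
#'
#' Perspective-projects the walker's 3D keypoint trajectories into pixel
#' keypoints, producing a `gait_track` in raw image coordinates (origin
#' top-left, y down) with confidence 1 everywhere — exactly what an ideal
#' pose estimator would output. Use [corrupt_track()] afterwards for noise,
#' dropout, and label swaps.
#'
#' @param sim A `walker_sim` from [simulate_walk()].
#' @param camera A `pinhole_camera` (typically [frontal_camera()] or
#'   [sagittal_camera()]).
#' @return A `gait_track` (image coordinates) with view and direction
#'   metadata taken from the camera.
#' @export
project_walk <- function(sim, camera) {
  traj <- sim$traj
  fps <- sim$spec$fps
  qx <- traj$x - camera$position[1]
  qy <- traj$y - camera$position[2]
  qz <- traj$z - camera$position[3]
  depth <- qx * camera$view[1] + qy * camera$view[2] + qz * camera$view[3]
  if (any(depth <= 0.05)) {
    abort("a keypoint reached the camera plane; move the camera or shorten the walk.",
          class = "videogait_projection_error")
  }
  lat <- qx * camera$right[1] + qy * camera$right[2] + qz * camera$right[3]
  vert <- qy  # camera up is world +y
  u <- camera$cx + camera$f_px * lat / depth
  v <- camera$cy - camera$f_px * vert / depth
  view <- if (!is.null(camera$frontal_direction)) "frontal" else "sagittal"
  direction <- camera$frontal_direction %||% camera$sagittal_direction %||%
    NA_character_
  n_kp <- 25L
  nf <- nrow(traj) %/% n_kp
  # traj is keypoint-major (body25 order); gait_track wants frame-major
  ord <- as.vector(t(matrix(seq_len(nf * n_kp), nf, n_kp)))
  df <- tibble(
    frame = rep(seq_len(nf) - 1L, each = n_kp),
    keypoint = rep(body25_keypoints, nf),
    x = u[ord], y = v[ord], confidence = 1
  )
  gait_track(df, fps = fps, view = view, direction = direction,
             image_width = camera$image_width,
             image_height = camera$image_height, coords = "image")
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Corrupt a track with noise, dropout, and label swaps
#'
#' Applies the measurement imperfections of a real pose estimator to an
#' ideal track: additive Gaussian pixel noise on every observed coordinate,
#' random keypoint dropout (confidence set to 0, coordinates missing), and
#' left/right label swaps of the lower-limb keypoint pairs on randomly
#' chosen frames. All randomness is controlled by `seed`; the injection log
#' is reproducible bit-exactly.
#'
#' @param track A `gait_track`.
#' @param sigma_px SD of the Gaussian pixel noise (px).
#' @param dropout_p Per keypoint-frame dropout probability in `[0, 1]`.
#' @param swap_rate Per-frame probability of a left/right label swap in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted `gait_track`; the attribute `"corruption_log"`
#'   (accessor [corruption_log()]) records the swapped frames and the number
#'   of dropped keypoints.
#' @export
corrupt_track <- function(track, sigma_px = 0, dropout_p = 0, swap_rate = 0,
                          seed = 1L) {
  stopifnot(dropout_p >= 0, dropout_p <= 1, swap_rate >= 0, swap_rate <= 1)
  xm <- track_matrix(track, "x"); ym <- track_matrix(track, "y")
  cm <- track_matrix(track, "confidence")
  nf <- nrow(xm)
  log <- with_local_seed(seed, {
    if (sigma_px > 0) {
      obs <- !is.na(xm)
      xm[obs] <- xm[obs] + rnorm(sum(obs), 0, sigma_px)
      obs <- !is.na(ym)
      ym[obs] <- ym[obs] + rnorm(sum(obs), 0, sigma_px)
    }
    n_drop <- 0L
    if (dropout_p > 0) {
      drop <- matrix(runif(nf * 25L) < dropout_p, nf, 25L)
      xm[drop] <- NA_real_; ym[drop] <- NA_real_; cm[drop] <- 0
      n_drop <- sum(drop)
    }
    swapped <- integer(0)
    if (swap_rate > 0) {
      swapped <- which(runif(nf) < swap_rate) - 1L
      pairs <- body25_pairs(lower_limb_only = TRUE)
      li <- match(vapply(pairs, `[[`, "", 1L), body25_keypoints)
      ri <- match(vapply(pairs, `[[`, "", 2L), body25_keypoints)
      rows <- swapped + 1L
      tmp <- xm[rows, li]; xm[rows, li] <- xm[rows, ri]; xm[rows, ri] <- tmp
      tmp <- ym[rows, li]; ym[rows, li] <- ym[rows, ri]; ym[rows, ri] <- tmp
      tmp <- cm[rows, li]; cm[rows, li] <- cm[rows, ri]; cm[rows, ri] <- tmp
    }
    list(swapped_frames = swapped, n_dropped = n_drop,
         sigma_px = sigma_px, dropout_p = dropout_p, swap_rate = swap_rate,
         seed = as.integer(seed))
  })
  out <- track_set_matrix(track, x = xm, y = ym, confidence = cm)
  attr(out, "corruption_log") <- log
  out
}

#' @rdname corrupt_track
#' @export
corruption_log <- function(track) {
  attr(track, "corruption_log") %||%
    list(swapped_frames = integer(0), n_dropped = 0L)
}
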