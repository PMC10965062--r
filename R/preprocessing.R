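#' Correct left-right limb label swaps
#'
#' Pose estimators occasionally exchange the left and right labels of paired
#' limb keypoints for a frame or a run of frames. For each frame this keeps
#' whichever labeling (original, or with every lower-limb left/right pair
#' exchanged) minimizes the summed displacement of the paired keypoints from
#' the previous corrected frame, replacing the manual visual inspection a
#' human rater would perform. Correction starts at the first frame where both
#' ankles are present.
#'
#' @param track A `gait_track` in gait coordinates.
#' @param override Optional integer vector of frame indices to force-swap
#'   (reproduces manual edits); these frames bypass the displacement test.
#' @return The corrected `gait_track`. The attribute `"swap_report"`
#'   (accessor [swap_report()]) lists the frames whose labels were exchanged
#'   and the total count.
#' @export
correct_left_right <- function(track, override = NULL) {
  pairs <- body25_pairs(lower_limb_only = TRUE)
  li <- match(vapply(pairs, `[[`, "", 1L), body25_keypoints)
  ri <- match(vapply(pairs, `[[`, "", 2L), body25_keypoints)
  xm <- track_matrix(track, "x"); ym <- track_matrix(track, "y")
  cm <- track_matrix(track, "confidence")
  n <- nrow(xm)
  la <- match("l_ankle", body25_keypoints); ra <- match("r_ankle", body25_keypoints)
  start <- which(!is.na(xm[, la]) & !is.na(xm[, ra]))[1]
  swapped <- integer(0)
  if (!is.na(start)) {
    ref_x <- xm[start, ]; ref_y <- ym[start, ]
    frames <- setdiff(seq(start, n), start)
    for (f in c(start, frames)) {
      force_swap <- !is.null(override) && (f - 1L) %in% override
      cost <- function(ix) {
        # summed distance of paired keypoints to the reference positions
        dl <- sqrt((xm[f, ix$l] - ref_x[li])^2 + (ym[f, ix$l] - ref_y[li])^2)
        dr <- sqrt((xm[f, ix$r] - ref_x[ri])^2 + (ym[f, ix$r] - ref_y[ri])^2)
        d <- c(dl, dr)
        if (all(is.na(d))) return(NA_real_)
        sum(d, na.rm = TRUE) / sum(!is.na(d))
      }
      c_orig <- cost(list(l = li, r = ri))
      c_swap <- cost(list(l = ri, r = li))
      do_swap <- force_swap ||
        (!is.na(c_orig) && !is.na(c_swap) && c_swap < c_orig)
      if (do_swap && f != start) {
        tmp <- xm[f, li]; xm[f, li] <- xm[f, ri]; xm[f, ri] <- tmp
        tmp <- ym[f, li]; ym[f, li] <- ym[f, ri]; ym[f, ri] <- tmp
        tmp <- cm[f, li]; cm[f, li] <- cm[f, ri]; cm[f, ri] <- tmp
        swapped <- c(swapped, f - 1L)
      }
      upd <- !is.na(xm[f, ])
      ref_x[upd] <- xm[f, upd]; ref_y[upd] <- ym[f, upd]
    }
    # continuity cannot observe the global polarity: if the anchor frame
    # itself carried exchanged labels, the loop "corrects" every other frame
    # to match it. A majority of corrected frames means the anchor was the
    # outlier; flip the whole trial and complement the report.
    eligible <- which(!is.na(xm[, la]) | !is.na(xm[, ra])) - 1L
    if (length(swapped) > length(eligible) / 2) {
      rows <- eligible + 1L
      tmp <- xm[rows, li]; xm[rows, li] <- xm[rows, ri]; xm[rows, ri] <- tmp
      tmp <- ym[rows, li]; ym[rows, li] <- ym[rows, ri]; ym[rows, ri] <- tmp
      tmp <- cm[rows, li]; cm[rows, li] <- cm[rows, ri]; cm[rows, ri] <- tmp
      swapped <- setdiff(eligible, swapped)
    }
  }
  out <- track_set_matrix(track, x = xm, y = ym, confidence = cm)
  attr(out, "swap_report") <- list(swapped_frames = swapped,
                                   n_corrected = length(swapped))
  out
}

#' @rdname correct_left_right
#' @export
swap_report <- function(track) {
  attr(track, "swap_report") %||% list(swapped_frames = integer(0), n_corrected = 0L)
}

# fill interior NA runs of duration <= max_gap_s (inclusive) by linear
# interpolation; leading/trailing runs stay NA
fill_gaps_vector <- function(x, fps, max_gap_s = 0.12) {
  miss <- is.na(x)
  if (!any(miss) || all(miss)) return(x)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  filled <- approx(which(!miss), x[!miss], xout = seq_along(x), method = "linear",
                   rule = 1)$y
  max_n <- max_gap_s * fps + 1e-9
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (starts[k] == 1L || ends[k] == length(x)) next  # never extrapolate
    if (r$lengths[k] <= max_n) x[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
  }
  x
}

#' Fill short gaps in keypoint trajectories
#'
#' Linearly interpolates interior runs of missing samples whose duration is
#' at most `max_gap_s` (inclusive) between the bounding observed samples.
#' Longer gaps and leading/trailing runs are left missing — values are never
#' extrapolated. Observed samples are never altered, so the operation is
#' idempotent.
#'
#' @param x A numeric vector or a `gait_track` (every keypoint's x and y are
#'   filled; confidence is left as reported).
#' @param fps Sampling rate (Hz). Taken from the track metadata when `x` is a
#'   `gait_track`.
#' @param max_gap_s Longest gap to fill, in seconds.
#' @return Object of the same type as `x`.
#' @export
fill_gaps <- function(x, fps = NULL, max_gap_s = 0.12) {
  UseMethod("fill_gaps")
}

#' @export
fill_gaps.numeric <- function(x, fps = NULL, max_gap_s = 0.12) {
  if (is.null(fps)) abort("`fps` is required for numeric input.",
                          class = "videogait_config_error")
  fill_gaps_vector(x, fps, max_gap_s)
}

#' @export
fill_gaps.gait_track <- function(x, fps = NULL, max_gap_s = 0.12) {
  fps <- fps %||% track_meta(x)$fps
  xm <- track_matrix(x, "x"); ym <- track_matrix(x, "y")
  for (j in seq_len(ncol(xm))) {
    xm[, j] <- fill_gaps_vector(xm[, j], fps, max_gap_s)
    ym[, j] <- fill_gaps_vector(ym[, j], fps, max_gap_s)
  }
  track_set_matrix(x, x = xm, y = ym)
}

# steady-state initial filter state for a unit-step input (direct form II
# transposed), so the forward/backward passes start without a startup
# transient
iir_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)   # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# single-pass IIR filter, direct form II transposed, with initial state
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2L) for (j in seq_len(n - 2L)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# forward-backward pass with odd-reflection padding and steady-state initial
# conditions (zero phase; squared magnitude response)
filtfilt_zero_lag <- function(b, a, x, padlen) {
  nx <- length(x)
  padlen <- min(padlen, nx - 1L)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L, by = -1L)]
  post <- 2 * x[nx] - x[seq(nx - 1L, nx - padlen, by = -1L)]
  ext <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1L, padlen + nx)]
}

#' Zero-lag low-pass Butterworth filter
#'
#' Smooths a trajectory with an order-`order` low-pass Butterworth filter
#' applied forward and backward, which cancels the phase shift (zero lag) and
#' doubles the effective order. Edges are handled by odd-reflection padding
#' of length `3 * order` together with steady-state initial conditions, so a
#' constant series passes through unchanged.
#'
#' @param x Numeric vector (no interior `NA`s — gap-fill or trim first) or a
#'   `gait_track`.
#' @param fps Sampling rate (Hz); from track metadata when `x` is a track.
#' @param cutoff_hz Low-pass cutoff frequency (Hz); must be below the Nyquist
#'   frequency `fps / 2`.
#' @param order Filter order of each pass.
#' @return Filtered object of the same type and length as `x`. For tracks,
#'   each keypoint trajectory is filtered over its longest fully observed
#'   span; leading/trailing missing samples remain missing.
#' @export
lowpass_zero_lag <- function(x, fps = NULL, cutoff_hz, order = 4) {
  UseMethod("lowpass_zero_lag")
}

butter_coeffs <- function(cutoff_hz, fps, order) {
  if (cutoff_hz >= fps / 2) {
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz).",
                  cutoff_hz, fps / 2), class = "videogait_config_error")
  }
  bf <- signal::butter(order, cutoff_hz / (fps / 2), type = "low")
  list(b = bf$b, a = bf$a)
}

#' @export
lowpass_zero_lag.numeric <- function(x, fps = NULL, cutoff_hz, order = 4) {
  if (is.null(fps)) abort("`fps` is required for numeric input.",
                          class = "videogait_config_error")
  co <- butter_coeffs(cutoff_hz, fps, order)
  obs <- which(!is.na(x))
  if (length(obs) == 0L) return(x)
  i0 <- obs[1]; i1 <- obs[length(obs)]
  seg <- x[i0:i1]
  if (anyNA(seg)) {
    abort("interior missing samples: gap-fill or trim before filtering.",
          class = "videogait_data_error")
  }
  if (length(seg) > 3L * order + 1L) {
    x[i0:i1] <- filtfilt_zero_lag(co$b, co$a, seg, padlen = 3L * order)
  }
  x
}

#' @export
lowpass_zero_lag.gait_track <- function(x, fps = NULL, cutoff_hz, order = 4) {
  fps <- fps %||% track_meta(x)$fps
  xm <- track_matrix(x, "x"); ym <- track_matrix(x, "y")
  for (j in seq_len(ncol(xm))) {
    ok <- !is.na(xm[, j])
    if (!any(ok)) next
    span <- longest_observed_span(ok)
    if (length(span) < 3L * order + 2L) next
    xm[span, j] <- lowpass_zero_lag(xm[span, j], fps, cutoff_hz, order)
    ym[span, j] <- lowpass_zero_lag(ym[span, j], fps, cutoff_hz, order)
  }
  track_set_matrix(x, x = xm, y = ym)
}

longest_observed_span <- function(ok) {
  r <- rle(ok)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)[which.max(r$lengths[r$values])]
  seq(starts[k], ends[k])
}
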