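#' Agreement statistics between two measurement systems
#'
#' Bland-Altman style comparison of paired measurements of the same quantity
#' from two systems (e.g. video vs motion capture), at whatever pairing level
#' the inputs represent (matched steps, trial averages, or session averages):
#' the mean and SD of the differences `x - y`, the mean and SD of the
#' absolute differences (errors), the 95% limits of agreement
#' `mean(d) +/- 1.96 * sd(d)`, and the Pearson correlation of the paired
#' values.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2`.
#' @param level Optional label for the pairing level (`"step"`, `"trial"`,
#'   `"session"`, ...).
#' @param parameter Optional label for the quantity compared.
#' @return An object of class `gait_agreement` with fields `mean_diff`,
#'   `sd_diff`, `mae`, `sd_abs`, `loa_low`, `loa_high`, `r`, `n`. `r` is
#'   `NA` when either input has zero variance. Use [tidy()] or [glance()]
#'   for a tabular view.
#' @export
agreement <- function(x, y, level = NA_character_, parameter = NA_character_) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n || n < 2L) {
    abort("need at least two complete pairs.", class = "videogait_data_error")
  }
  d <- x - y
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  structure(list(
    mean_diff = mean(d), sd_diff = sd(d),
    mae = mean(abs(d)), sd_abs = sd(abs(d)),
    loa_low = mean(d) - 1.96 * sd(d),
    loa_high = mean(d) + 1.96 * sd(d),
    r = r, n = n, level = level, parameter = parameter
  ), class = "gait_agreement")
}

#' @export
print.gait_agreement <- function(x, ...) {
  cat(sprintf(
    paste0("Agreement (%s, %s; n = %d)\n",
           "  difference : %.4f ± %.4f\n",
           "  error      : %.4f ± %.4f\n",
           "  95%% LoA    : [%.4f, %.4f]\n",
           "  Pearson r  : %s\n"),
    x$parameter %||% NA, x$level %||% NA, x$n,
    x$mean_diff, x$sd_diff, x$mae, x$sd_abs, x$loa_low, x$loa_high,
    ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r))))
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x A `gait_agreement` object.
#' @param ... Unused.
#' @return `tidy()`: one row per statistic (`statistic`, `value`).
#'   `glance()`: a one-row tibble with all statistics as columns.
#' @exportS3Method generics::tidy
tidy.gait_agreement <- function(x, ...) {
  tibble(
    statistic = c("mean_diff", "sd_diff", "mae", "sd_abs",
                  "loa_low", "loa_high", "r", "n"),
    value = c(x$mean_diff, x$sd_diff, x$mae, x$sd_abs,
              x$loa_low, x$loa_high, x$r, x$n)
  )
}

#' @rdname tidy.gait_agreement
#' @exportS3Method generics::glance
glance.gait_agreement <- function(x, ...) {
  tibble(parameter = x$parameter, level = x$level,
         mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         mae = x$mae, sd_abs = x$sd_abs,
         loa_low = x$loa_low, loa_high = x$loa_high, r = x$r, n = x$n)
}

# resample one cycle of a waveform onto a 0-100% grid (linear interpolation
# in cycle phase)
normalize_cycle <- function(time, value, t_start, t_end, n = 101L) {
  phase_t <- seq(t_start, t_end, length.out = n)
  approx(time, value, xout = phase_t, rule = 2)$y
}

#' Waveform mean absolute error over gait cycles
#'
#' Compares two joint-angle waveform sets cycle by cycle. Gait cycles run
#' between consecutive same-side heel-strikes; each cycle of each series is
#' time-normalized to `n_points` samples spanning 0-100% of the cycle, and
#' the MAE is the mean absolute difference over those samples, averaged over
#' cycles.
#'
#' @param angles_a,angles_b [joint_angles()] tibbles sharing a clock.
#' @param events A [gait_events()] table defining the cycles (matched
#'   heel-strikes).
#' @param n_points Samples per normalized cycle.
#' @return A tibble of class `waveform_mae` (`side`, `joint`, `mae_deg`,
#'   `n_cycles`); empty when no complete cycle exists.
#' @export
kinematic_mae <- function(angles_a, angles_b, events, n_points = 101L) {
  hs <- events[events$event == "heel_strike", ]
  out <- list()
  for (s in c("left", "right")) {
    t_hs <- sort(hs$time_s[hs$side == s])
    if (length(t_hs) < 2L) next
    cycles <- tibble(t0 = t_hs[-length(t_hs)], t1 = t_hs[-1])
    for (j in c("hip", "knee", "ankle")) {
      wa <- angles_a[angles_a$side == s & angles_a$joint == j, ]
      wb <- angles_b[angles_b$side == s & angles_b$joint == j, ]
      if (nrow(wa) == 0L || nrow(wb) == 0L) next
      maes <- purrr::map2_dbl(cycles$t0, cycles$t1, function(t0, t1) {
        ya <- normalize_cycle(wa$time, wa$angle_deg, t0, t1, n_points)
        yb <- normalize_cycle(wb$time, wb$angle_deg, t0, t1, n_points)
        mean(abs(ya - yb))
      })
      maes <- maes[!is.na(maes)]
      if (length(maes) == 0L) next
      out[[length(out) + 1L]] <- tibble(side = s, joint = j,
                                        mae_deg = mean(maes),
                                        n_cycles = length(maes))
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(side = character(), joint = character(),
           mae_deg = double(), n_cycles = integer())
  structure(res, class = c("waveform_mae", class(res)))
}

#' Export an agreement report as CSV or JSON
#'
#' Writes one or several agreement reports as a flat table mirroring the
#' difference / error / limits-of-agreement layout used for system
#' comparisons.
#'
#' @param reports A `gait_agreement` or a list of them.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_agreement <- function(reports, path) {
  if (inherits(reports, "gait_agreement")) reports <- list(reports)
  tab <- dplyr::bind_rows(lapply(reports, glance))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    readr::write_csv(tab, path)
  }
  invisible(path)
}
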