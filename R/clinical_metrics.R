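#' Label steps by the side of their terminating heel-strike
#'
#' A step runs between two consecutive bilateral heel-strikes and takes the
#' side of the heel-strike that ends it: the left (or paretic) step time is
#' the duration from a right (non-paretic) heel-strike to the next left
#' (paretic) heel-strike, and vice versa. The same rule labels torso-travel
#' step lengths. Two consecutive same-side heel-strikes produce a step
#' flagged invalid rather than silently dropped.
#'
#' @param events A [gait_events()] table (only heel-strikes are used).
#' @return A tibble with one row per step: `side`, `t_start`, `t_end`,
#'   `step_time_s`, `valid`.
#' @export
assign_step_sides <- function(events) {
  hs <- events[events$event == "heel_strike", ]
  hs <- hs[order(hs$time_s), ]
  if (nrow(hs) < 2L) {
    return(tibble(side = character(), t_start = double(), t_end = double(),
                  step_time_s = double(), valid = logical()))
  }
  tibble(
    side = hs$side[-1],
    t_start = hs$time_s[-nrow(hs)],
    t_end = hs$time_s[-1],
    step_time_s = diff(hs$time_s),
    valid = hs$side[-1] != hs$side[-nrow(hs)]
  )
}

#' Step asymmetry index
#'
#' The difference between the two sides' mean step values divided by their
#' sum, `(mean_a - mean_b) / (mean_a + mean_b)`: zero for symmetric gait,
#' bounded in (-1, 1) for positive step values, and antisymmetric under side
#' exchange. By convention side `a` is the paretic (stroke) or left side.
#'
#' @param a,b Numeric vectors of per-step values (e.g. step times or lengths)
#'   for the paretic/left and non-paretic/right sides.
#' @return The asymmetry index (dimensionless scalar).
#' @export
asymmetry <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) {
    abort("both sides need at least one step.", class = "videogait_data_error")
  }
  ma <- mean(a); mb <- mean(b)
  if (ma + mb <= 0) {
    abort("asymmetry undefined: side means sum to a non-positive value.",
          class = "videogait_data_error")
  }
  (ma - mb) / (ma + mb)
}

# per-trial means of the spatiotemporal parameters plus asymmetries
trial_means <- function(steps, paretic_side = "left") {
  other <- setdiff(c("left", "right"), paretic_side)
  # asymmetries first: summarise() lets later expressions see earlier
  # results, and the means below reuse the column names
  steps |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(
      n_steps = dplyr::n(),
      step_time_asym = asym_or_na(.data$step_time_s, .data$side, paretic_side, other),
      step_length_asym = asym_or_na(.data$step_length_m, .data$side, paretic_side, other),
      step_time_s = mean(.data$step_time_s),
      step_length_m = mean(.data$step_length_m),
      speed_mps = mean(.data$speed_mps),
      .groups = "drop"
    )
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

asym_or_na <- function(values, side, a, b) {
  va <- values[side == a]; vb <- values[side == b]
  if (length(va) < 1L || length(vb) < 1L) return(NA_real_)
  asymmetry(va, vb)
}

#' Session-level gait summary
#'
#' Aggregates a set of walking trials recorded in one session and condition
#' into the averages a clinical gait analysis reports: mean step time, step
#' length, gait speed, step asymmetries, and (optionally) trunk inclination.
#' The session value of each parameter is the unweighted mean of the trial
#' means — each trial counts equally regardless of how many steps it
#' contains. Asymmetries are computed within each trial and then averaged;
#' `pooled = TRUE` instead pools all steps of the session before computing
#' them (useful for step-level comparisons).
#'
#' @param steps A step table covering one or more trials (column `trial_id`
#'   distinguishes them).
#' @param condition Condition label (e.g. `"preferred"` or `"fast"`);
#'   defaults to the step table's `condition` value.
#' @param trunk Optional tibble with `trial_id` and `inclination_deg`
#'   (per-event values from [trunk_inclination()]); averaged per trial, then
#'   across trials.
#' @param paretic_side Which side is the paretic/left reference side for the
#'   asymmetry sign (`"left"` by default).
#' @param pooled Pool steps across trials instead of averaging trial means.
#' @return A one-row tibble of class `session_summary`.
#' @export
session_summary <- function(steps, condition = NULL, trunk = NULL,
                            paretic_side = c("left", "right"),
                            pooled = FALSE) {
  paretic_side <- match.arg(paretic_side)
  if (nrow(steps) == 0L) {
    abort("no steps to summarise.", class = "videogait_data_error")
  }
  condition <- condition %||% steps$condition[1]
  other <- setdiff(c("left", "right"), paretic_side)
  if (pooled) {
    out <- tibble(
      condition = condition, n_trials = length(unique(steps$trial_id)),
      n_steps = nrow(steps),
      step_time_s = mean(steps$step_time_s),
      step_length_m = mean(steps$step_length_m),
      speed_mps = mean(steps$speed_mps),
      step_time_asym = asym_or_na(steps$step_time_s, steps$side, paretic_side, other),
      step_length_asym = asym_or_na(steps$step_length_m, steps$side, paretic_side, other)
    )
  } else {
    tm <- trial_means(steps, paretic_side)
    out <- tibble(
      condition = condition, n_trials = nrow(tm), n_steps = sum(tm$n_steps),
      step_time_s = mean(tm$step_time_s),
      step_length_m = mean(tm$step_length_m),
      speed_mps = mean(tm$speed_mps),
      step_time_asym = mean_or_na(tm$step_time_asym),
      step_length_asym = mean_or_na(tm$step_length_asym)
    )
  }
  out$trunk_inclination_deg <- if (is.null(trunk)) NA_real_ else {
    per_trial <- tapply(trunk$inclination_deg, trunk$trial_id,
                        mean, na.rm = TRUE)
    mean(per_trial)
  }
  structure(out, class = c("session_summary", class(out)))
}

#' Speed-related change in gait parameters
#'
#' The change in each gait parameter that accompanies a change in walking
#' speed: elementwise `fast - preferred` of two session summaries from the
#' same subject and measurement system. A parameter missing in either
#' condition is missing in the output.
#'
#' @param pref,fast [session_summary()] rows for the preferred- and
#'   fast-speed conditions.
#' @return A one-row tibble of class `speed_change` with the same parameter
#'   columns as the summaries (suffix-free), each holding fast minus
#'   preferred.
#' @export
speed_change <- function(pref, fast) {
  params <- c("step_time_s", "step_length_m", "speed_mps",
              "step_time_asym", "step_length_asym", "trunk_inclination_deg")
  out <- tibble(.rows = 1L)
  for (p in params) {
    out[[p]] <- if (p %in% names(pref) && p %in% names(fast)) {
      fast[[p]] - pref[[p]]
    } else NA_real_
  }
  structure(out, class = c("speed_change", class(out)))
}

#' Read and write step-table CSV files
#'
#' @param steps A step table.
#' @param path File path.
#' @return `read_steps_csv()` returns the step-table tibble;
#'   `write_steps_csv()` returns `path` invisibly.
#' @export
write_steps_csv <- function(steps, path) {
  readr::write_csv(steps, path)
  invisible(path)
}

#' @rdname write_steps_csv
#' @export
read_steps_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
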