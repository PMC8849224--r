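#' Build the dosing schedule for one study condition
#'
#' The study administers capsules three times a day, at 45 min, 4 h and 8 h
#' after waking, for ten days. In the caffeine condition every capsule
#' contains 150 mg caffeine (450 mg/day); in the placebo condition every
#' capsule is inert (dose 0, inactive); in the deprivation condition the
#' caffeine capsules stop after `active_days` days and placebo follows, so
#' that the day-10 sampling window falls 24--43 h after the last active dose.
#'
#' @param condition One of `"caffeine"`, `"deprivation"`, `"placebo"`.
#' @param n_days Number of study days (default 10).
#' @param dose_mg Caffeine dose per capsule (mg, default 150).
#' @param dose_offsets_h Dose times within a day, hours after waking
#'   (default `c(0.75, 4, 8)`).
#' @param wake_interval_h Hours between successive wake times (default 24).
#' @param active_days For the deprivation condition, the number of days with
#'   active capsules before the switch to placebo (default `n_days - 1`).
#'
#' @return A `dosing_schedule`: a data frame with columns `time_h` (hours
#'   since study start, sorted), `dose_mg` and `active`, carrying the
#'   condition and design settings as attributes.
#' @examples
#' sched <- build_schedule("caffeine")
#' sum(sched$active)        # 30 active capsules
#' daily_dose(sched)        # 450 mg on a full caffeine day
#' @export
build_schedule <- function(condition = c("caffeine", "deprivation", "placebo"),
                           n_days = 10,
                           dose_mg = 150,
                           dose_offsets_h = c(0.75, 4, 8),
                           wake_interval_h = 24,
                           active_days = n_days - 1) {
  condition <- match.arg(condition)
  stopifnot(n_days >= 1, dose_mg >= 0, wake_interval_h > 0,
            length(dose_offsets_h) >= 1, all(dose_offsets_h >= 0))
  dose_offsets_h <- sort(dose_offsets_h)
  day <- rep(seq_len(n_days), each = length(dose_offsets_h))
  time_h <- (day - 1) * wake_interval_h + rep(dose_offsets_h, times = n_days)
  active <- switch(condition,
    caffeine    = rep(TRUE, length(time_h)),
    placebo     = rep(FALSE, length(time_h)),
    deprivation = day <= active_days
  )
  if (condition == "deprivation" && (active_days < 1 || active_days >= n_days)) {
    stop("'active_days' must be in [1, n_days - 1] for the deprivation condition",
         call. = FALSE)
  }
  sched <- data.frame(time_h = time_h,
                      dose_mg = ifelse(active, dose_mg, 0),
                      active = active)
  structure(sched,
            condition = condition, n_days = n_days, dose_mg = dose_mg,
            dose_offsets_h = dose_offsets_h, wake_interval_h = wake_interval_h,
            class = c("dosing_schedule", "data.frame"))
}

#' Time of the last (active) dose in a schedule
#'
#' For the caffeine and deprivation conditions this is the last caffeine
#' administration, the reference point for all post-dose latencies. The
#' placebo condition has no active dose; the last capsule time is returned
#' so that its sampling grid sits at the same clock times as in the other
#' conditions.
#'
#' @param schedule A [build_schedule()] object.
#' @return Time (h since study start).
#' @export
last_dose_time <- function(schedule) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  if (any(schedule$active)) max(schedule$time_h[schedule$active])
  else max(schedule$time_h)
}

#' Total active dose on a full dosing day
#'
#' @param schedule A [build_schedule()] object.
#' @param day Day number (default 1, a full active day in the caffeine and
#'   deprivation conditions).
#' @return Dose (mg).
#' @export
daily_dose <- function(schedule, day = 1) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  w <- attr(schedule, "wake_interval_h")
  sel <- schedule$time_h >= (day - 1) * w & schedule$time_h < day * w
  sum(schedule$dose_mg[sel])
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat(sprintf("<dosing_schedule> condition = %s, %d days, %d events (%d active)\n",
              attr(x, "condition"), attr(x, "n_days"), nrow(x), sum(x$active)))
  cat(sprintf("  last dose at %.2f h; %g mg per active capsule\n",
              last_dose_time(x), attr(x, "dose_mg")))
  invisible(x)
}

#' Day-10 saliva sampling grid for a condition
#'
#' Eleven saliva samples are collected at 105--120 min intervals. For the
#' caffeine and placebo conditions the grid starts at the pre-first-dose
#' baseline sample on the last study day (the overnight-residual sample,
#' 7.25 h before the last dose, i.e. about 17 h after the previous day's
#' last intake) and proceeds in steps of `spacing_h`; the default spacing of
#' 1.80 h (108 min) places the earliest post-dose sample at exactly +1.75 h
#' after the last dose, the design's minimum observable peak latency. For
#' the deprivation condition the grid spans `deprivation_window_h` after the
#' last active dose (default 24--43 h, spacing 1.9 h).
#'
#' @param schedule A [build_schedule()] object.
#' @param n_samples Number of samples (default 11).
#' @param spacing_h Sample spacing for the caffeine/placebo grid (h).
#' @param baseline_offset_h Offset of the baseline sample relative to the
#'   last dose (h); defaults to minus the span of the daily dose offsets
#'   (-7.25 h for the default design).
#' @param deprivation_window_h Two-vector: start and end of the deprivation
#'   sampling window, hours after the last active dose.
#'
#' @return A `sampling_grid`: list with `times` (h since study start),
#'   `reference` (last-dose time) and `offsets` (h after last dose).
#' @examples
#' g <- sampling_grid(build_schedule("caffeine"))
#' g$offsets   # -7.25 ... +10.75, earliest post-dose sample at +1.75
#' @export
sampling_grid <- function(schedule,
                          n_samples = 11,
                          spacing_h = 1.8,
                          baseline_offset_h = NULL,
                          deprivation_window_h = c(24, 43)) {
  stopifnot(inherits(schedule, "dosing_schedule"), n_samples >= 2)
  ref <- last_dose_time(schedule)
  condition <- attr(schedule, "condition")
  if (condition == "deprivation") {
    offsets <- seq(deprivation_window_h[1], deprivation_window_h[2],
                   length.out = n_samples)
  } else {
    if (is.null(baseline_offset_h)) {
      off <- attr(schedule, "dose_offsets_h")
      baseline_offset_h <- -(max(off) - min(off))
    }
    offsets <- baseline_offset_h + spacing_h * (seq_len(n_samples) - 1)
  }
  sp <- diff(offsets)
  if (n_samples == 11 && (any(sp < 1.75 - 1e-9) || any(sp > 2 + 1e-9))) {
    warning("sample spacing outside the design's 105-120 min interval",
            call. = FALSE)
  }
  structure(list(times = ref + offsets, reference = ref, offsets = offsets),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("<sampling_grid> %d samples, reference dose at %.2f h\n",
              length(x$times), x$reference))
  cat("  offsets after last dose (h):", paste(round(x$offsets, 2), collapse = ", "),
      "\n")
  invisible(x)
}
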