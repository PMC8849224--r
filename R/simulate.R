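#' Build a concentration profile data frame
#'
#' The package's exchange shape for one analyte's concentration--time
#' samples: columns `time_h`, `conc_ug_ml`, `censored` and optionally
#' `analyte` and latency after the last dose.
#'
#' @param time_h Sample times (h).
#' @param conc_ug_ml Concentrations (ug/ml), non-negative.
#' @param censored Logical flags, recycled; censored samples carry
#'   concentration 0.
#' @param analyte Optional analyte label.
#' @param time_after_last_dose_h Optional latencies after the last dose (h).
#' @return A data frame of class `concentration_profile`.
#' @export
concentration_profile <- function(time_h, conc_ug_ml, censored = FALSE,
                                  analyte = NULL,
                                  time_after_last_dose_h = NULL) {
  stopifnot(length(time_h) == length(conc_ug_ml), all(conc_ug_ml >= 0))
  out <- data.frame(time_h = time_h, conc_ug_ml = conc_ug_ml,
                    censored = rep_len(as.logical(censored), length(time_h)))
  if (!is.null(analyte)) out$analyte <- analyte
  if (!is.null(time_after_last_dose_h)) {
    out$time_after_last_dose_h <- time_after_last_dose_h
  }
  class(out) <- c("concentration_profile", "data.frame")
  out
}

#' Simulate noise-free concentration profiles for one subject
#'
#' Evaluates the multiple-dose profile by superposition: the concentration
#' at each sampling time is the sum of the single-dose closed forms
#' ([parent_conc()], [metabolite_conc()]) over all active dose events of the
#' schedule, shifted to each event time. Linearity holds exactly, so the
#' profile of an n-event schedule equals the sum of n single-event profiles.
#'
#' @param schedule A [build_schedule()] object.
#' @param params A [pk_params()] object or one-row cohort data frame.
#' @param grid A [sampling_grid()] object or a numeric vector of times
#'   (h since study start).
#' @return A long data frame with columns `analyte` (`"caffeine"`,
#'   `"paraxanthine"`), `time_h`, `time_after_last_dose_h`, `conc_ug_ml`,
#'   `censored` (all `FALSE`; see [apply_noise()]).
#' @examples
#' sched <- build_schedule("caffeine")
#' prof <- simulate_profiles(sched, pk_params(), sampling_grid(sched))
#' subset(prof, analyte == "caffeine")
#' @export
simulate_profiles <- function(schedule, params, grid) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  params <- as_pk_params(params)
  if (inherits(grid, "sampling_grid")) {
    times <- grid$times
    ref <- grid$reference
  } else {
    stopifnot(is.numeric(grid))
    times <- grid
    ref <- last_dose_time(schedule)
  }
  events <- schedule[schedule$active & schedule$dose_mg > 0, , drop = FALSE]
  ca <- numeric(length(times))
  px <- numeric(length(times))
  for (k in seq_len(nrow(events))) {
    lag <- times - events$time_h[k]
    ca <- ca + parent_conc(lag, events$dose_mg[k], params)
    px <- px + metabolite_conc(lag, events$dose_mg[k], params)
  }
  rbind(
    concentration_profile(times, ca, FALSE, "caffeine", times - ref),
    concentration_profile(times, px, FALSE, "paraxanthine", times - ref)
  )
}

#' Simulate the full three-condition study for a cohort
#'
#' Runs [build_schedule()], [sampling_grid()] and [simulate_profiles()] for
#' every subject and condition, and optionally applies assay noise and LLOQ
#' censoring. Noise streams are derived deterministically from `seed` per
#' subject and condition.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param conditions Conditions to simulate.
#' @param n_days,dose_mg,dose_offsets_h,wake_interval_h,active_days Design
#'   settings passed to [build_schedule()].
#' @param n_samples,spacing_h,deprivation_window_h Grid settings passed to
#'   [sampling_grid()].
#' @param noise_cv Assay coefficient of variation (0 for noise-free).
#' @param lloq Named quantification floors per analyte (ug/ml).
#' @param seed Master integer seed for the noise streams.
#' @return A long data frame: `subject_id`, `condition`, `analyte`,
#'   `time_h`, `time_after_last_dose_h`, `conc_ug_ml`, `censored`.
#' @examples
#' cohort <- generate_cohort(2, seed = 1)
#' study <- simulate_study(cohort, noise_cv = 0)
#' table(study$condition, study$analyte)
#' @export
simulate_study <- function(cohort,
                           conditions = c("caffeine", "deprivation", "placebo"),
                           n_days = 10, dose_mg = 150,
                           dose_offsets_h = c(0.75, 4, 8),
                           wake_interval_h = 24,
                           active_days = n_days - 1,
                           n_samples = 11, spacing_h = 1.8,
                           deprivation_window_h = c(24, 43),
                           noise_cv = 0.1,
                           lloq = c(caffeine = 0.04, paraxanthine = 0.02),
                           seed = 1) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  out <- vector("list", length(conditions) * nrow(cohort))
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    sched <- build_schedule(cond, n_days = n_days, dose_mg = dose_mg,
                            dose_offsets_h = dose_offsets_h,
                            wake_interval_h = wake_interval_h,
                            active_days = active_days)
    grid <- sampling_grid(sched, n_samples = n_samples, spacing_h = spacing_h,
                          deprivation_window_h = deprivation_window_h)
    for (si in seq_len(nrow(cohort))) {
      prof <- simulate_profiles(sched, cohort[si, , drop = FALSE], grid)
      if (noise_cv > 0 || any(lloq > 0)) {
        prof <- apply_noise(prof, cv = noise_cv, lloq = lloq,
                            seed = derive_seed(seed, si, ci))
      }
      prof <- cbind(subject_id = cohort$subject_id[si], condition = cond, prof)
      idx <- idx + 1L
      out[[idx]] <- prof
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res[, c("subject_id", "condition", "analyte", "time_h",
          "time_after_last_dose_h", "conc_ug_ml", "censored")]
}
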