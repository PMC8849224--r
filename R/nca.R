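# Non-compartmental descriptors computed directly from sampled
# concentration-time profiles, matching the saliva-study definitions:
# the peak is the maximal level after the last administration, the
# half-life is the time from the peak to the C50 crossing (half the peak),
# the elimination rate is a log-linear fit over the post-peak samples, and
# AUCs use the trapezoidal rule over the sampled window.

profile_cols <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (is.null(profile$time_h) || is.null(profile$conc_ug_ml)) {
    stop("profile needs 'time_h' and 'conc_ug_ml' columns", call. = FALSE)
  }
  cens <- if (is.null(profile$censored)) rep(FALSE, nrow(profile)) else
    as.logical(profile$censored)
  o <- order(profile$time_h)
  list(time = profile$time_h[o], conc = profile$conc_ug_ml[o], cens = cens[o])
}

#' Peak level and peak time after the last dose
#'
#' `cmax` is the maximal uncensored concentration observed after
#' `last_dose_time`; `tmax` is that sample's latency from the last dose,
#' with ties broken by the earliest time. Because the grid's first
#' post-dose sample bounds the observable latency from below, `tmax` can
#' never be smaller than that sample's latency (grid censoring).
#'
#' @param profile A profile data frame (`time_h`, `conc_ug_ml`, `censored`).
#' @param last_dose_time Time of the last active dose (h, same clock as
#'   `time_h`).
#' @return A list with elements `cmax` (ug/ml) and `tmax` (h after the
#'   last dose).
#' @examples
#' prof <- concentration_profile(c(2, 4, 6), c(3, 3, 1))
#' nca_peak(prof, last_dose_time = 0)  # tie broken at the earlier sample
#' @export
nca_peak <- function(profile, last_dose_time) {
  p <- profile_cols(profile)
  sel <- p$time > last_dose_time & !p$cens
  if (!any(sel)) {
    stop("undefined result: no uncensored samples after the last dose",
         call. = FALSE)
  }
  tt <- p$time[sel]; cc <- p$conc[sel]
  i <- which(cc == max(cc))[1]
  list(cmax = cc[i], tmax = tt[i] - last_dose_time)
}

#' C50-crossing half-life
#'
#' The half-life is the time from the observed peak to the moment the
#' concentration falls to half the peak level (C50). The post-peak samples
#' are scanned for the first bracketing pair and the crossing time is
#' interpolated, log-linearly by default (exact for exponential decline) or
#' linearly. Censored and non-positive samples are excluded from the
#' search. If no crossing lies within the sampled window the descriptor is
#' undefined and `NA` is returned (a flagged value, not an error): sparse
#' grids routinely force this for slowly eliminated metabolites.
#'
#' @inheritParams nca_peak
#' @param interpolation `"log"` (default) or `"linear"` crossing
#'   interpolation.
#' @return Half-life (h), or `NA_real_` when the profile never reaches C50.
#' @examples
#' # hand-checkable log-linear crossing: 2 + 4*log(2)/log(4) = 4 h
#' prof <- concentration_profile(c(2, 6), c(4, 1))
#' half_life_c50(prof, last_dose_time = 0)  # 2.0
#' @export
half_life_c50 <- function(profile, last_dose_time,
                          interpolation = c("log", "linear")) {
  interpolation <- match.arg(interpolation)
  pk <- nca_peak(profile, last_dose_time)
  p <- profile_cols(profile)
  sel <- p$time >= last_dose_time + pk$tmax & !p$cens & p$conc > 0
  tt <- p$time[sel]; cc <- p$conc[sel]
  half <- pk$cmax / 2
  if (length(tt) < 2) return(NA_real_)
  for (i in seq_len(length(tt) - 1L)) {
    if (cc[i] >= half && cc[i + 1] <= half) {
      tstar <- if (interpolation == "log") {
        tt[i] + (tt[i + 1] - tt[i]) *
          (log(cc[i]) - log(half)) / (log(cc[i]) - log(cc[i + 1]))
      } else {
        tt[i] + (tt[i + 1] - tt[i]) * (cc[i] - half) / (cc[i] - cc[i + 1])
      }
      return(tstar - (last_dose_time + pk$tmax))
    }
  }
  NA_real_
}

#' Elimination rate constant by log-linear regression
#'
#' Ordinary least squares of log concentration on time over all uncensored,
#' positive samples strictly after the peak; returns minus the slope.
#' Undefined (`NA`) with fewer than three usable post-peak samples.
#'
#' @inheritParams nca_peak
#' @return Elimination rate (1/h), or `NA_real_`.
#' @seealso [kel_from_half_life()] for the `ln(2) / t_1/2` alternative.
#' @export
kel_loglinear <- function(profile, last_dose_time) {
  pk <- nca_peak(profile, last_dose_time)
  p <- profile_cols(profile)
  sel <- p$time > last_dose_time + pk$tmax & !p$cens & p$conc > 0
  if (sum(sel) < 3) return(NA_real_)
  fit <- lm(log(p$conc[sel]) ~ p$time[sel])
  -unname(coef(fit)[2])
}

#' Elimination rate from a C50 half-life
#'
#' The alternative estimator `ln(2) / half_life`; provided because sampled
#' studies report both descriptors and the two estimators need not agree on
#' profiles that are not mono-exponential from the peak.
#'
#' @param half_life Half-life (h); `NA` propagates.
#' @return Rate (1/h).
#' @export
kel_from_half_life <- function(half_life) log(2) / half_life

#' Trapezoidal area under the curve
#'
#' Linear trapezoidal rule over the samples inside `[t_start, t_end]`.
#' Censored samples enter as 0 (conservative; the bias is bounded by LLOQ
#' times the window width). Exact for piecewise-linear profiles and
#' additive over adjacent windows.
#'
#' @inheritParams nca_peak
#' @param t_start,t_end Window bounds (h); default to the sampled range.
#' @return AUC (ug h/ml).
#' @examples
#' prof <- concentration_profile(0:3, c(0, 2, 2, 0))
#' auc_trapezoid(prof)  # 4
#' @export
auc_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  p <- profile_cols(profile)
  if (is.null(t_start)) t_start <- min(p$time)
  if (is.null(t_end)) t_end <- max(p$time)
  sel <- p$time >= t_start - 1e-9 & p$time <= t_end + 1e-9
  if (sum(sel) < 2) {
    stop("need at least two samples inside the AUC window", call. = FALSE)
  }
  tt <- p$time[sel]
  cc <- ifelse(p$cens[sel], 0, p$conc[sel])
  sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2)
}

#' Overnight residual concentration
#'
#' The concentration at the pre-first-dose baseline sample on the last
#' study day (collected about 17 h after the previous day's last intake);
#' it indexes how much of the compound is carried overnight during daily
#' intake. A censored baseline returns 0.
#'
#' @inheritParams nca_peak
#' @param pre_dose_time Time of the baseline sample (h).
#' @return Concentration (ug/ml).
#' @export
overnight_residual <- function(profile, pre_dose_time) {
  p <- profile_cols(profile)
  i <- which(abs(p$time - pre_dose_time) <= 1e-6)
  if (!length(i)) {
    stop("no baseline sample at the requested pre-dose time", call. = FALSE)
  }
  i <- i[1]
  if (p$cens[i]) 0 else p$conc[i]
}

#' Metabolite-to-parent AUC disproportionality
#'
#' The ratio of the metabolite's AUC to the parent's over the same window;
#' values above the single-dose expectation index relative metabolite
#' accumulation.
#'
#' @param auc_px Metabolite AUC (ug h/ml).
#' @param auc_ca Parent AUC (ug h/ml); must be positive for a defined ratio.
#' @return The ratio, or `NA_real_` for a non-positive denominator.
#' @export
disproportionality <- function(auc_px, auc_ca) {
  ifelse(is.na(auc_ca) | auc_ca <= 0, NA_real_, auc_px / auc_ca)
}

#' Per-subject NCA descriptor table
#'
#' Computes, for every subject and analyte of a simulated or imported
#' study: peak level and time, C50 half-life, elimination rate, AUC over
#' the caffeine-condition window (`auc_c`), AUC over the deprivation window
#' (`auc_w`, when that condition is present) and the overnight residual.
#' Last-dose times and the baseline sample are recovered from the profile
#' latencies, so the table can be built from any CSV in the package's
#' exchange dialect.
#'
#' @param profiles A long profile data frame as produced by
#'   [simulate_study()] or read by [read_profiles()].
#' @param interpolation Passed to [half_life_c50()].
#' @param kel_method `"regression"` ([kel_loglinear()], default) or
#'   `"half_life"` (`ln 2 / t_1/2`).
#' @return A data frame, one row per subject x analyte, with columns
#'   `subject_id`, `analyte`, `cmax`, `tmax`, `half_life`, `kel`, `auc_c`,
#'   `auc_w`, `residual`, `dispro` (metabolite/parent AUC ratio, on
#'   metabolite rows) and `n_kel_samples`.
#' @examples
#' study <- simulate_study(generate_cohort(3, seed = 1), noise_cv = 0)
#' nca_table(study)
#' @export
nca_table <- function(profiles, interpolation = c("log", "linear"),
                      kel_method = c("regression", "half_life")) {
  interpolation <- match.arg(interpolation)
  kel_method <- match.arg(kel_method)
  stopifnot(is.data.frame(profiles))
  if (!"caffeine" %in% profiles$condition) {
    stop("profiles must contain the caffeine condition", call. = FALSE)
  }
  rows <- list()
  for (sid in unique(profiles$subject_id)) {
    sub <- profiles[profiles$subject_id == sid, , drop = FALSE]
    res <- list()
    for (an in unique(sub$analyte)) {
      caf <- sub[sub$condition == "caffeine" & sub$analyte == an, , drop = FALSE]
      caf <- caf[order(caf$time_h), , drop = FALSE]
      ldt <- caf$time_h[1] - caf$time_after_last_dose_h[1]
      pk <- nca_peak(caf, ldt)
      hl <- half_life_c50(caf, ldt, interpolation)
      n_kel <- sum(caf$time_h > ldt + pk$tmax & !caf$censored &
                     caf$conc_ug_ml > 0)
      kel <- if (kel_method == "regression") kel_loglinear(caf, ldt) else
        kel_from_half_life(hl)
      auc_c <- auc_trapezoid(caf)
      resid <- overnight_residual(caf, min(caf$time_h))
      auc_w <- NA_real_
      dep <- sub[sub$condition == "deprivation" & sub$analyte == an, , drop = FALSE]
      if (nrow(dep) >= 2) auc_w <- auc_trapezoid(dep)
      res[[an]] <- data.frame(subject_id = sid, analyte = an,
                              cmax = pk$cmax, tmax = pk$tmax,
                              half_life = hl, kel = kel,
                              auc_c = auc_c, auc_w = auc_w,
                              residual = resid, dispro = NA_real_,
                              n_kel_samples = n_kel)
    }
    if (all(c("caffeine", "paraxanthine") %in% names(res))) {
      res$paraxanthine$dispro <- disproportionality(res$paraxanthine$auc_c,
                                                    res$caffeine$auc_c)
    }
    rows[[sid]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of NCA descriptors
#'
#' Summarises a [nca_table()] in the shape of a kinetics summary table:
#' median and interquartile range for peak time and half-life; mean, SD
#' (n-1 denominator), minimum and maximum for the elimination rate, peak
#' level, overnight residual and both AUCs. Undefined descriptors are
#' excluded pairwise and their counts reported.
#'
#' @param nca A data frame from [nca_table()].
#' @return A data frame with one row per analyte x descriptor:
#'   `analyte`, `descriptor`, `n`, `n_missing`, `median`, `iqr_lo`,
#'   `iqr_hi`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_nca <- function(nca) {
  stopifnot(is.data.frame(nca), nrow(nca) >= 1)
  descs <- c("tmax", "half_life", "kel", "cmax", "residual", "auc_c",
             "auc_w", "dispro")
  out <- list()
  for (an in unique(nca$analyte)) {
    d <- nca[nca$analyte == an, , drop = FALSE]
    for (v in descs) {
      x <- d[[v]]
      n_missing <- sum(is.na(x))
      x <- x[!is.na(x)]
      row <- data.frame(analyte = an, descriptor = v,
                        n = length(x), n_missing = n_missing,
                        median = NA_real_, iqr_lo = NA_real_,
                        iqr_hi = NA_real_, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_)
      if (length(x)) {
        row$median <- median(x)
        q <- unname(quantile(x, c(0.25, 0.75)))
        row$iqr_lo <- q[1]; row$iqr_hi <- q[2]
        row$mean <- mean(x)
        row$sd <- if (length(x) > 1) sd(x) else 0
        row$min <- min(x); row$max <- max(x)
      }
      out[[paste(an, v)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
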