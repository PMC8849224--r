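# Inter-individual association statistics and pointwise condition
# contrasts. Descriptors are continuous, so the covariate regressions are
# identity-link ordinary least squares; the printed q-values of the source
# study family the three habitual-intake tests together (m = 3).

#' OLS association between a covariate and a kinetic descriptor
#'
#' Ordinary least-squares regression of a descriptor on a subject-level
#' covariate (typically habitual intake in mg/kg/day), with the slope's
#' standard error and two-sided t-test p-value. Pairs with an undefined
#' descriptor are dropped and counted.
#'
#' @param x Covariate values.
#' @param y Descriptor values (may contain `NA`).
#' @param predictor,outcome Labels carried into the result.
#' @return A one-row data frame: `predictor`, `outcome`, `n_used`,
#'   `n_dropped`, `beta`, `se`, `p`.
#' @examples
#' set.seed(1)
#' x <- runif(20, 4, 9)
#' ols_association(x, 4.3 - 0.11 * x + rnorm(20, sd = 0.5),
#'                 predictor = "habitual_mg_kg_day", outcome = "half_life")
#' @export
ols_association <- function(x, y, predictor = "x", outcome = "y") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0) stop("degenerate design: constant covariate", call. = FALSE)
  fit <- summary(lm(y ~ x))$coefficients
  data.frame(predictor = predictor, outcome = outcome,
             n_used = length(x), n_dropped = n_dropped,
             beta = fit[2, 1], se = fit[2, 2], p = fit[2, 4])
}

#' Benjamini--Hochberg false-discovery adjustment
#'
#' `"standard"` is the usual step-up adjustment (monotone, capped at 1).
#' `"rank_scaled"` returns the raw `p * m / rank` values without the
#' step-up monotonicity pass; it is provided because published q-values are
#' sometimes of this form (a rank-scaled value can exceed a larger raw
#' p-value's adjustment, which the standard procedure never allows).
#'
#' @param p P-values in `[0, 1]`.
#' @param mode `"standard"` (default) or `"rank_scaled"`.
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' p <- c(0.002, 0.036, 0.04)
#' bh_adjust(p)                  # 0.006 0.040 0.040
#' bh_adjust(p, "rank_scaled")   # 0.006 0.054 0.040
#' @export
bh_adjust <- function(p, mode = c("standard", "rank_scaled")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "standard") {
    p.adjust(p, method = "BH")
  } else {
    p * length(p) / rank(p, ties.method = "first")
  }
}

#' Pointwise paired condition contrasts over the sampling grid
#'
#' For two conditions sampled on matched grids in the same subjects,
#' performs a paired t-test at every grid position and adjusts the
#' resulting p-values by the standard BH procedure across the grid's tests.
#' Subjects are paired by `subject_id`; samples are paired by their order
#' in time within each subject.
#'
#' @param a,b Profile data frames for one analyte each (columns
#'   `subject_id`, `time_h`, `conc_ug_ml`), with the same subjects and the
#'   same number of samples per subject.
#' @return A data frame, one row per grid position: `sample`,
#'   `time_after_last_dose_h` (from `a`, when present), `mean_diff`
#'   (a minus b), `t`, `df`, `p`, `q`.
#' @examples
#' study <- simulate_study(generate_cohort(6, seed = 2), noise_cv = 0.1)
#' ca <- subset(study, analyte == "caffeine")
#' pointwise_contrast(subset(ca, condition == "caffeine"),
#'                    subset(ca, condition == "placebo"))
#' @export
pointwise_contrast <- function(a, b) {
  mat <- function(d) {
    subs <- sort(unique(d$subject_id))
    rows <- lapply(subs, function(s) {
      x <- d[d$subject_id == s, , drop = FALSE]
      x <- x[order(x$time_h), , drop = FALSE]
      x$conc_ug_ml
    })
    len <- vapply(rows, length, 1L)
    if (length(unique(len)) != 1L) {
      stop("subjects have unequal numbers of samples", call. = FALSE)
    }
    list(m = do.call(rbind, rows), subjects = subs)
  }
  ma <- mat(a); mb <- mat(b)
  if (!identical(ma$subjects, mb$subjects)) {
    stop("conditions contain different subjects", call. = FALSE)
  }
  if (ncol(ma$m) != ncol(mb$m)) {
    stop("conditions sampled on grids of different size", call. = FALSE)
  }
  d <- ma$m - mb$m
  n <- nrow(d)
  if (n < 2) stop("need at least 2 paired subjects", call. = FALSE)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  tstat <- ifelse(s == 0, ifelse(m == 0, 0, Inf * sign(m)),
                  m / (s / sqrt(n)))
  p <- ifelse(s == 0 & m == 0, 1, 2 * pt(-abs(tstat), df = n - 1))
  tald <- rep(NA_real_, ncol(d))
  if (!is.null(a$time_after_last_dose_h)) {
    a1 <- a[a$subject_id == ma$subjects[1], , drop = FALSE]
    a1 <- a1[order(a1$time_h), , drop = FALSE]
    tald <- a1$time_after_last_dose_h
  }
  data.frame(sample = seq_len(ncol(d)),
             time_after_last_dose_h = tald,
             mean_diff = m, t = tstat, df = n - 1, p = p,
             q = bh_adjust(p))
}

#' Habitual-intake association panel
#'
#' Reproduces the study's inter-individual analysis: regressions of the
#' caffeine half-life, the paraxanthine half-life and the
#' paraxanthine/caffeine AUC disproportionality on habitual intake
#' (mg/kg/day), with FDR adjustment across the three tests as one family.
#'
#' @param nca A [nca_table()] data frame.
#' @param cohort A [generate_cohort()] data frame (or cohort CSV) supplying
#'   `subject_id` and `habitual_mg_kg_day`.
#' @param fdr_mode Passed to [bh_adjust()].
#' @return A data frame with one row per test: the [ols_association()]
#'   columns plus `q`. A test with fewer than three defined descriptor
#'   values (sparse grids leave the metabolite half-life undefined in many
#'   subjects) is reported as a flagged row with `NA` estimates, and the
#'   FDR family shrinks to the fitted tests.
#' @export
associations <- function(nca, cohort, fdr_mode = c("standard", "rank_scaled")) {
  fdr_mode <- match.arg(fdr_mode)
  stopifnot(is.data.frame(nca), is.data.frame(cohort))
  pull <- function(an, var) {
    d <- nca[nca$analyte == an, , drop = FALSE]
    d[[var]][match(cohort$subject_id, d$subject_id)]
  }
  x <- cohort$habitual_mg_kg_day
  try_fit <- function(y, outcome) {
    tryCatch(ols_association(x, y, "habitual_mg_kg_day", outcome),
             error = function(e) {
               # sparse grids can leave a descriptor undefined in most
               # subjects; report a flagged row rather than failing
               data.frame(predictor = "habitual_mg_kg_day", outcome = outcome,
                          n_used = sum(!is.na(x) & !is.na(y)),
                          n_dropped = sum(is.na(x) | is.na(y)),
                          beta = NA_real_, se = NA_real_, p = NA_real_)
             })
  }
  res <- rbind(
    try_fit(pull("caffeine", "half_life"), "half_life_caffeine"),
    try_fit(pull("paraxanthine", "half_life"), "half_life_paraxanthine"),
    try_fit(pull("paraxanthine", "dispro"), "auc_ratio_px_ca")
  )
  res$q <- NA_real_
  ok <- !is.na(res$p)
  if (any(ok)) res$q[ok] <- bh_adjust(res$p[ok], fdr_mode)
  res
}
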