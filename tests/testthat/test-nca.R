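test_that("peak detection follows the after-last-dose definition", {
  # strictly decreasing post-dose profile: peak at the first post-dose sample
  prof <- concentration_profile(c(1, 2, 3, 4), c(5, 4, 3, 2))
  pk <- nca_peak(prof, last_dose_time = 0.5)
  expect_equal(pk$cmax, 5)
  expect_equal(pk$tmax, 0.5)
  # ties broken by the earliest time
  tie <- concentration_profile(c(2, 4, 6), c(3, 3, 1))
  expect_equal(nca_peak(tie, 0), list(cmax = 3, tmax = 2))
  # censored samples never carry the peak
  cen <- concentration_profile(c(1, 2), c(9, 1), censored = c(TRUE, FALSE))
  expect_equal(nca_peak(cen, 0)$cmax, 1)
  expect_error(nca_peak(prof, last_dose_time = 10), "no uncensored")
})

test_that("C50 half-life interpolates log-linearly and flags no-crossing", {
  # hand-computed crossing: 2 + 4 * ln2/ln4 = 4 h from peak at 2 h
  two <- concentration_profile(c(2, 6), c(4, 1))
  expect_equal(half_life_c50(two, 0), 2)
  expect_equal(half_life_c50(two, 0, interpolation = "linear"),
               2 + 4 * (4 - 2) / (4 - 1) - 2)
  # constant profile never crosses C50
  flat <- concentration_profile(1:5, rep(2, 5))
  expect_true(is.na(half_life_c50(flat, 0)))
})

test_that("C50 half-life is exact on mono-exponential declines, any grid", {
  set.seed(5)
  for (rep in 1:20) {
    k <- runif(1, 0.05, 0.5)
    tt <- sort(runif(10, 0.5, 4 / k))
    prof <- concentration_profile(tt, 3 * exp(-k * tt))
    hl <- half_life_c50(prof, 0)
    if (!is.na(hl)) expect_equal(hl, log(2) / k, tolerance = 1e-10)
  }
  # anchored value: terminal half-life 4.33 h on a dense grid
  tt <- seq(0.25, 24, by = 0.25)
  prof <- concentration_profile(tt, 5 * exp(-log(2) / 4.33 * tt))
  expect_equal(half_life_c50(prof, 0), 4.33, tolerance = 0.01)
})

test_that("log-linear Kel matches the OLS oracle and flags sparse fits", {
  # noise-free mono-exponential: exact recovery
  tt <- c(2, 4.5, 7, 11)
  prof <- concentration_profile(c(1, tt), c(6, 5 * exp(-0.21 * tt)))
  expect_equal(kel_loglinear(prof, 0), 0.21, tolerance = 1e-10)
  # noisy decline: minus slope of the normal-equations oracle
  set.seed(8)
  tn <- 2:10
  cn <- 5 * exp(-0.3 * tn) * exp(rnorm(9, 0, 0.2))
  pn <- concentration_profile(c(1, tn), c(6, cn))
  expect_equal(kel_loglinear(pn, 0), -ols_oracle(tn, log(cn))$beta,
               tolerance = 1e-10)
  # fewer than 3 post-peak samples: undefined
  few <- concentration_profile(c(1, 2, 3), c(5, 4, 3))
  expect_true(is.na(kel_loglinear(few, 0)))
  expect_equal(kel_from_half_life(4.33), log(2) / 4.33)
})

test_that("trapezoidal AUC is exact for polylines and additive", {
  prof <- concentration_profile(0:3, c(0, 2, 2, 0))
  expect_equal(auc_trapezoid(prof), 4)
  expect_equal(auc_trapezoid(concentration_profile(0:3, rep(0, 4))), 0)
  expect_equal(auc_trapezoid(prof, 0, 1) + auc_trapezoid(prof, 1, 3),
               auc_trapezoid(prof))
  # censored samples enter as zero
  cen <- concentration_profile(0:2, c(1, 1, 1),
                               censored = c(FALSE, TRUE, FALSE))
  expect_equal(auc_trapezoid(cen), 1)
  expect_error(auc_trapezoid(prof, 0, 0.5), "two samples")
})

test_that("dense-grid AUC converges at second order to dose/clearance", {
  p <- pk_params(ka = 3, ke = 0.16, v_parent = 30)
  auc_at <- function(h) {
    tt <- seq(0, 120, by = h)
    auc_trapezoid(concentration_profile(tt, parent_conc(tt, 150, p)))
  }
  truth <- 150 / (p$v_parent * p$ke)   # analytic AUC 0 -> infinity
  expect_equal(auc_at(0.05), truth, tolerance = 1e-3)
  # halving the spacing divides the quadrature error by about four
  err1 <- abs(auc_at(0.4) - truth)
  err2 <- abs(auc_at(0.2) - truth)
  expect_gt(err1 / err2, 3.5)
  expect_lt(err1 / err2, 4.5)
})

test_that("overnight residual reads the baseline sample", {
  prof <- concentration_profile(c(216.75, 218.55), c(0.47, 3.1))
  expect_equal(overnight_residual(prof, 216.75), 0.47)
  cen <- concentration_profile(c(216.75, 218.55), c(0, 3.1),
                               censored = c(TRUE, FALSE))
  expect_equal(overnight_residual(cen, 216.75), 0)
  expect_error(overnight_residual(prof, 200), "baseline")
  # placebo condition: no active dose, zero residual
  pl <- build_schedule("placebo")
  prof_pl <- simulate_profiles(pl, pk_params(), sampling_grid(pl))
  ca <- prof_pl[prof_pl$analyte == "caffeine", ]
  expect_equal(overnight_residual(ca, min(ca$time_h)), 0)
  # noise-free day-10 simulation: residual equals the profile at baseline
  caf <- build_schedule("caffeine")
  g <- sampling_grid(caf)
  prof_ca <- simulate_profiles(caf, pk_params(), g)
  ca10 <- prof_ca[prof_ca$analyte == "caffeine", ]
  expect_equal(overnight_residual(ca10, g$times[1]), ca10$conc_ug_ml[1])
})

test_that("disproportionality handles degenerate denominators", {
  expect_equal(disproportionality(3, 3), 1)
  expect_equal(disproportionality(0, 3), 0)
  expect_true(is.na(disproportionality(3, 0)))
  # smoke value: ratio of typical cohort-mean AUCs
  expect_equal(disproportionality(84.8, 36.1), 2.349, tolerance = 1e-3)
})

test_that("cohort summary matches order statistics and ignores ordering", {
  study <- simulate_study(generate_cohort(8, seed = 21), noise_cv = 0.1,
                          seed = 21)
  nca <- nca_table(study)
  s1 <- summarize_nca(nca)
  s2 <- summarize_nca(nca[rev(seq_len(nrow(nca))), ])
  rownames(s2) <- NULL
  expect_equal(s1[order(s1$analyte, s1$descriptor), ],
               s2[order(s2$analyte, s2$descriptor), ], ignore_attr = TRUE)
  # sort-based oracle for the caffeine half-life median / quartiles
  hl <- sort(nca$half_life[nca$analyte == "caffeine"])
  hl <- hl[!is.na(hl)]
  row <- s1[s1$analyte == "caffeine" & s1$descriptor == "half_life", ]
  med_oracle <- if (length(hl) %% 2) hl[(length(hl) + 1) / 2] else
    mean(hl[length(hl) / 2 + 0:1])
  expect_equal(row$median, med_oracle)
  expect_true(row$iqr_lo >= row$min && row$iqr_hi <= row$max)
  expect_true(row$min <= row$median && row$median <= row$max)
  # degenerate single-subject summary
  one <- summarize_nca(nca[nca$subject_id == "S01", ])
  kel1 <- one[one$analyte == "caffeine" & one$descriptor == "kel", ]
  expect_equal(kel1$sd, 0)
  expect_equal(kel1$median, kel1$mean)
  expect_equal(kel1$iqr_hi - kel1$iqr_lo, 0)
})

test_that("grid censoring bounds the observable peak time", {
  # fast-absorbing parent peaks before the first post-dose sample; the
  # observed Tmax collapses to the grid's earliest latency
  sched <- build_schedule("caffeine")
  g <- sampling_grid(sched)
  prof <- simulate_profiles(sched, pk_params(), g)
  ca <- prof[prof$analyte == "caffeine", ]
  pk <- nca_peak(ca, g$reference)
  expect_equal(pk$tmax, 1.75)
  expect_gte(pk$tmax, min(g$offsets[g$offsets > 0]))
})
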