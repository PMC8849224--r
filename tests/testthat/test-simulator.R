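test_that("multiple-dose profiles superpose single-dose profiles exactly", {
  p <- pk_params()
  full <- build_schedule("caffeine", n_days = 3)
  grid <- seq(0.5, 72, by = 1.5)
  prof <- simulate_profiles(full, p, grid)
  ca <- prof$conc_ug_ml[prof$analyte == "caffeine"]
  px <- prof$conc_ug_ml[prof$analyte == "paraxanthine"]
  ca_sum <- px_sum <- numeric(length(grid))
  for (k in seq_len(nrow(full))) {
    ca_sum <- ca_sum + parent_conc(grid - full$time_h[k], full$dose_mg[k], p)
    px_sum <- px_sum + metabolite_conc(grid - full$time_h[k], full$dose_mg[k], p)
  }
  expect_equal(ca, ca_sum, tolerance = 1e-12)
  expect_equal(px, px_sum, tolerance = 1e-12)
  # two identical doses tau apart: C(t) = C1(t) + C1(t - tau)
  s2 <- build_schedule("caffeine", n_days = 2, dose_offsets_h = 1)
  pr2 <- simulate_profiles(s2, p, grid)
  one <- parent_conc(grid - 1, 150, p) + parent_conc(grid - 25, 150, p)
  expect_equal(pr2$conc_ug_ml[pr2$analyte == "caffeine"], one,
               tolerance = 1e-12)
})

test_that("day-10 pre-dose residual matches the geometric-series closed form", {
  p <- pk_params()
  sched <- build_schedule("caffeine")
  grid <- sampling_grid(sched)
  tb <- grid$times[1]                       # pre-first-dose baseline, day 10
  prof <- simulate_profiles(sched, p, grid)
  offs <- attr(sched, "dose_offsets_h")
  r <- function(l) exp(-24 * l)
  geom <- function(l, lag0) exp(-l * lag0) * (1 - r(l)^9) / (1 - r(l))
  ca_oracle <- 0
  px_oracle <- 0
  for (off in offs) {
    lag0 <- tb - (8 * 24 + off)             # lag from the day-9 dose
    A <- 150 * p$ka / p$v_parent / (p$ka - p$ke)
    ca_oracle <- ca_oracle + A * (geom(p$ke, lag0) - geom(p$ka, lag0))
    B <- p$fm * 150 * p$ka * p$ke / p$v_metab
    cfs <- c(1 / ((p$ke - p$ka) * (p$km - p$ka)),
             1 / ((p$ka - p$ke) * (p$km - p$ke)),
             1 / ((p$ka - p$km) * (p$ke - p$km)))
    px_oracle <- px_oracle + B * (cfs[1] * geom(p$ka, lag0) +
                                  cfs[2] * geom(p$ke, lag0) +
                                  cfs[3] * geom(p$km, lag0))
  }
  expect_equal(prof$conc_ug_ml[prof$analyte == "caffeine"][1], ca_oracle,
               tolerance = 1e-9)
  expect_equal(prof$conc_ug_ml[prof$analyte == "paraxanthine"][1], px_oracle,
               tolerance = 1e-9)
})

test_that("morning residual accumulates monotonically toward steady state", {
  p <- pk_params()
  sched <- build_schedule("caffeine", n_days = 10)
  # sample 15 min before each day's first capsule
  pre_dose <- (0:9) * 24 + 0.5
  prof <- simulate_profiles(sched, p, pre_dose)
  for (an in c("caffeine", "paraxanthine")) {
    res <- prof$conc_ug_ml[prof$analyte == an]
    inc <- diff(res)
    expect_true(all(inc >= 0))
    expect_true(all(diff(inc) <= 1e-9))     # increments shrink day over day
    # geometric tail: the remaining gap to steady state is bounded by the
    # last increment times r / (1 - r) with r the daily carry-over factor
    l <- if (an == "caffeine") p$ke else min(p$ke, p$km)
    r <- exp(-24 * l)
    gap_bound <- inc[length(inc)] * r / (1 - r)
    expect_lt(gap_bound, 0.01 * res[10])    # day 10 is within 1% of steady state
  }
})

test_that("deprivation clears caffeine but not paraxanthine", {
  p <- pk_params()
  caf <- build_schedule("caffeine")
  dep <- build_schedule("deprivation")
  prof_c <- simulate_profiles(caf, p, sampling_grid(caf))
  prof_d <- simulate_profiles(dep, p, sampling_grid(dep))
  post <- prof_c$time_after_last_dose_h > 0
  cmax_ca <- max(prof_c$conc_ug_ml[prof_c$analyte == "caffeine" & post])
  cmax_px <- max(prof_c$conc_ug_ml[prof_c$analyte == "paraxanthine" & post])
  frac_ca <- prof_d$conc_ug_ml[prof_d$analyte == "caffeine"] / cmax_ca
  frac_px <- prof_d$conc_ug_ml[prof_d$analyte == "paraxanthine"] / cmax_px
  expect_true(all(frac_ca < 0.05))
  expect_true(all(frac_px > frac_ca))
})

test_that("cohort generation is reproducible and respects the design bounds", {
  a <- generate_cohort(20, seed = 11)
  b <- generate_cohort(20, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$habitual_mg_day >= 300 & a$habitual_mg_day <= 600))
  expect_true(all(a$weight_kg > 40))
  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(5, config = cohort_config(cv_ke = -1)))
  # enlarging the cohort never reshuffles earlier subjects' draws
  big <- generate_cohort(25, seed = 11)
  expect_equal(big$weight_kg[1:20], a$weight_kg)
  expect_equal(big$habitual_mg_day[1:20], a$habitual_mg_day)
})

test_that("covariate slopes act on half-lives exactly when noise is off", {
  cfg <- cohort_config(cv_ke = 0, cv_km = 0, cv_v = 0,
                       beta_parent = -0.11, beta_metab = -0.14)
  ch <- generate_cohort(20, seed = 3, config = cfg)
  x <- ch$habitual_mg_kg_day
  expect_equal(log(2) / ch$ke, 4.33 - 0.11 * (x - mean(x)), tolerance = 1e-12)
  expect_equal(log(2) / ch$km, 7.79 - 0.14 * (x - mean(x)), tolerance = 1e-12)
})

test_that("assay noise has the requested CV and censors below the floor", {
  prof <- concentration_profile(1:4, c(2, 1, 0.5, 0.2))
  expect_equal(apply_noise(prof, cv = 0, lloq = 0.04, seed = 1), prof)
  low <- concentration_profile(1:11, rep(0.01, 11))
  cens <- apply_noise(low, cv = 0, lloq = 0.04, seed = 1)
  expect_true(all(cens$censored))
  expect_true(all(cens$conc_ug_ml == 0))
  # Monte-Carlo check of the multiplicative error model
  big <- concentration_profile(seq_len(10000), rep(1, 10000))
  noisy <- apply_noise(big, cv = 0.1, lloq = 0, seed = 99)
  emp_cv <- sd(noisy$conc_ug_ml) / mean(noisy$conc_ug_ml)
  expect_lt(abs(emp_cv - 0.1), 0.005)
  expect_lt(abs(mean(noisy$conc_ug_ml) - 1), 0.01)  # unit-mean multiplier
})
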