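# caffpx

Simulation and non-compartmental analysis of salivary caffeine and
paraxanthine kinetics under daily dosing.

Most people take caffeine every day, yet most caffeine pharmacokinetics is
single-dose. Under a conventional regimen — 150 mg three times a day
(45 min, 4 h and 8 h after waking) for ten days — neither caffeine nor its
primary metabolite paraxanthine (formed from ~84% of the dose via CYP1A2,
eliminated more slowly than its parent) is fully cleared overnight, and
paraxanthine accumulates. `caffpx` provides, for researchers who study
this regimen or want to plan one:

* a **seeded simulator** of the three-condition study design (daily
  caffeine, acute deprivation sampled 24–43 h after the last dose,
  placebo) for cohorts with realistic weights, habitual intake and
  inter-individual kinetic variability, built on the closed-form
  gut → parent → metabolite cascade

  C(t) = (D/Vₚ) · kₐ/(kₐ−kₑ) · (e^(−kₑt) − e^(−kₐt))

  and its triple-exponential metabolite analogue, with exact multiple-dose
  superposition, log-normal assay noise and LLOQ censoring;
* the **non-compartmental descriptors** used in saliva studies of this
  design: Cmax/Tmax after the last dose, the C50 half-life (time from the
  peak to the interpolated crossing of half the peak), the log-linear
  elimination rate Kel, trapezoidal AUC over the sampled windows, the
  overnight residual, and the paraxanthine/caffeine AUC
  disproportionality;
* **inter-individual statistics**: OLS regressions of descriptors on
  habitual intake (mg/kg/day) with Benjamini–Hochberg FDR control, and
  pointwise paired condition contrasts along the sampling grid;
* a **reproducible pipeline** (CSV in/out, JSON/YAML configuration, run
  manifest) plus a thin command-line front end (`inst/cli/caffpx.R`).

## Worked example

```r
library(caffpx)
res <- run_pipeline(default_config(out_dir = "caffpx-run"))
#> [caffpx] cohort: 20 subjects (seed 1)
#> [caffpx] simulate: 1320 samples, 566 censored
#> [caffpx] nca: 40 subject x analyte rows, 20 undefined half-lives
#> [caffpx] stats: 3 association tests (1 undefined), min q = 0.67
#> [caffpx] stats: 22 pointwise contrasts
#> [caffpx] report: outputs in caffpx-run

subset(res$nca_summary, analyte == "caffeine")[, c("descriptor", "median", "mean", "sd")]
#>   descriptor median  mean    sd
#>         tmax   1.75  1.84  0.40
#>    half_life   4.04  4.11  1.06
#>          kel   0.17  0.17  0.04
#>         cmax   4.78  5.05  1.29
#>     residual   0.44  0.47  0.28
#>        auc_c  51.14 55.85 13.22
#>        auc_w   0.79  0.91  0.92
```

Reading this: every subject's observed caffeine peak time is censored at
the grid's earliest post-dose sample (1.75 h, the design's 105-min minimum
latency); the C50 half-life centres near 4 h; the morning pre-dose
residual (~0.4–0.5 µg/ml here) is the caffeine still carried overnight on
day 10; and the deprivation-window AUC (`auc_w`) is near zero for caffeine
while remaining large for paraxanthine (`res$nca_summary`, paraxanthine
rows) — the metabolite is still present after 24–43 h of abstinence. The
paraxanthine half-life is undefined for all 20 subjects (`n_missing`):
on an 11-sample grid ending ~11 h post dose, a compound with a ~8 h
terminal half-life peaking 3–5 h post dose does not fall to half its peak
inside the window. The association panel (`res$associations`) regresses
the defined descriptors on habitual intake and reports slope, p and
FDR-adjusted q per test.

Pointwise contrasts show where conditions separate, e.g. at the baseline
sample caffeine vs placebo differs by the overnight residual:

```r
head(res$contrasts[res$contrasts$analyte == "caffeine",
                   c("time_after_last_dose_h", "mean_diff", "t", "q")], 2)
#>  time_after_last_dose_h mean_diff        t            q
#>                   -7.25      0.47  7.49389 4.362601e-07
#>                   -5.45      3.10 20.18169 7.429904e-14
```

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/caffpx.R run-all --seed 1 --out caffpx-run
```

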