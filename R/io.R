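# CSV interchange and run configuration. CSV is the single exchange
# format: the data are small and auditability matters.

PROFILE_COLS <- c("subject_id", "condition", "analyte", "time_h",
                  "time_after_last_dose_h", "conc_ug_ml", "censored")

#' Write / read concentration profiles
#'
#' One row per sample: `subject_id`, `condition`
#' (`caffeine|deprivation|placebo`), `analyte` (`caffeine|paraxanthine`),
#' `time_h` (since study start), `time_after_last_dose_h`, `conc_ug_ml`,
#' `censored` (0/1). Values and censoring flags round-trip losslessly.
#' On input, concentrations may be given in ng/ml either via
#' `units = "ng/ml"` or a per-file `conc_units` column; they are stored as
#' ug/ml. Files with missing columns, negative concentrations or duplicate
#' (subject, condition, analyte, time) keys are rejected with a row-level
#' message.
#'
#' @param profiles A long profile data frame ([simulate_study()] shape).
#' @param path CSV file path.
#' @param units Input concentration units, `"ug/ml"` (default) or
#'   `"ng/ml"`.
#' @return `read_profiles()` returns the validated data frame;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(all(PROFILE_COLS %in% names(profiles)))
  out <- profiles[, PROFILE_COLS]
  out$censored <- as.integer(out$censored)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path, units = c("ug/ml", "ng/ml")) {
  units <- match.arg(units)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PROFILE_COLS, names(d))
  if (length(missing_cols)) {
    stop("profile file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(d$conc_units)) {
    scale <- ifelse(d$conc_units == "ng/ml", 1e-3,
                    ifelse(d$conc_units == "ug/ml", 1, NA_real_))
    if (anyNA(scale)) {
      stop("unknown 'conc_units' value at row ",
           which(is.na(scale))[1], call. = FALSE)
    }
    d$conc_ug_ml <- d$conc_ug_ml * scale
    d$conc_units <- NULL
  } else if (units == "ng/ml") {
    d$conc_ug_ml <- d$conc_ug_ml * 1e-3
  }
  bad <- which(!is.finite(d$conc_ug_ml) | d$conc_ug_ml < 0)
  if (length(bad)) {
    stop("negative or non-finite concentration at row ", bad[1], call. = FALSE)
  }
  key <- paste(d$subject_id, d$condition, d$analyte, d$time_h)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (subject, condition, analyte, time) key at row ", dup[1],
         call. = FALSE)
  }
  d$censored <- as.logical(d$censored)
  d[, PROFILE_COLS]
}

#' Write / read a simulated cohort
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param path CSV file path.
#' @return `read_cohort()` returns the data frame; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "weight_kg", "habitual_mg_day", "habitual_mg_kg_day",
            "ka", "ke", "km", "fm", "v_parent", "v_metab")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Default run configuration
#'
#' Every field documents and reproduces the study design: 20 subjects,
#' 150 mg caffeine three times a day (45 min, 4 h, 8 h after waking) for
#' ten days, eleven saliva samples on day 10, deprivation sampled 24--43 h
#' after the last active dose, assay noise CV 10% with LLOQ floors 0.04
#' (caffeine) and 0.02 (paraxanthine) ug/ml.
#'
#' @param ... Named overrides of top-level fields (nested lists are merged
#'   field-wise).
#' @return A named list of class `caffpx_config`.
#' @examples
#' cfg <- default_config(n_subjects = 5, noise_cv = 0)
#' cfg$population$t12_parent
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_subjects = 20L,
    n_days = 10L,
    dose_mg = 150,
    dose_offsets_h = c(0.75, 4, 8),
    wake_interval_h = 24,
    deprivation_active_days = 9L,
    conditions = c("caffeine", "deprivation", "placebo"),
    grid = list(n_samples = 11L, spacing_h = 1.8,
                deprivation_window_h = c(24, 43)),
    population = cohort_config(),
    noise_cv = 0.1,
    interpolation = "log",
    kel_method = "regression",
    fdr_mode = "standard",
    out_dir = "caffpx-run"
  )
  over <- list(...)
  if (length(over)) cfg <- modifyList(cfg, over)
  validate_config(cfg)
}

#' Read a run configuration from JSON or YAML
#'
#' Fields present in the file override the defaults of [default_config()];
#' everything else keeps its documented default.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  )
  cfg <- modifyList(unclass(default_config()), over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_days >= 1, cfg$dose_mg >= 0,
            cfg$noise_cv >= 0, cfg$grid$n_samples >= 2)
  if (!all(cfg$conditions %in% c("caffeine", "deprivation", "placebo"))) {
    stop("unknown condition in config", call. = FALSE)
  }
  if (!"caffeine" %in% cfg$conditions) {
    stop("config must include the caffeine condition", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  # population entries may arrive partially specified from a config file
  cfg$population <- modifyList(cohort_config(), cfg$population)
  structure(cfg, class = "caffpx_config")
}
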