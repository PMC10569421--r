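#' Study configuration for the AF association scan
#'
#' Bundles every tunable parameter of the scan: the study period, eligibility
#' thresholds, window width around the index date, reporting cap, bootstrap
#' settings and the master random seed. Defaults follow the design of the
#' source case-control study of new-onset atrial fibrillation in UK primary
#' and secondary care (study period 1998-01-01 to 2016-05-31, adults with at
#' least one year of registration, five-year windows, the leading 100
#' conditions, 2,000 balanced-bootstrap replicates).
#'
#' @param study_start,study_end Calendar bounds of the study period
#'   (`Date` or `"YYYY-MM-DD"`).
#' @param min_age Minimum age in years at study entry.
#' @param min_registration_years Required registration time before study
#'   entry, in years.
#' @param window_years Half-width, in years, of the pre/post windows around
#'   the index date.
#' @param top_n Number of leading conditions reported per stratum.
#' @param bootstrap_B Number of balanced-bootstrap replicates.
#' @param ci_level Two-sided confidence level for percentile intervals.
#' @param min_case_patients Conditions observed in fewer case patients than
#'   this are dropped (small-cell convention for UK EHR outputs).
#' @param age_match_tolerance_years Maximum birth-year difference allowed
#'   between a case and its control.
#' @param match_ratio Controls matched per case.
#' @param continuity_correction Constant added to both counts when a
#'   condition has zero control patients.
#' @param count_mode `"patients"` counts each patient at most once per
#'   condition and stratum (the default estimand); `"visits"` counts every
#'   in-window event.
#' @param rng_seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @param verbose Emit stage-count messages during a pipeline run.
#'
#' @return An object of class `study_config` (a validated named list).
#' @examples
#' cfg <- study_config(rng_seed = 42)
#' cfg$window_years
#' @export
study_config <- function(study_start = "1998-01-01",
                         study_end = "2016-05-31",
                         min_age = 18L,
                         min_registration_years = 1,
                         window_years = 5,
                         top_n = 100L,
                         bootstrap_B = 2000L,
                         ci_level = 0.95,
                         min_case_patients = 5L,
                         age_match_tolerance_years = 0L,
                         match_ratio = 1L,
                         continuity_correction = 0.5,
                         count_mode = c("patients", "visits"),
                         rng_seed = 1L,
                         verbose = TRUE) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    min_age = as.integer(min_age),
    min_registration_years = as.numeric(min_registration_years),
    window_years = as.numeric(window_years),
    top_n = as.integer(top_n),
    bootstrap_B = as.integer(bootstrap_B),
    ci_level = as.numeric(ci_level),
    min_case_patients = as.integer(min_case_patients),
    age_match_tolerance_years = as.integer(age_match_tolerance_years),
    match_ratio = as.integer(match_ratio),
    continuity_correction = as.numeric(continuity_correction),
    count_mode = match.arg(count_mode),
    rng_seed = as.integer(rng_seed),
    verbose = isTRUE(verbose)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      cfg$study_start >= cfg$study_end)
    stopf("study_start must precede study_end")
  if (cfg$window_years <= 0) stopf("window_years must be > 0")
  if (cfg$top_n < 1L) stopf("top_n must be >= 1")
  if (cfg$bootstrap_B < 2L) stopf("bootstrap_B must be >= 2")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stopf("ci_level must lie strictly between 0 and 1")
  if (cfg$min_case_patients < 0L) stopf("min_case_patients must be >= 0")
  if (cfg$match_ratio < 1L) stopf("match_ratio must be >= 1")
  if (cfg$continuity_correction <= 0)
    stopf("continuity_correction must be > 0")
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("AF association-scan configuration\n")
  cat(sprintf("  study period     : %s to %s\n", x$study_start, x$study_end))
  cat(sprintf("  eligibility      : age >= %d, registration >= %g y\n",
              x$min_age, x$min_registration_years))
  cat(sprintf("  windows          : %g y pre / %g y post index\n",
              x$window_years, x$window_years))
  cat(sprintf("  matching         : 1:%d, birth-year tolerance %d y\n",
              x$match_ratio, x$age_match_tolerance_years))
  cat(sprintf("  reporting        : top %d per stratum, min %d case patients\n",
              x$top_n, x$min_case_patients))
  cat(sprintf("  bootstrap        : B = %d, %g%% percentile CIs\n",
              x$bootstrap_B, 100 * x$ci_level))
  cat(sprintf("  counting mode    : %s\n", x$count_mode))
  cat(sprintf("  rng seed         : %d\n", x$rng_seed))
  invisible(x)
}

log_stage <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

# the four analysis strata: care setting x window period
strata_keys <- function() {
  data.frame(
    setting = rep(c("primary", "secondary"), each = 2L),
    period = rep(c("pre", "post"), times = 2L),
    stringsAsFactors = FALSE
  )
}

stratum_label <- function(setting, period) paste(setting, period, sep = "_")
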