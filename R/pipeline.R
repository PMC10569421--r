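#' EHR-wide association scan around new-onset AF
#'
#' The core fitting function: applies eligibility, identifies incident AF
#' cases, samples age/sex-matched controls under risk-set constraints,
#' counts condition occurrence in the pre/post windows for both care
#' settings, computes frequency ratios, ranks the leading conditions,
#' attaches balanced-bootstrap percentile confidence intervals and disease
#' groups. Deterministic given `config$rng_seed` and the inputs; storage
#' order of the input rows does not affect the result.
#'
#' @param patients Patient table ([read_patients()] format).
#' @param events Event table ([read_events()] format).
#' @param af_codes AF phenotype [code_list()]; default the shipped list.
#' @param config A [study_config()].
#' @param scheme A [disease_groups()] scheme.
#' @param compute_ci Compute bootstrap CIs (set `FALSE` to skip the most
#'   expensive stage).
#' @param ci_codes `"ranked"` computes CIs for the reported leading
#'   conditions only (the default, bounding compute); `"all"` for every
#'   condition surviving the count threshold.
#' @param code_labels Optional named character vector mapping codes to
#'   display labels.
#' @return An object of class `ehrwas_scan`: list with the ranked `results`
#'   table (columns `stratum`, `rank`, `code`, `vocabulary`, `label`,
#'   `n_case`, `n_control`, `pct_case`, `pct_control`, `freq_ratio`,
#'   `ci_low`, `ci_high`, `disease_group`, `zero_control_flag`), the
#'   matched `pairs`, the `cases`, stage `counts` and the `config`.
#' @examples
#' sim <- simulate_ehr(synth_config(n_patients = 400, af_annual_hazard = 0.05,
#'                                  rng_seed = 1))
#' cfg <- study_config(min_case_patients = 1, bootstrap_B = 50,
#'                     rng_seed = 1, verbose = FALSE)
#' fit <- ehrwas_scan(sim$patients, sim$events, config = cfg)
#' head(fit$results)
#' @export
ehrwas_scan <- function(patients, events, af_codes = af_code_list(),
                        config = study_config(), scheme = disease_groups(),
                        compute_ci = TRUE, ci_codes = c("ranked", "all"),
                        code_labels = NULL) {
  ci_codes <- match.arg(ci_codes)
  patients <- validate_patients(patients)
  events <- validate_events(events)

  eligible <- apply_eligibility(patients, events, af_codes, config)
  log_stage(config, "eligible patients: %d of %d", nrow(eligible),
            nrow(patients))
  cases <- identify_cases(eligible, events, af_codes, config)
  log_stage(config, "incident AF cases: %d", nrow(cases))
  if (!nrow(cases))
    stopf("no incident AF cases found: nothing to match or scan")
  pairs <- match_controls(cases, eligible, events, af_codes, config)
  log_stage(config, "matched pairs: %d", nrow(pairs))
  if (!nrow(pairs))
    stopf("no matched pairs could be formed: cannot run the scan")

  counts <- count_conditions(pairs, events, config, af_codes)
  if (!nrow(counts))
    stopf("no condition passes the min_case_patients threshold")
  res <- frequency_ratio(counts, config)
  ranked <- rank_leading(res, config)

  if (compute_ci) {
    target <- if (ci_codes == "ranked") ranked else res
    target <- bootstrap_cis(pairs, events, target, config, af_codes)
    m <- match(paste(ranked$setting, ranked$period, ranked$code),
               paste(target$setting, target$period, target$code))
    ranked$ci_low <- target$ci_low[m]
    ranked$ci_high <- target$ci_high[m]
  } else {
    ranked$ci_low <- NA_real_
    ranked$ci_high <- NA_real_
  }

  ranked$disease_group <- classify_code(ranked$code, ranked$vocabulary,
                                        scheme, warn_unmatched = FALSE)
  ranked$label <- if (is.null(code_labels)) ranked$code else
    ifelse(is.na(code_labels[ranked$code]), ranked$code,
           code_labels[ranked$code])
  ranked$stratum <- stratum_label(ranked$setting, ranked$period)
  cols <- c("stratum", "setting", "period", "rank", "code", "vocabulary",
            "label", "n_case", "n_control", "pct_case", "pct_control",
            "freq_ratio", "ci_low", "ci_high", "disease_group",
            "zero_control_flag")
  ranked <- ranked[, cols]

  structure(list(
    results = ranked,
    pairs = pairs,
    cases = cases,
    counts = c(patients = nrow(patients), eligible = nrow(eligible),
               cases = nrow(cases), pairs = nrow(pairs)),
    config = config,
    scheme = scheme
  ), class = "ehrwas_scan")
}

#' @export
print.ehrwas_scan <- function(x, ...) {
  cat("EHR-wide association scan (new-onset AF)\n")
  cat(sprintf("  patients %d -> eligible %d -> cases %d -> matched pairs %d\n",
              x$counts["patients"], x$counts["eligible"], x$counts["cases"],
              x$counts["pairs"]))
  tab <- table(x$results$stratum)
  cat(sprintf("  ranked conditions: %s\n",
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.ehrwas_scan <- function(object, n = 5L, ...) {
  cat("EHR-wide association scan (new-onset AF)\n")
  print(object$config)
  for (s in unique(object$results$stratum)) {
    r <- object$results[object$results$stratum == s, , drop = FALSE]
    cat(sprintf("\n%s: %d conditions; leading %d by frequency ratio:\n",
                s, nrow(r), min(n, nrow(r))))
    top <- utils::head(r[, c("rank", "code", "n_case", "n_control",
                             "freq_ratio", "ci_low", "ci_high",
                             "disease_group")], n)
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
as.data.frame.ehrwas_scan <- function(x, ...) x$results

#' @export
plot.ehrwas_scan <- function(x, file_prefix = NULL,
                             formats = c("svg", "png"), ...) {
  if (is.null(file_prefix)) file_prefix <- file.path(tempdir(), "iris")
  invisible(render_iris(x$results, file_prefix, x$scheme, formats))
}

#' Write the four ranked result tables
#'
#' One CSV per stratum (`ranked_<setting>_<period>.csv`) with the standard
#' result columns; output is byte-identical across runs for identical
#' scans.
#'
#' @param scan An [ehrwas_scan()] object.
#' @param dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_ranked_tables <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- scan$results
  cols <- c("stratum", "rank", "code", "vocabulary", "label", "n_case",
            "n_control", "pct_case", "pct_control", "freq_ratio", "ci_low",
            "ci_high", "disease_group", "zero_control_flag")
  files <- character(0)
  for (s in unique(res$stratum)) {
    path <- file.path(dir, sprintf("ranked_%s.csv", s))
    utils::write.csv(res[res$stratum == s, cols], path, row.names = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}

#' Run the full pipeline and write its artefacts
#'
#' Convenience wrapper around [ehrwas_scan()]: fits the scan, writes one
#' ranked table per stratum and the iris-plot figure (SVG and PNG) into
#' `out_dir`.
#'
#' @inheritParams ehrwas_scan
#' @param out_dir Output directory.
#' @return The `ehrwas_scan` object, invisibly.
#' @export
run_pipeline <- function(patients, events, af_codes = af_code_list(),
                         config = study_config(),
                         scheme = disease_groups(), out_dir = ".") {
  fit <- ehrwas_scan(patients, events, af_codes, config, scheme)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ranked_tables(fit, out_dir)
  render_iris(fit$results, file.path(out_dir, "iris"), scheme)
  log_stage(config, "wrote ranked tables and iris plot to %s", out_dir)
  invisible(fit)
}
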