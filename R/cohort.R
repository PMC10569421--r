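#' Apply cohort eligibility rules
#'
#' Study entry is the later of `reg_start + min_registration_years` and
#' `study_start`. A patient is eligible when their dates are valid, entry
#' falls on or before both `study_end` and `reg_end`, they are alive at
#' entry, they are at least `min_age` years old at entry (computed on birth
#' year), and they have no AF-phenotype code strictly before entry.
#'
#' @param patients Patient table ([read_patients()] format).
#' @param events Event table ([read_events()] format).
#' @param af_codes AF phenotype [code_list()].
#' @param config A [study_config()].
#' @return The eligible subset of `patients`, with an `entry_date` column
#'   appended.
#' @export
apply_eligibility <- function(patients, events, af_codes, config) {
  if (!nrow(patients)) {
    patients$entry_date <- as.Date(numeric(0), origin = "1970-01-01")
    return(patients)
  }
  entry <- pmax(patients$reg_start + year_days(config$min_registration_years),
                config$study_start)
  age_at_entry <- as.integer(format(entry, "%Y")) - patients$birth_year
  af_first <- first_phenotype_date(events, af_codes)
  af_before_entry <- !is.na(match(patients$patient_id, names(af_first))) &
    af_first[patients$patient_id] < entry
  af_before_entry[is.na(af_before_entry)] <- FALSE

  keep <- entry <= config$study_end &
    entry <= patients$reg_end &
    (is.na(patients$death_date) | patients$death_date > entry) &
    age_at_entry >= config$min_age &
    !af_before_entry

  out <- patients[keep, , drop = FALSE]
  out$entry_date <- entry[keep]
  rownames(out) <- NULL
  out
}

#' Identify incident AF cases and their index dates
#'
#' The index date is the earliest AF-phenotype event between study entry
#' and the end of observation (`min(reg_end, study_end)`). ICD-10 entries of
#' the phenotype match by prefix (`I48` captures `I48.0`, ...); Read entries
#' match verbatim.
#'
#' @param eligible Eligible patients from [apply_eligibility()].
#' @param events Event table.
#' @param af_codes AF phenotype [code_list()].
#' @param config A [study_config()].
#' @return Data frame `patient_id`, `index_date`, sorted by
#'   `(index_date, patient_id)`.
#' @export
identify_cases <- function(eligible, events, af_codes, config) {
  empty <- data.frame(patient_id = character(0),
                      index_date = as.Date(numeric(0), origin = "1970-01-01"),
                      stringsAsFactors = FALSE)
  if (!nrow(eligible)) return(empty)
  af <- events[matches_code_list(events, af_codes), , drop = FALSE]
  m <- match(af$patient_id, eligible$patient_id)
  ok <- !is.na(m)
  af <- af[ok, , drop = FALSE]; m <- m[ok]
  in_obs <- af$event_date >= eligible$entry_date[m] &
    af$event_date <= pmin(eligible$reg_end[m], config$study_end)
  af <- af[in_obs, , drop = FALSE]
  if (!nrow(af)) return(empty)
  first <- tapply(af$event_date, af$patient_id, min)
  cases <- data.frame(patient_id = names(first),
                      index_date = as.Date(as.vector(first),
                                           origin = "1970-01-01"),
                      stringsAsFactors = FALSE)
  cases <- cases[order(cases$index_date, cases$patient_id), , drop = FALSE]
  rownames(cases) <- NULL
  cases
}

#' Incidence-density matched control sampling
#'
#' Cases are processed in ascending index-date order. For each, the risk set
#' holds eligible patients of the same sex whose birth year differs by at
#' most `age_match_tolerance_years`, who are under observation (entered and
#' registered) and alive at the case's index date, have no AF code on or
#' before it, are not the case itself and have not been used as a control
#' before. `match_ratio` controls are sampled uniformly without replacement
#' (the same person never serves as a control twice; a sampled control may
#' still become a case later, after its own onset). Cases whose risk set is
#' too small are dropped, with a warning when more than 1% go unmatched.
#'
#' @param cases Output of [identify_cases()].
#' @param eligible Output of [apply_eligibility()].
#' @param events Event table (for AF-freeness at the index date).
#' @param af_codes AF phenotype [code_list()].
#' @param config A [study_config()]; the sampling stream derives from
#'   `config$rng_seed`.
#' @return Data frame of matched pairs: `case_id`, `control_id`,
#'   `index_date`, `case_sex`, `age_difference_years`.
#' @export
match_controls <- function(cases, eligible, events, af_codes, config) {
  af_first <- first_phenotype_date(events, af_codes)
  cand_af <- af_first[match(eligible$patient_id, names(af_first))]
  cases <- cases[order(cases$index_date, cases$patient_id), , drop = FALSE]

  # candidate lookup by (sex, birth_year) keeps each risk-set filter small
  cand_order <- order(eligible$patient_id)
  cand <- eligible[cand_order, , drop = FALSE]
  cand_af <- cand_af[cand_order]
  cell_of <- split(seq_len(nrow(cand)), paste(cand$sex, cand$birth_year))

  case_sex <- cand$sex[match(cases$patient_id, cand$patient_id)]
  case_by <- cand$birth_year[match(cases$patient_id, cand$patient_id)]
  used <- new.env(parent = emptyenv())
  tol <- config$age_match_tolerance_years
  k <- config$match_ratio

  out_case <- out_control <- character(0)
  out_index <- as.Date(numeric(0), origin = "1970-01-01")
  out_sex <- character(0); out_dy <- integer(0)
  n_unmatched <- 0L

  with_seed(stage_seed(config$rng_seed, 4L), {
    for (i in seq_len(nrow(cases))) {
      idx_date <- cases$index_date[i]
      cells <- paste(case_sex[i], (case_by[i] - tol):(case_by[i] + tol))
      rows <- unlist(cell_of[cells], use.names = FALSE)
      if (length(rows)) {
        ok <- cand$patient_id[rows] != cases$patient_id[i] &
          cand$entry_date[rows] <= idx_date &
          cand$reg_end[rows] >= idx_date &
          idx_date <= config$study_end &
          (is.na(cand$death_date[rows]) | cand$death_date[rows] > idx_date) &
          (is.na(cand_af[rows]) | cand_af[rows] > idx_date)
        rows <- rows[ok]
        rows <- rows[!vapply(cand$patient_id[rows], exists, logical(1),
                             envir = used, inherits = FALSE)]
      }
      if (length(rows) < k) {
        n_unmatched <- n_unmatched + 1L
        next
      }
      rows <- rows[order(cand$patient_id[rows])]
      pick <- rows[sample.int(length(rows), k)]
      for (id in cand$patient_id[pick]) assign(id, TRUE, envir = used)
      out_case <- c(out_case, rep(cases$patient_id[i], k))
      out_control <- c(out_control, sort(cand$patient_id[pick]))
      out_index <- c(out_index, rep(idx_date, k))
      out_sex <- c(out_sex, rep(case_sex[i], k))
      out_dy <- c(out_dy,
                  cand$birth_year[pick][order(cand$patient_id[pick])] -
                    case_by[i])
    }
  })

  if (n_unmatched > 0L) {
    log_stage(config, "dropped %d unmatched case(s)", n_unmatched)
    if (n_unmatched > 0.01 * max(nrow(cases), 1L))
      warning(sprintf("%d of %d cases (>1%%) could not be matched",
                      n_unmatched, nrow(cases)), call. = FALSE)
  }
  data.frame(case_id = out_case, control_id = out_control,
             index_date = out_index, case_sex = out_sex,
             age_difference_years = out_dy, stringsAsFactors = FALSE)
}
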