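# hand-rolled fixture builders and brute-force oracles, deliberately
# independent of the package's vectorised implementations

mk_patients <- function(id, sex = "F", birth_year = 1940,
                        reg_start = "1990-01-01", reg_end = "2016-05-31",
                        death_date = NA) {
  data.frame(patient_id = id, sex = sex, birth_year = birth_year,
             reg_start = as.Date(reg_start), reg_end = as.Date(reg_end),
             death_date = as.Date(death_date),
             stringsAsFactors = FALSE)
}

mk_events <- function(id, date, code, vocabulary = "ICD10",
                      setting = "secondary") {
  data.frame(patient_id = id, event_date = as.Date(date), code = code,
             vocabulary = vocabulary, setting = setting,
             stringsAsFactors = FALSE)
}

test_af_codes <- function() {
  code_list("af_test", c("I48", "G573.00"), c("ICD10", "READ2"))
}

window_days_of <- function(config) as.integer(round(config$window_years * 365.25))

# event-by-event date comparison, one loop, no vectorisation
oracle_window <- function(events, index_date, config, period) {
  W <- window_days_of(config)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    d <- events$event_date[i]
    keep[i] <- if (period == "pre") {
      d >= index_date - W && d < index_date
    } else {
      d > index_date && d <= index_date + W
    }
  }
  events[keep, , drop = FALSE]
}

# quadruple loop over strata, pairs, roles and events; patient-level counts
oracle_counts <- function(pairs, events, config, af_codes = NULL) {
  W <- window_days_of(config)
  is_af <- if (is.null(af_codes)) rep(FALSE, nrow(events)) else {
    af <- rep(FALSE, nrow(events))
    for (i in seq_len(nrow(events))) {
      for (j in seq_len(nrow(af_codes$entries))) {
        e <- af_codes$entries[j, ]
        if (e$vocabulary == "ICD10" && events$vocabulary[i] == "ICD10" &&
            startsWith(events$code[i], e$code)) af[i] <- TRUE
        if (e$vocabulary == "READ2" && events$vocabulary[i] == "READ2" &&
            events$code[i] == e$code) af[i] <- TRUE
      }
    }
    af
  }
  out <- list()
  for (setting in c("primary", "secondary")) {
    for (period in c("pre", "post")) {
      tally <- list()
      for (p in seq_len(nrow(pairs))) {
        for (role in c("case", "control")) {
          pid <- if (role == "case") pairs$case_id[p] else pairs$control_id[p]
          idx <- pairs$index_date[p]
          seen <- character(0)
          for (i in seq_len(nrow(events))) {
            if (events$patient_id[i] != pid) next
            if (is_af[i]) next
            if (events$setting[i] != setting) next
            d <- events$event_date[i]
            inw <- if (period == "pre") d >= idx - W && d < idx
                   else d > idx && d <= idx + W
            if (!inw) next
            if (events$code[i] %in% seen) next
            seen <- c(seen, events$code[i])
            key <- events$code[i]
            if (is.null(tally[[key]]))
              tally[[key]] <- c(case = 0L, control = 0L,
                                vocab = events$vocabulary[i])
            tally[[key]][role] <- as.integer(tally[[key]][role]) + 1L
          }
        }
      }
      for (key in names(tally)) {
        out[[length(out) + 1L]] <- data.frame(
          setting = setting, period = period, code = key,
          vocabulary = unname(tally[[key]]["vocab"]),
          n_case = as.integer(tally[[key]]["case"]),
          n_control = as.integer(tally[[key]]["control"]),
          n_pairs = nrow(pairs), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  out <- out[out$n_case >= config$min_case_patients, , drop = FALSE]
  out$pct_case <- 100 * out$n_case / out$n_pairs
  out$pct_control <- 100 * out$n_control / out$n_pairs
  out[order(out$setting, out$period, out$code), , drop = FALSE]
}

# independent re-implementation of the matching contract: cases in ascending
# index-date order, risk set filtered by explicit per-candidate loops,
# candidates sorted by id, one sample.int() draw per case from the shared
# seeded stream
oracle_match <- function(cases, eligible, events, af_codes, config) {
  af_first <- rep(as.Date(NA), nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    dates <- as.Date(character(0))
    for (j in seq_len(nrow(events))) {
      if (events$patient_id[j] != eligible$patient_id[i]) next
      hit <- FALSE
      for (k in seq_len(nrow(af_codes$entries))) {
        e <- af_codes$entries[k, ]
        if (e$vocabulary == "ICD10" && events$vocabulary[j] == "ICD10" &&
            startsWith(events$code[j], e$code)) hit <- TRUE
        if (e$vocabulary == "READ2" && events$vocabulary[j] == "READ2" &&
            events$code[j] == e$code) hit <- TRUE
      }
      if (hit) dates <- c(dates, events$event_date[j])
    }
    if (length(dates)) af_first[i] <- min(dates)
  }
  cases <- cases[order(cases$index_date, cases$patient_id), , drop = FALSE]
  used <- character(0)
  pairs <- NULL
  set.seed((config$rng_seed + 97L * 4L) %% 2147483587)
  for (ci in seq_len(nrow(cases))) {
    idx <- cases$index_date[ci]
    crow <- which(eligible$patient_id == cases$patient_id[ci])
    risk <- integer(0)
    for (i in seq_len(nrow(eligible))) {
      if (eligible$patient_id[i] == cases$patient_id[ci]) next
      if (eligible$sex[i] != eligible$sex[crow]) next
      if (abs(eligible$birth_year[i] - eligible$birth_year[crow]) >
            config$age_match_tolerance_years) next
      if (eligible$entry_date[i] > idx) next
      if (eligible$reg_end[i] < idx) next
      if (idx > config$study_end) next
      if (!is.na(eligible$death_date[i]) && eligible$death_date[i] <= idx) next
      if (!is.na(af_first[i]) && af_first[i] <= idx) next
      if (eligible$patient_id[i] %in% used) next
      risk <- c(risk, i)
    }
    if (length(risk) < config$match_ratio) next
    risk <- risk[order(eligible$patient_id[risk])]
    pick <- risk[sample.int(length(risk), config$match_ratio)]
    used <- c(used, eligible$patient_id[pick])
    pairs <- rbind(pairs, data.frame(
      case_id = cases$patient_id[ci],
      control_id = sort(eligible$patient_id[pick]),
      index_date = idx, stringsAsFactors = FALSE))
  }
  pairs
}

# replicate-by-replicate brute force over a fixed bootstrap plan
oracle_bootstrap_ci <- function(plan, pairs, events, config, setting, period,
                                code, af_codes = NULL) {
  # per-pair indicators from scratch
  W <- window_days_of(config)
  ind <- function(pid, idx) {
    for (i in seq_len(nrow(events))) {
      if (events$patient_id[i] != pid) next
      if (events$setting[i] != setting) next
      if (events$code[i] != code) next
      d <- events$event_date[i]
      inw <- if (period == "pre") d >= idx - W && d < idx
             else d > idx && d <= idx + W
      if (inw) return(1L)
    }
    0L
  }
  case_i <- mapply(ind, pairs$case_id, pairs$index_date)
  ctrl_i <- mapply(ind, pairs$control_id, pairs$index_date)
  cc <- config$continuity_correction
  ratios <- numeric(nrow(plan))
  for (b in seq_len(nrow(plan))) {
    nc <- sum(case_i[plan[b, ]])
    nk <- sum(ctrl_i[plan[b, ]])
    ratios[b] <- if (nk == 0) (nc + cc) / cc
                 else if (nc == 0) cc / (nk + cc)
                 else nc / nk
  }
  alpha <- (1 - config$ci_level) / 2
  stats::quantile(ratios, c(alpha, 1 - alpha), type = 1, names = FALSE)
}
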