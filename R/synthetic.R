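#' Configuration for the synthetic EHR generator
#'
#' The generator emulates the population a UK primary/secondary-care linkage
#' would supply: registrants with demographics and registration intervals
#' overlapping a study period, a constant-hazard atrial-fibrillation onset
#' process over each patient's registered, in-study adult time, and
#' independent per-(patient, code) homogeneous Poisson event streams. For
#' codes named in `planted_effects`, a case's event rate is multiplied by
#' `pre_ratio` during the window before its onset and by `post_ratio` after
#' it, giving every downstream stage a known ground truth to recover.
#'
#' @param n_patients Number of registrants.
#' @param female_fraction Bernoulli probability of sex `"F"`.
#' @param birth_year_range Integer `(min, max)`; birth years drawn uniformly.
#' @param registration_span_years Numeric `(min, max)` registration length.
#' @param reg_start_range Dates `(min, max)`; registration starts drawn
#'   uniformly, then intervals ending before `study_start` are shifted
#'   forward so every interval overlaps the study period.
#' @param af_annual_hazard Constant per-year AF onset hazard.
#' @param death_annual_hazard Constant per-year mortality hazard, applied
#'   identically to everyone (no case/control differential).
#' @param code_universe Data frame with columns `code`, `vocabulary`,
#'   `setting`, `base_rate` (events per patient-year).
#' @param planted_effects Named list `code -> c(pre_ratio, post_ratio)`.
#' @param window_years Width of the planted pre/post effect windows; should
#'   equal the scan's `window_years`.
#' @param study_start,study_end Study period the population is built around.
#' @param min_age Adult age used for the AF risk window.
#' @param rng_seed Master seed for the generator.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_patients = 100, rng_seed = 7)
#' pop <- generate_population(cfg)
#' @export
synth_config <- function(n_patients = 1000L,
                         female_fraction = 0.5,
                         birth_year_range = c(1915L, 1975L),
                         registration_span_years = c(8, 28),
                         reg_start_range = c("1988-01-01", "2008-01-01"),
                         af_annual_hazard = 0.01,
                         death_annual_hazard = 0,
                         code_universe = default_code_universe(),
                         planted_effects = list(),
                         window_years = 5,
                         study_start = "1998-01-01",
                         study_end = "2016-05-31",
                         min_age = 18L,
                         rng_seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    female_fraction = as.numeric(female_fraction),
    birth_year_range = as.integer(birth_year_range),
    registration_span_years = as.numeric(registration_span_years),
    reg_start_range = as.Date(reg_start_range),
    af_annual_hazard = as.numeric(af_annual_hazard),
    death_annual_hazard = as.numeric(death_annual_hazard),
    code_universe = code_universe,
    planted_effects = planted_effects,
    window_years = as.numeric(window_years),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    min_age = as.integer(min_age),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_patients < 0L) stopf("n_patients must be >= 0")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    stopf("female_fraction must lie in [0, 1]")
  if (cfg$af_annual_hazard < 0) stopf("af_annual_hazard must be >= 0")
  if (any(cfg$code_universe$base_rate < 0)) stopf("base rates must be >= 0")
  for (eff in cfg$planted_effects)
    if (any(eff <= 0)) stopf("planted ratios must be > 0")
  missing_fx <- setdiff(names(cfg$planted_effects), cfg$code_universe$code)
  if (length(missing_fx))
    stopf("planted effect(s) on code(s) absent from the universe: %s",
          paste(missing_fx, collapse = ", "))
  stopifnot(all(c("code", "vocabulary", "setting", "base_rate") %in%
                  names(cfg$code_universe)))
  class(cfg) <- "synth_config"
  cfg
}

#' Default synthetic code universe
#'
#' A deterministic set of plausible condition codes: ICD-10 subcodes over
#' common chapters for secondary care and terminal 7-character Read-style
#' codes for primary care. The AF phenotype codes themselves are never
#' included.
#'
#' @param n_primary,n_secondary Number of codes per care setting.
#' @param base_rate Events per patient-year for every code.
#' @return Data frame usable as `code_universe` in [synth_config()].
#' @export
default_code_universe <- function(n_primary = 20L, n_secondary = 20L,
                                  base_rate = 0.1) {
  stems <- c("A41", "C34", "D69", "E11", "G40", "I10", "I21", "I50",
             "I63", "J18", "J44", "K29", "M54", "N17", "R06", "S22")
  icd <- as.vector(t(outer(stems, 0:9, function(s, d) paste0(s, ".", d))))
  icd <- icd[seq_len(min(n_secondary, length(icd)))]
  if (n_secondary > length(icd))
    stopf("at most %d secondary codes available", length(icd))
  read <- sprintf("Z%03d.00", seq_len(n_primary))
  data.frame(
    code = c(read, icd),
    vocabulary = c(rep("READ2", length(read)), rep("ICD10", length(icd))),
    setting = c(rep("primary", length(read)), rep("secondary", length(icd))),
    base_rate = base_rate,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic patient registry
#'
#' @param cfg A [synth_config()].
#' @return Patient table in the format of [read_patients()].
#' @export
generate_population <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0L) {
    return(data.frame(patient_id = character(0), sex = character(0),
                      birth_year = integer(0),
                      reg_start = as.Date(numeric(0), origin = "1970-01-01"),
                      reg_end = as.Date(numeric(0), origin = "1970-01-01"),
                      death_date = as.Date(numeric(0), origin = "1970-01-01"),
                      stringsAsFactors = FALSE))
  }
  with_seed(stage_seed(cfg$rng_seed, 1L), {
    sex <- ifelse(stats::runif(n) < cfg$female_fraction, "F", "M")
    birth_year <- as.integer(floor(stats::runif(
      n, cfg$birth_year_range[1L], cfg$birth_year_range[2L] + 1L)))
    start_span <- as.numeric(cfg$reg_start_range[2L] - cfg$reg_start_range[1L])
    reg_start <- cfg$reg_start_range[1L] +
      floor(stats::runif(n, 0, start_span + 1))
    span_days <- year_days(stats::runif(n, cfg$registration_span_years[1L],
                                        cfg$registration_span_years[2L]))
    reg_end <- reg_start + pmax(span_days, 1L)
    # guarantee overlap with the study period (shift late-ending intervals)
    shift <- pmax(0, as.numeric(cfg$study_start - reg_end) + 1)
    reg_start <- reg_start + shift
    reg_end <- reg_end + shift
    death_date <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
    if (cfg$death_annual_hazard > 0) {
      wait <- stats::rexp(n, cfg$death_annual_hazard)
      d <- reg_start + floor(wait * 365.25)
      died <- d <= reg_end
      death_date[died] <- d[died]
      reg_end[died] <- d[died]
    }
    validate_patients(data.frame(
      patient_id = sprintf("p%06d", seq_len(n)),
      sex = sex,
      birth_year = pmin(pmax(birth_year, 1880L), 2016L),
      reg_start = reg_start,
      reg_end = reg_end,
      death_date = death_date,
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate AF onsets over each patient's at-risk time
#'
#' Each patient's first AF onset is drawn from a constant-hazard process
#' over the intersection of their registration interval, the study period
#' and their adult years; a waiting time falling beyond that interval means
#' the patient never becomes a case.
#'
#' @param population Patient table from [generate_population()].
#' @param cfg The [synth_config()] used to generate it.
#' @return An object of class `ground_truth`: list with `cases`
#'   (`patient_id`, `onset_date`) and the planted effect map.
#' @export
generate_af_onsets <- function(population, cfg) {
  adult <- as.Date(sprintf("%d-01-01", population$birth_year + cfg$min_age))
  risk_start <- pmax(population$reg_start, cfg$study_start, adult)
  risk_end <- pmin(population$reg_end, cfg$study_end)
  onset <- with_seed(stage_seed(cfg$rng_seed, 2L), {
    if (cfg$af_annual_hazard <= 0) {
      as.Date(rep(NA_real_, nrow(population)), origin = "1970-01-01")
    } else {
      wait <- stats::rexp(nrow(population), cfg$af_annual_hazard)
      risk_start + floor(wait * 365.25)
    }
  })
  is_case <- !is.na(onset) & risk_start <= risk_end & onset <= risk_end
  truth <- list(
    cases = data.frame(patient_id = population$patient_id[is_case],
                       onset_date = onset[is_case],
                       stringsAsFactors = FALSE),
    planted_effects = cfg$planted_effects,
    window_years = cfg$window_years
  )
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("synthetic ground truth: %d AF cases, %d planted effect(s)\n",
              nrow(x$cases), length(x$planted_effects)))
  invisible(x)
}

#' Generate coded event streams
#'
#' For every (patient, code) pair an independent homogeneous Poisson stream
#' at the code's base rate, with a case's rate multiplied by the planted
#' pre-ratio on the window before onset and the post-ratio after it. Every
#' case additionally receives one AF code (`I48`, secondary care) on its
#' onset date. All events fall inside the patient's registration interval.
#'
#' @param population Patient table.
#' @param truth Ground truth from [generate_af_onsets()].
#' @param cfg The [synth_config()].
#' @return Event table in the format of [read_events()].
#' @export
generate_events <- function(population, truth, cfg) {
  if (!all(truth$cases$patient_id %in% population$patient_id))
    stopf("ground truth references unknown patients")
  segs <- build_rate_segments(population, truth, cfg)
  codes <- cfg$code_universe
  n_cases <- nrow(truth$cases)
  af_events <- data.frame(
    patient_id = truth$cases$patient_id,
    event_date = truth$cases$onset_date,
    code = rep_len("I48", n_cases),
    vocabulary = rep_len("ICD10", n_cases),
    setting = rep_len("secondary", n_cases),
    stringsAsFactors = FALSE
  )
  if (!nrow(segs) || !nrow(codes) || all(codes$base_rate == 0))
    return(validate_events(af_events))

  pre_mult <- post_mult <- rep(1, nrow(codes))
  if (length(cfg$planted_effects)) {
    hit <- match(names(cfg$planted_effects), codes$code)
    for (i in seq_along(hit)) {
      if (is.na(hit[i])) next
      pre_mult[hit[i]] <- cfg$planted_effects[[i]][1L]
      post_mult[hit[i]] <- cfg$planted_effects[[i]][2L]
    }
  }
  ev <- with_seed(stage_seed(cfg$rng_seed, 3L), {
    S <- nrow(segs); C <- nrow(codes)
    rate <- outer(segs$len, codes$base_rate / 365.25)
    pre_rows <- segs$period == "pre"
    post_rows <- segs$period == "post"
    if (any(pre_rows))
      rate[pre_rows, ] <- rate[pre_rows, , drop = FALSE] *
        matrix(pre_mult, sum(pre_rows), C, byrow = TRUE)
    if (any(post_rows))
      rate[post_rows, ] <- rate[post_rows, , drop = FALSE] *
        matrix(post_mult, sum(post_rows), C, byrow = TRUE)
    n <- stats::rpois(S * C, as.vector(rate))
    idx <- rep.int(seq_along(n), n)
    s_idx <- (idx - 1L) %% S + 1L
    c_idx <- (idx - 1L) %/% S + 1L
    data.frame(
      patient_id = segs$patient_id[s_idx],
      event_date = as.Date(
        segs$start[s_idx] + floor(stats::runif(length(idx)) * segs$len[s_idx]),
        origin = "1970-01-01"),
      code = codes$code[c_idx],
      vocabulary = codes$vocabulary[c_idx],
      setting = codes$setting[c_idx],
      stringsAsFactors = FALSE
    )
  })
  validate_events(rbind(ev, af_events))
}

# split each patient's registration into constant-rate day segments:
# base / pre-window / onset day / post-window / base
build_rate_segments <- function(population, truth, cfg) {
  a <- as.integer(population$reg_start)
  b <- as.integer(population$reg_end)
  onset <- rep(NA_integer_, nrow(population))
  m <- match(truth$cases$patient_id, population$patient_id)
  onset[m] <- as.integer(truth$cases$onset_date)
  W <- year_days(cfg$window_years)

  seg <- function(pid, start, end, period) {
    keep <- !is.na(start) & !is.na(end) & end >= start
    data.frame(patient_id = pid[keep], start = start[keep],
               len = end[keep] - start[keep] + 1L,
               period = rep_len(period, sum(keep)),
               stringsAsFactors = FALSE)
  }
  pid <- population$patient_id
  noncase <- is.na(onset)
  rbind(
    seg(pid[noncase], a[noncase], b[noncase], "base"),
    seg(pid[!noncase], a[!noncase],
        pmin(b[!noncase], onset[!noncase] - W - 1L), "base"),
    seg(pid[!noncase], pmax(a[!noncase], onset[!noncase] - W),
        pmin(b[!noncase], onset[!noncase] - 1L), "pre"),
    seg(pid[!noncase], onset[!noncase], pmin(b[!noncase], onset[!noncase]),
        "base"),
    seg(pid[!noncase], pmax(a[!noncase], onset[!noncase] + 1L),
        pmin(b[!noncase], onset[!noncase] + W), "post"),
    seg(pid[!noncase], pmax(a[!noncase], onset[!noncase] + W + 1L),
        b[!noncase], "base")
  )
}

#' One-call synthetic EHR simulation
#'
#' Runs [generate_population()], [generate_af_onsets()] and
#' [generate_events()] and returns all three pieces. Regeneration with the
#' same configuration is bit-identical.
#'
#' @param cfg A [synth_config()].
#' @return List with `patients`, `events`, `truth` and the `config`.
#' @export
simulate_ehr <- function(cfg) {
  patients <- generate_population(cfg)
  truth <- generate_af_onsets(patients, cfg)
  events <- generate_events(patients, truth, cfg)
  list(patients = patients, events = events, truth = truth, config = cfg)
}

#' Analytically implied patient-level frequency ratio of a planted effect
#'
#' The generator plants effects as event-rate multipliers, while the scan
#' counts patients with at least one in-window event. For base rate
#' \eqn{\lambda}, window width \eqn{W} years and rate multiplier \eqn{r},
#' the implied patient-level frequency ratio is
#' \deqn{\frac{1 - e^{-r\lambda W}}{1 - e^{-\lambda W}}.}
#'
#' @param cfg A [synth_config()].
#' @param code Code carrying the planted effect.
#' @param period `"pre"` or `"post"`.
#' @return The implied frequency ratio (a number).
#' @export
implied_freq_ratio <- function(cfg, code, period = c("pre", "post")) {
  period <- match.arg(period)
  i <- match(code, cfg$code_universe$code)
  if (is.na(i)) stopf("code %s not in the code universe", dQuote(code))
  lam <- cfg$code_universe$base_rate[i]
  eff <- cfg$planted_effects[[code]]
  r <- if (is.null(eff)) 1 else eff[[if (period == "pre") 1L else 2L]]
  W <- cfg$window_years
  (1 - exp(-r * lam * W)) / (1 - exp(-lam * W))
}
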