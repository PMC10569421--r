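test_that("eligibility matches a hand-evaluated truth table", {
  cfg <- study_config(verbose = FALSE)
  af <- test_af_codes()
  # entry = max(reg_start + 1y, 1998-01-01); rules evaluated by hand
  spec <- list(
    #            id  sex  by    reg_start     reg_end       death         elig
    list("adult_long", "F", 1940, "1990-01-01", "2010-01-01", NA, TRUE),
    list("age_5_at_entry", "F", 2005, "2009-01-01", "2015-01-01", NA, FALSE),
    list("age_18_exact", "M", 1980, "1990-01-01", "2010-01-01", NA, TRUE),
    list("age_17_at_entry", "M", 1981, "1990-01-01", "2010-01-01", NA, FALSE),
    list("reg_1y_exact", "F", 1940, "2005-01-02", "2010-01-01", NA, TRUE),
    list("reg_ends_before_study", "F", 1940, "1980-01-01", "1995-01-01", NA, FALSE),
    list("reg_ends_at_entry", "F", 1940, "1990-01-01", "1998-01-01", NA, TRUE),
    list("reg_starts_after_end", "F", 1940, "2016-01-01", "2018-01-01", NA, FALSE),
    list("dies_before_entry", "M", 1940, "1990-01-01", "2010-01-01",
         "1997-06-01", FALSE),
    list("dies_on_entry_day", "M", 1940, "1990-01-01", "2010-01-01",
         "1998-01-01", FALSE),
    list("dies_after_entry", "M", 1940, "1990-01-01", "2010-01-01",
         "1999-06-01", TRUE),
    list("af_before_entry", "F", 1940, "1990-01-01", "2010-01-01", NA, FALSE),
    list("af_after_entry", "F", 1940, "1990-01-01", "2010-01-01", NA, TRUE),
    list("late_reg_entry_after_study_end", "F", 1940, "2016-01-01",
         "2018-06-01", NA, FALSE),
    list("born_1920_elderly", "M", 1920, "1990-01-01", "2010-01-01", NA, TRUE),
    list("short_reg_inside_study", "M", 1940, "2005-01-01", "2005-06-01",
         NA, FALSE),
    list("entry_on_study_end", "F", 1940, "2015-06-01", "2017-01-01", NA, TRUE)
  )
  patients <- do.call(rbind, lapply(spec, function(s)
    mk_patients(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]])))
  events <- rbind(
    mk_events("af_before_entry", "1997-05-01", "I48"),
    mk_events("af_after_entry", "1999-01-01", "I48"))
  want <- vapply(spec, function(s) s[[7]], logical(1))
  elig <- apply_eligibility(patients, events, af, cfg)
  got <- vapply(spec, function(s) s[[1]] %in% elig$patient_id, logical(1))
  names(want) <- names(got) <- vapply(spec, `[[`, "", 1)
  expect_identical(got, want)
  # dies_after_entry: death 1999-06-01 > entry 1998-01-01
  expect_equal(elig$entry_date[elig$patient_id == "adult_long"],
               as.Date("1998-01-01"))
  expect_equal(elig$entry_date[elig$patient_id == "reg_1y_exact"],
               as.Date("2006-01-02"))
})

test_that("index date is the earliest in-observation AF code", {
  cfg <- study_config(verbose = FALSE)
  af <- test_af_codes()
  patients <- mk_patients(c("a", "b", "c"), reg_start = "1990-01-01",
                          reg_end = "2005-12-31")
  events <- rbind(
    mk_events("a", "2004-03-01", "I48.1"),
    mk_events("a", "2005-01-01", "G573.00", "READ2", "primary"),
    mk_events("b", "2003-01-01", "I47.1"),            # not an AF code
    mk_events("c", "2006-03-01", "I48"))              # after reg_end
  elig <- apply_eligibility(patients, events, af, cfg)
  cases <- identify_cases(elig, events, af, cfg)
  expect_equal(cases$patient_id, "a")
  expect_equal(cases$index_date, as.Date("2004-03-01"))
})

test_that("risk-set matching enforces every pair invariant", {
  cfg <- study_config(verbose = FALSE, rng_seed = 5)
  af <- test_af_codes()
  patients <- rbind(
    mk_patients("case1", "F", 1940, "1995-01-01", "2010-01-01"),
    mk_patients("ok", "F", 1940, "2000-01-01", "2010-01-01"),
    mk_patients("prior_af", "F", 1940, "1995-01-01", "2010-01-01"),
    mk_patients("wrong_sex", "M", 1940, "1995-01-01", "2010-01-01"),
    mk_patients("wrong_year", "F", 1941, "1995-01-01", "2010-01-01"),
    mk_patients("gone", "F", 1940, "1995-01-01", "2004-01-01"))
  events <- rbind(
    mk_events("case1", "2005-06-01", "I48"),
    mk_events("prior_af", "1997-06-01", "I48"))  # AF before entry: ineligible
  elig <- apply_eligibility(patients, events, af, cfg)
  cases <- identify_cases(elig, events, af, cfg)
  pairs <- match_controls(cases, elig, events, af, cfg)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$control_id, "ok")   # the only admissible candidate
  expect_equal(pairs$index_date, cases$index_date)
  expect_equal(pairs$age_difference_years, 0L)
})

test_that("a control can later become a case, but is never reused", {
  cfg <- study_config(verbose = FALSE, rng_seed = 1)
  af <- test_af_codes()
  patients <- rbind(
    mk_patients("early", "F", 1940, "1995-01-01", "2012-01-01"),
    mk_patients("late", "F", 1940, "1995-01-01", "2012-01-01"),
    mk_patients("spare", "F", 1940, "1995-01-01", "2012-01-01"))
  events <- rbind(
    mk_events("early", "2004-01-01", "I48"),
    mk_events("late", "2008-01-01", "I48"))
  elig <- apply_eligibility(patients, events, af, cfg)
  cases <- identify_cases(elig, events, af, cfg)
  expect_equal(nrow(cases), 2L)
  pairs <- suppressWarnings(match_controls(cases, elig, events, af, cfg))
  # "late" is AF-free at 2004 and thus eligible as early's control
  ok_controls <- pairs$control_id[pairs$case_id == "early"]
  expect_true(ok_controls %in% c("late", "spare"))
  expect_false(anyDuplicated(pairs$control_id) > 0)
})

test_that("matching equals an independent brute-force re-implementation", {
  af <- test_af_codes()
  for (seed in c(2, 7, 19)) {
    cfg <- study_config(verbose = FALSE, rng_seed = seed)
    set.seed(seed * 100)
    n <- 25
    patients <- mk_patients(sprintf("q%02d", 1:n),
                            sex = sample(c("F", "M"), n, TRUE),
                            birth_year = sample(1938:1942, n, TRUE),
                            reg_start = "1995-01-01", reg_end = "2012-01-01")
    case_ids <- sprintf("q%02d", 1:5)
    events <- mk_events(case_ids,
                        as.character(as.Date("2003-01-01") + seq(0, 800, 200)),
                        "I48")
    elig <- apply_eligibility(patients, events, af, cfg)
    cases <- identify_cases(elig, events, af, cfg)
    got <- suppressWarnings(match_controls(cases, elig, events, af, cfg))
    want <- oracle_match(cases, elig, events, af, cfg)
    expect_equal(got[, c("case_id", "control_id", "index_date")],
                 want, ignore_attr = TRUE)
  }
})

test_that("matching is invariant to input storage order", {
  af <- test_af_codes()
  cfg <- study_config(verbose = FALSE, rng_seed = 4)
  sim <- simulate_ehr(synth_config(n_patients = 300, af_annual_hazard = 0.05,
                                   rng_seed = 12))
  run <- function(patients, events) {
    elig <- apply_eligibility(ehrwas:::validate_patients(patients),
                              ehrwas:::validate_events(events), af, cfg)
    cases <- identify_cases(elig, events, af, cfg)
    suppressWarnings(match_controls(cases, elig, events, af, cfg))
  }
  p1 <- run(sim$patients, sim$events)
  set.seed(1)
  p2 <- run(sim$patients[sample(nrow(sim$patients)), ],
            sim$events[sample(nrow(sim$events)), ])
  expect_identical(p1, p2)
})
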