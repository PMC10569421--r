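test_that("windows are half-open and exclude the index day", {
  cfg <- study_config(verbose = FALSE)
  idx <- as.Date("2005-06-01")
  ev <- mk_events(rep("p", 5),
                  c("2001-01-01", "2000-06-01", "2005-06-01", "2005-06-02",
                    "2010-06-02"),
                  c("A00.1", "A00.2", "A00.3", "A00.4", "A00.5"))
  pre <- window_events(ev, idx, cfg, "pre")
  post <- window_events(ev, idx, cfg, "post")
  expect_setequal(pre$code, c("A00.1", "A00.2"))  # 2000-06-01 = idx - 1826
  expect_setequal(post$code, "A00.4")             # index day in neither
  expect_false("A00.3" %in% c(pre$code, post$code))

  # AF phenotype codes are dropped from the scanned stream
  af <- test_af_codes()
  ev2 <- rbind(ev, mk_events("p", "2004-01-01", "I48.2"))
  expect_false("I48.2" %in% window_events(ev2, idx, cfg, "pre", af)$code)
})

test_that("window assignment equals a brute-force date comparison", {
  cfg <- study_config(verbose = FALSE)
  idx <- as.Date("2005-06-01")
  set.seed(8)
  ev <- mk_events(rep("p", 200),
                  as.Date("1998-01-01") + sample.int(6000, 200, TRUE),
                  sprintf("B%02d.1", sample.int(99, 200, TRUE)))
  for (period in c("pre", "post")) {
    expect_equal(window_events(ev, idx, cfg, period),
                 oracle_window(ev, idx, cfg, period), ignore_attr = TRUE)
  }
})

test_that("counting is patient-level and respects the case threshold", {
  cfg <- study_config(verbose = FALSE, min_case_patients = 1L)
  pairs <- data.frame(case_id = "c1", control_id = "k1",
                      index_date = as.Date("2005-06-01"),
                      stringsAsFactors = FALSE)
  ev <- rbind(
    mk_events(rep("c1", 3), c("2003-01-01", "2003-05-01", "2004-01-01"),
              "I50.9"),                    # 3 admissions, 1 patient
    mk_events("k1", "2003-02-01", "K29.0"))
  cnt <- count_conditions(pairs, ev, cfg)
  i50 <- cnt[cnt$code == "I50.9" & cnt$period == "pre", ]
  expect_equal(i50$n_case, 1L)
  expect_equal(i50$n_control, 0L)
  # control-only codes have n_case = 0 and are dropped at threshold >= 1
  expect_false("K29.0" %in% cnt$code)
  cfg0 <- study_config(verbose = FALSE, min_case_patients = 0L)
  cnt0 <- count_conditions(pairs, ev, cfg0)
  expect_true("K29.0" %in% cnt0$code)
})

test_that("a 20-pair fixture reproduces the brute-force count table", {
  af <- test_af_codes()
  cfg <- study_config(verbose = FALSE, min_case_patients = 1L)
  set.seed(14)
  n <- 20
  pairs <- data.frame(case_id = sprintf("c%02d", 1:n),
                      control_id = sprintf("k%02d", 1:n),
                      index_date = as.Date("2004-01-01") +
                        sample.int(2000, n, TRUE),
                      stringsAsFactors = FALSE)
  ids <- sample(c(pairs$case_id, pairs$control_id), 600, TRUE)
  ev <- mk_events(
    ids, as.Date("1999-01-01") + sample.int(5500, 600, TRUE),
    sample(c("I50.9", "I63.5", "K29.0", "C34.1", "I48.1"), 600, TRUE))
  ev2 <- mk_events(
    sample(ids, 200), as.Date("1999-01-01") + sample.int(5500, 200, TRUE),
    sample(c("H33..00", "G20..00"), 200, TRUE), "READ2", "primary")
  events <- rbind(ev, ev2)
  got <- count_conditions(pairs, events, cfg, af)
  got <- got[order(got$setting, got$period, got$code), ]
  want <- oracle_counts(pairs, events, cfg, af)
  expect_equal(got, want, ignore_attr = TRUE)
  # counting is invariant to duplicating events within a patient
  dup <- rbind(events, events[sample.int(nrow(events), 300), ])
  cnt_dup <- count_conditions(pairs, dup, cfg, af)
  cnt_dup <- cnt_dup[order(cnt_dup$setting, cnt_dup$period, cnt_dup$code), ]
  expect_equal(cnt_dup, got, ignore_attr = TRUE)
})

test_that("frequency ratios follow the definition and the zero-control rule", {
  cfg <- study_config(verbose = FALSE)
  base <- data.frame(setting = "secondary", period = "pre",
                     code = c("A", "B", "C", "D"), vocabulary = "ICD10",
                     n_case = c(2L, 7L, 7L, 7L),
                     n_control = c(1L, 7L, 2L, 0L), n_pairs = 20L,
                     stringsAsFactors = FALSE)
  base$pct_case <- 100 * base$n_case / base$n_pairs
  base$pct_control <- 100 * base$n_control / base$n_pairs
  r <- frequency_ratio(base, cfg)
  expect_equal(r$freq_ratio, c(2, 1, 3.5, (7 + 0.5) / 0.5))
  expect_equal(r$zero_control_flag, c(FALSE, FALSE, FALSE, TRUE))
  bad <- base; bad$n_case[1] <- 0L
  expect_error(frequency_ratio(bad, cfg), "n_case = 0")
})

test_that("ranking is a deterministic total order cut at top_n", {
  cfg <- study_config(verbose = FALSE, top_n = 2L)
  res <- data.frame(setting = "secondary", period = "pre",
                    code = c("A10.1", "B20.2", "C30.3"),
                    vocabulary = "ICD10",
                    n_case = c(6L, 10L, 3L), n_control = c(2L, 2L, 2L),
                    n_pairs = 50L, pct_case = c(12, 20, 6),
                    pct_control = 4, freq_ratio = c(3, 5, 1.5),
                    zero_control_flag = FALSE, stringsAsFactors = FALSE)
  top <- rank_leading(res, cfg)
  expect_equal(top$code, c("B20.2", "A10.1"))
  expect_equal(top$rank, 1:2)
  # fewer available than top_n: all returned
  cfg100 <- study_config(verbose = FALSE, top_n = 100L)
  expect_equal(nrow(rank_leading(res, cfg100)), 3L)
  # ties on ratio and pct_case break lexicographically and stably
  tie <- res
  tie$freq_ratio <- 2; tie$pct_case <- 10
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    expect_equal(rank_leading(tie[perm, ], cfg100)$code,
                 c("A10.1", "B20.2", "C30.3"))
  }
})

test_that("swapping case and control labels inverts the frequency ratios", {
  cfg <- study_config(verbose = FALSE, min_case_patients = 1L)
  sim <- simulate_ehr(synth_config(n_patients = 400, af_annual_hazard = 0.05,
                                   rng_seed = 18))
  af <- af_code_list()
  elig <- apply_eligibility(sim$patients, sim$events, af, cfg)
  cases <- identify_cases(elig, sim$events, af, cfg)
  pairs <- suppressWarnings(match_controls(cases, elig, sim$events, af, cfg))
  fwd <- frequency_ratio(count_conditions(pairs, sim$events, cfg, af), cfg)
  swapped <- pairs
  swapped$case_id <- pairs$control_id
  swapped$control_id <- pairs$case_id
  rev <- frequency_ratio(count_conditions(swapped, sim$events, cfg, af), cfg)
  key <- function(d) paste(d$setting, d$period, d$code)
  common <- intersect(key(fwd)[!fwd$zero_control_flag & fwd$n_control > 0],
                      key(rev)[!rev$zero_control_flag & rev$n_control > 0])
  f <- fwd$freq_ratio[match(common, key(fwd))]
  b <- rev$freq_ratio[match(common, key(rev))]
  expect_gt(length(common), 20)
  expect_equal(f, 1 / b, tolerance = 1e-12)
})

test_that("under the synthetic null, log frequency ratios centre at zero", {
  cfg <- study_config(verbose = FALSE, min_case_patients = 1L, rng_seed = 30)
  uni <- default_code_universe(60, 60, base_rate = 0.15)
  sim <- simulate_ehr(synth_config(n_patients = 1500,
                                   af_annual_hazard = 0.035,
                                   birth_year_range = c(1925, 1955),
                                   code_universe = uni, rng_seed = 30))
  af <- af_code_list()
  elig <- apply_eligibility(sim$patients, sim$events, af, cfg)
  cases <- identify_cases(elig, sim$events, af, cfg)
  pairs <- suppressWarnings(match_controls(cases, elig, sim$events, af, cfg))
  res <- frequency_ratio(count_conditions(pairs, sim$events, cfg, af), cfg)
  res <- res[res$n_control > 0 & res$setting == "secondary", ]
  lr <- log(res$freq_ratio)
  nz <- lr[lr != 0]
  expect_gte(length(nz), 100)
  p <- stats::binom.test(sum(nz > 0), length(nz))$p.value
  expect_gt(p, 0.01)
})
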