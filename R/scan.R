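#' Window events around an index date
#'
#' The pre window keeps events with
#' `index - window <= date < index`; the post window keeps
#' `index < date <= index + window`. Events on the index day itself belong
#' to neither window, and AF-phenotype codes are excluded from the scanned
#' stream (they define the index, not a finding).
#'
#' @param events Event table.
#' @param index_date The index date the window is anchored on.
#' @param config A [study_config()] (supplies `window_years`).
#' @param period `"pre"` or `"post"`.
#' @param af_codes Optional [code_list()] to exclude; `NULL` keeps all codes.
#' @return The filtered event table.
#' @export
window_events <- function(events, index_date, config,
                          period = c("pre", "post"), af_codes = NULL) {
  period <- match.arg(period)
  W <- year_days(config$window_years)
  keep <- if (period == "pre") {
    events$event_date >= index_date - W & events$event_date < index_date
  } else {
    events$event_date > index_date & events$event_date <= index_date + W
  }
  if (!is.null(af_codes)) keep <- keep & !matches_code_list(events, af_codes)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Patient-level occurrence indicators per stratum. Returns, for each of the
# four strata, logical matrices `case` and `control` of dimension
# n_pairs x n_codes (TRUE = that pair's member has >= 1 in-window event with
# that code) plus the code table. With count_mode = "visits" the matrices
# hold event counts instead of indicators. This single kernel backs both
# count_conditions() and the bootstrap, so the two can never disagree.
occurrence_matrices <- function(pairs, events, config, af_codes = NULL) {
  stopifnot(nrow(pairs) >= 1L)
  ev <- data.table::as.data.table(events)
  if (!is.null(af_codes))
    ev <- ev[!matches_code_list(ev, af_codes)]
  W <- year_days(config$window_years)
  n_pairs <- nrow(pairs)

  roles <- list(
    case = data.table::data.table(patient_id = pairs$case_id,
                                  pair = seq_len(n_pairs),
                                  index_date = pairs$index_date),
    control = data.table::data.table(patient_id = pairs$control_id,
                                     pair = seq_len(n_pairs),
                                     index_date = pairs$index_date)
  )
  # long table of (role, pair, setting, period, code) in-window hits
  hits <- lapply(names(roles), function(rl) {
    j <- merge(ev, roles[[rl]], by = "patient_id", allow.cartesian = TRUE)
    if (!nrow(j)) return(NULL)
    per <- rep(NA_character_, nrow(j))
    per[j$event_date >= j$index_date - W &
          j$event_date < j$index_date] <- "pre"
    per[j$event_date > j$index_date &
          j$event_date <= j$index_date + W] <- "post"
    j <- j[which(!is.na(per))]
    j$period <- per[!is.na(per)]
    j$role <- rl
    j[, c("role", "pair", "setting", "period", "code", "vocabulary"),
      with = FALSE]
  })
  hits <- data.table::rbindlist(hits[!vapply(hits, is.null, logical(1))])

  keys <- strata_keys()
  out <- vector("list", nrow(keys))
  names(out) <- stratum_label(keys$setting, keys$period)
  for (s in seq_len(nrow(keys))) {
    h <- if (nrow(hits)) {
      hits[which(hits[["setting"]] == keys$setting[s] &
                   hits[["period"]] == keys$period[s])]
    } else hits
    codes <- unique(h[, c("code", "vocabulary"), with = FALSE])
    data.table::setorder(codes, code)
    mk <- function(rl) {
      m <- matrix(0L, n_pairs, nrow(codes),
                  dimnames = list(NULL, codes$code))
      hr <- h[which(h[["role"]] == rl)]
      if (nrow(hr)) {
        if (config$count_mode == "visits") {
          agg <- hr[, list(n = .N), by = c("pair", "code")]
          m[cbind(agg$pair, match(agg$code, codes$code))] <- agg$n
        } else {
          m[cbind(hr$pair, match(hr$code, codes$code))] <- 1L
        }
      }
      m
    }
    out[[s]] <- list(setting = keys$setting[s], period = keys$period[s],
                     codes = as.data.frame(codes), case = mk("case"),
                     control = mk("control"))
  }
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Count condition occurrence among cases and controls
#'
#' For each of the four strata (care setting x pre/post window) and each
#' condition code, counts the case and control patients with at least one
#' qualifying in-window event (default patient-level mode: repeat visits by
#' the same patient count once). Conditions seen in fewer than
#' `min_case_patients` case patients are dropped.
#'
#' @param pairs Matched pairs from [match_controls()].
#' @param events Event table.
#' @param config A [study_config()].
#' @param af_codes Optional AF [code_list()] excluded from the scan.
#' @return Data frame with columns `setting`, `period`, `code`,
#'   `vocabulary`, `n_case`, `n_control`, `n_pairs`, `pct_case`,
#'   `pct_control`.
#' @export
count_conditions <- function(pairs, events, config, af_codes = NULL) {
  if (!nrow(pairs)) stopf("no matched pairs to scan")
  occ <- occurrence_matrices(pairs, events, config, af_codes)
  n_pairs <- attr(occ, "n_pairs")
  res <- lapply(occ, function(s) {
    if (!nrow(s$codes)) return(NULL)
    n_case <- as.integer(colSums(s$case > 0L))
    n_control <- as.integer(colSums(s$control > 0L))
    if (config$count_mode == "visits") {
      n_case <- as.integer(colSums(s$case))
      n_control <- as.integer(colSums(s$control))
    }
    data.frame(setting = s$setting, period = s$period,
               code = s$codes$code, vocabulary = s$codes$vocabulary,
               n_case = n_case, n_control = n_control, n_pairs = n_pairs,
               pct_case = 100 * n_case / n_pairs,
               pct_control = 100 * n_control / n_pairs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  res <- res[res$n_case >= config$min_case_patients, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Case/control frequency ratio
#'
#' The ratio of the case percentage to the control percentage. When no
#' control patient has the condition, the continuity correction `c` is
#' added to both counts before converting to percentages, giving
#' `(n_case + c) / c`, and `zero_control_flag` is set.
#'
#' @param counts Data frame as produced by [count_conditions()] (any subset
#'   of rows).
#' @param config A [study_config()] (supplies `continuity_correction`).
#' @return `counts` with `freq_ratio` and `zero_control_flag` appended.
#' @export
frequency_ratio <- function(counts, config) {
  if (any(counts$n_case < 1L))
    stopf("frequency ratio undefined for n_case = 0 (pre-filter such codes)")
  cc <- config$continuity_correction
  zero <- counts$n_control == 0L
  ratio <- ifelse(zero,
                  (counts$n_case + cc) / cc,
                  counts$n_case / counts$n_control)
  counts$freq_ratio <- ratio
  counts$zero_control_flag <- zero
  counts
}

#' Rank the leading conditions per stratum
#'
#' Within each stratum, rows are ordered by descending frequency ratio,
#' then descending case percentage, then ascending code string (a
#' deterministic total order), ranks `1..K` assigned, and the list cut at
#' `top_n`.
#'
#' @param results Data frame with frequency ratios (from
#'   [frequency_ratio()]).
#' @param config A [study_config()] (supplies `top_n`).
#' @return The ranked subset with a `rank` column, strata stacked in the
#'   order primary/pre, primary/post, secondary/pre, secondary/post.
#' @export
rank_leading <- function(results, config) {
  keys <- strata_keys()
  out <- lapply(seq_len(nrow(keys)), function(s) {
    r <- results[results$setting == keys$setting[s] &
                   results$period == keys$period[s], , drop = FALSE]
    if (!nrow(r)) return(NULL)
    ord <- order(-r$freq_ratio, -r$pct_case, r$code)
    r <- r[ord[seq_len(min(config$top_n, nrow(r)))], , drop = FALSE]
    r$rank <- seq_len(nrow(r))
    r
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
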