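#' Balanced bootstrap resampling plan
#'
#' Builds `B` replicates of size `n_pairs` by concatenating `B` copies of
#' the pair indices, applying one seeded uniform permutation, and cutting
#' the result into `B` consecutive blocks. By construction every pair index
#' appears exactly `B` times across the whole plan (the balance property),
#' which removes first-order Monte-Carlo imbalance relative to ordinary
#' resampling.
#'
#' @param n_pairs Number of sampling units (matched pairs).
#' @param B Number of replicates.
#' @param seed Seed for the permutation.
#' @return An object of class `bootstrap_plan`: an integer matrix with `B`
#'   rows, each row one replicate's multiset of pair indices.
#' @examples
#' plan <- balanced_plan(3, 4, seed = 1)
#' table(plan)  # every index appears exactly 4 times
#' @export
balanced_plan <- function(n_pairs, B, seed) {
  if (n_pairs < 1L) stopf("n_pairs must be >= 1")
  if (B < 1L) stopf("B must be >= 1")
  pool <- rep.int(seq_len(n_pairs), B)
  perm <- with_seed(seed, sample(pool, length(pool)))
  plan <- matrix(perm, nrow = B, ncol = n_pairs, byrow = TRUE)
  class(plan) <- c("bootstrap_plan", class(plan))
  plan
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat(sprintf("balanced bootstrap plan: %d replicates x %d pairs\n",
              nrow(x), ncol(x)))
  invisible(x)
}

# B x n_pairs matrix of pair multiplicities per replicate
plan_multiplicities <- function(plan) {
  n <- ncol(plan)
  t(apply(plan, 1L, tabulate, nbins = n))
}

#' Balanced-bootstrap percentile confidence intervals
#'
#' Resamples whole matched pairs (preserving the matched design), recomputes
#' the case/control counts and the frequency ratio on every replicate — a
#' pair drawn `k` times contributes `k` times — and takes the percentile
#' interval of the `B` replicate ratios at
#' `(1 - ci_level)/2` and `1 - (1 - ci_level)/2`. Endpoints are order
#' statistics of the replicate set (`quantile` type 1). Replicates with a
#' zero control count fall back on the continuity correction, as the point
#' estimate does.
#'
#' @param pairs Matched pairs.
#' @param events Event table.
#' @param codes Data frame naming the `(setting, period, code)` rows to
#'   compute intervals for — typically the ranked leading conditions.
#' @param config A [study_config()] (supplies `bootstrap_B`, `ci_level`,
#'   `continuity_correction`, and the seed).
#' @param af_codes Optional AF [code_list()] excluded from the scan.
#' @param plan Optional pre-built [balanced_plan()]; by default one plan is
#'   derived from `config$rng_seed` and shared by all strata and codes.
#' @return `codes` with `ci_low` and `ci_high` columns appended.
#' @export
bootstrap_cis <- function(pairs, events, codes, config, af_codes = NULL,
                          plan = NULL) {
  if (!nrow(pairs)) stopf("no matched pairs to resample")
  occ <- occurrence_matrices(pairs, events, config, af_codes)
  n_pairs <- attr(occ, "n_pairs")
  if (is.null(plan))
    plan <- balanced_plan(n_pairs, config$bootstrap_B,
                          stage_seed(config$rng_seed, 5L))
  M <- plan_multiplicities(plan)
  alpha <- (1 - config$ci_level) / 2
  cc <- config$continuity_correction

  codes$ci_low <- NA_real_
  codes$ci_high <- NA_real_
  for (s in occ) {
    lab_rows <- which(codes$setting == s$setting & codes$period == s$period)
    if (!length(lab_rows)) next
    j <- match(codes$code[lab_rows], s$codes$code)
    present <- !is.na(j)
    if (!any(present)) next
    case_ind <- (s$case > 0L)[, j[present], drop = FALSE]
    ctrl_ind <- (s$control > 0L)[, j[present], drop = FALSE]
    if (config$count_mode == "visits") {
      case_ind <- s$case[, j[present], drop = FALSE]
      ctrl_ind <- s$control[, j[present], drop = FALSE]
    }
    n_case_b <- M %*% case_ind      # B x codes
    n_ctrl_b <- M %*% ctrl_ind
    ratio <- ifelse(n_ctrl_b == 0, (n_case_b + cc) / cc,
                    ifelse(n_case_b == 0, cc / (n_ctrl_b + cc),
                           n_case_b / n_ctrl_b))
    ci <- apply(ratio, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                type = 1L, names = FALSE)
    codes$ci_low[lab_rows[present]] <- ci[1L, ]
    codes$ci_high[lab_rows[present]] <- ci[2L, ]
  }
  codes
}
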