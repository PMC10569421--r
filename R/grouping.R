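#' The fourteen disease groups
#'
#' Conditions are classified into fourteen organ-system/disease groups:
#' cardiac-related (with subcategories arrhythmia, heart failure, heart
#' valve disease, cardiomyopathy, ischaemic heart disease, other),
#' cerebrovascular, peripheral or other vascular, bleeding/haemorrhagic,
#' infection, cancer, respiratory, endocrine/nutritional/metabolic,
#' gastrointestinal, renal, haematological, osteoarticular & muscular,
#' frailty/multimorbidity, and other. ICD-10 codes are classified by an
#' ordered rule list — per-code overrides first, then chapter/block ranges
#' on the 3-character category — and unmatched codes fall back on `other`.
#' Primary-care conditions circulate as free-text Read terms; those are
#' classified by an explicit term table derived from the packaged reference
#' rankings.
#'
#' @return An object of class `group_scheme`: the ordered group table (id,
#'   display label, clock position used by the iris layout), the ICD-10
#'   rule tables and the term table.
#' @examples
#' sch <- disease_groups()
#' classify_code("I63.5", "ICD10", sch)
#' @export
disease_groups <- function() {
  groups <- data.frame(
    group = c("cardiac", "cerebrovascular", "peripheral_vascular",
              "bleeding", "infection", "cancer", "respiratory",
              "endocrine_metabolic", "gastrointestinal", "renal",
              "haematological", "osteoarticular", "frailty", "other"),
    label = c("Cardiac-related", "Cerebrovascular",
              "Peripheral or other vascular", "Bleeding/haemorrhagic",
              "Infection", "Cancer", "Respiratory",
              "Endocrine, nutritional or metabolic", "Gastrointestinal",
              "Renal", "Haematological", "Osteoarticular & muscular",
              "Frailty or multimorbidity", "Other"),
    # clock-face position (12h = 0) driving the iris-plot sector order;
    # groups sharing an hour are ordered as listed in the figure legend
    clock_hour = c(3.5, 5, 10, 0, 8.2, 1.5, 11.5, 6, 7, 11, 8.1, 9, 6.1, 9.1),
    stringsAsFactors = FALSE
  )
  rules <- utils::read.csv(
    system.file("extdata", "icd10_group_rules.csv", package = "ehrwas",
                mustWork = TRUE),
    colClasses = "character", strip.white = TRUE)
  stopifnot(all(rules$group %in% groups$group))
  ref <- reference_rankings()
  terms <- unique(data.frame(
    term = normalize_term(ref$label[ref$setting == "primary"]),
    group = ref$group[ref$setting == "primary"],
    stringsAsFactors = FALSE))
  scheme <- list(
    groups = groups,
    exact = rules[rules$kind == "exact", c("code", "group")],
    ranges = data.frame(
      start = category_key(rules$start[rules$kind == "range"]),
      end = category_key(rules$end[rules$kind == "range"]),
      group = rules$group[rules$kind == "range"],
      stringsAsFactors = FALSE),
    terms = terms
  )
  class(scheme) <- "group_scheme"
  scheme
}

#' @export
print.group_scheme <- function(x, ...) {
  cat(sprintf(
    "disease grouping scheme: %d groups, %d code overrides, %d ranges, %d terms\n",
    nrow(x$groups), nrow(x$exact), nrow(x$ranges), nrow(x$terms)))
  invisible(x)
}

# sortable key for a 3-character ICD-10 category ("I63" -> 9*100 + 63)
category_key <- function(category) {
  match(substr(category, 1L, 1L), LETTERS) * 100L +
    suppressWarnings(as.integer(substr(category, 2L, 3L)))
}

normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Classify condition codes into disease groups
#'
#' ICD-10 codes are matched first against exact per-code overrides and then
#' against category ranges, the first hit winning; anything unmatched maps
#' to `"other"` (one summarising warning per call, controllable with
#' `warn_unmatched`). Read codes have no code-level rules and classify via
#' the term table only when a term is supplied. Compound printed codes such
#' as `"I50.0/I50.1"` are classified by their first component.
#'
#' @param code Character vector of codes.
#' @param vocabulary `"ICD10"` or `"READ2"` (recycled).
#' @param scheme A [disease_groups()] scheme.
#' @param term Optional character vector of condition terms used for
#'   non-ICD entries.
#' @param warn_unmatched Warn (once, with a count) about codes that fell
#'   back to `"other"`.
#' @return Character vector of group ids.
#' @export
classify_code <- function(code, vocabulary = "ICD10", scheme = disease_groups(),
                          term = NULL, warn_unmatched = TRUE) {
  n <- length(code)
  vocabulary <- rep_len(vocabulary, n)
  out <- rep(NA_character_, n)

  icd <- which(vocabulary == "ICD10")
  if (length(icd)) {
    x <- normalize_icd10(sub("/.*$", "", code[icd]))
    hit <- match(x, scheme$exact$code)
    out[icd[!is.na(hit)]] <- scheme$exact$group[hit[!is.na(hit)]]
    todo <- icd[is.na(hit)]
    if (length(todo)) {
      key <- category_key(substr(normalize_icd10(sub("/.*$", "", code[todo])),
                                 1L, 3L))
      for (r in seq_len(nrow(scheme$ranges))) {
        open <- is.na(out[todo])
        inr <- open & !is.na(key) & key >= scheme$ranges$start[r] &
          key <= scheme$ranges$end[r]
        out[todo[inr]] <- scheme$ranges$group[r]
      }
    }
  }
  if (!is.null(term)) {
    term <- rep_len(term, n)
    open <- which(is.na(out) & !is.na(term))
    hit <- match(normalize_term(term[open]), scheme$terms$term)
    out[open[!is.na(hit)]] <- scheme$terms$group[hit[!is.na(hit)]]
  }
  unmatched <- is.na(out)
  if (any(unmatched) && isTRUE(warn_unmatched))
    warning(sprintf("%d code(s) did not match any grouping rule; assigned 'other'",
                    sum(unmatched)), call. = FALSE)
  out[unmatched] <- "other"
  out
}

#' Cardiac subcategory of a code
#'
#' For codes in the cardiac-related group, the subcategory used in the
#' reference tables: arrhythmia, heart failure, heart valve disease,
#' cardiomyopathy, ischaemic heart disease, or other.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector (`NA` for non-cardiac codes).
#' @export
cardiac_subcategory <- function(code) {
  x <- normalize_icd10(sub("/.*$", "", code))
  cat3 <- substr(x, 1L, 3L)
  key <- category_key(cat3)
  out <- rep(NA_character_, length(code))
  out[x == "I25.5" | cat3 == "I42"] <- "cardiomyopathy"
  open <- is.na(out)
  out[open & (cat3 %in% c("I50") | x %in% c("I51.7", "E87.7"))] <- "heart_failure"
  open <- is.na(out)
  out[open & ((key >= category_key("I44") & key <= category_key("I49")) |
                cat3 == "R00")] <- "arrhythmia"
  open <- is.na(out)
  out[open & ((key >= category_key("I05") & key <= category_key("I09")) |
                (key >= category_key("I34") & key <= category_key("I37")) |
                x == "T82.0")] <- "valve"
  open <- is.na(out)
  out[open & key >= category_key("I20") & key <= category_key("I25")] <-
    "ischaemic"
  open <- is.na(out)
  cardiac <- classify_code(code, "ICD10", warn_unmatched = FALSE) == "cardiac"
  out[open & cardiac] <- "other_cardiac"
  out
}

#' Per-group condition counts of a ranked list
#'
#' Classifies each entry of a ranked result table (or reference fixture)
#' and tallies conditions per disease group. Entries carrying an ICD-10
#' code classify through the code rules; entries without one (primary-care
#' terms) classify through the term table.
#'
#' @param entries Data frame with a `code` column and optionally `label`
#'   and `vocabulary` columns.
#' @param scheme A [disease_groups()] scheme.
#' @return Named integer vector over all fourteen groups (zeros included),
#'   summing to `nrow(entries)`.
#' @export
group_counts <- function(entries, scheme = disease_groups()) {
  groups <- scheme$groups$group
  if (!nrow(entries)) {
    out <- integer(length(groups)); names(out) <- groups
    return(out)
  }
  code <- if ("code" %in% names(entries)) entries$code else NA_character_
  code <- ifelse(is.na(code) | !nzchar(code), NA_character_, code)
  vocab <- if ("vocabulary" %in% names(entries)) entries$vocabulary
           else ifelse(is.na(code), "READ2", "ICD10")
  term <- if ("label" %in% names(entries)) entries$label else NULL
  g <- classify_code(ifelse(is.na(code), "", code), vocab, scheme,
                     term = term, warn_unmatched = FALSE)
  out <- vapply(groups, function(gr) sum(g == gr), integer(1))
  out
}

#' Packaged reference rankings and novel-condition list
#'
#' `reference_rankings()` returns the four curated lists (pre/post index x
#' primary/secondary care) of the leading 100 conditions by disease group
#' from the source AF case-control analysis, 400 entries in total, used to
#' validate the grouping scheme. `novel_conditions()` returns the ten
#' conditions that analysis flagged as not previously reported in
#' association with AF. `fixture_exceptions()` enumerates the entries whose
#' printed group the shipped scheme knowingly does not reproduce.
#'
#' @return Data frames (see each file in `inst/extdata`).
#' @export
reference_rankings <- function() {
  utils::read.csv(
    system.file("extdata", "reference_rankings.csv", package = "ehrwas",
                mustWork = TRUE),
    colClasses = "character", strip.white = TRUE)
}

#' @rdname reference_rankings
#' @export
novel_conditions <- function() {
  utils::read.csv(
    system.file("extdata", "novel_conditions.csv", package = "ehrwas",
                mustWork = TRUE),
    colClasses = "character", strip.white = TRUE)
}

#' @rdname reference_rankings
#' @export
fixture_exceptions <- function() {
  utils::read.csv(
    system.file("extdata", "fixture_exceptions.csv", package = "ehrwas",
                mustWork = TRUE),
    colClasses = "character", strip.white = TRUE)
}
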