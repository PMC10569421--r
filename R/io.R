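#' Normalize ICD-10 codes to dotted form
#'
#' Hospital extracts vary between the dotted dialect (`"I63.5"`) and a
#' 4+ character undotted dialect (`"I635"`). Codes are upper-cased and a dot
#' is inserted after the 3-character category when absent; 3-character
#' categories (`"I48"`, `"C56"`) are left as they are.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of dotted, upper-case codes.
#' @examples
#' normalize_icd10(c("I635", "i63.5", "I48"))
#' @export
normalize_icd10 <- function(code) {
  x <- toupper(trimws(as.character(code)))
  undotted <- grepl("^[A-Z][0-9]{2}[0-9A-Z]+$", x) & !grepl("\\.", x)
  x[undotted] <- paste0(substr(x[undotted], 1L, 3L), ".",
                        substring(x[undotted], 4L))
  x
}

#' Read a patient registry table
#'
#' Expects comma-delimited text with header
#' `patient_id,sex,birth_year,reg_start,reg_end,death_date`, ISO-8601 dates
#' and an empty `death_date` field for patients alive at the end of
#' follow-up. Field-level invariants (known sex, parsable dates,
#' `reg_start < reg_end`, plausible birth year) are enforced with the
#' offending row named in the error.
#'
#' @param path Path to the file.
#' @return A `data.frame` with columns `patient_id` (character), `sex`
#'   (`"F"`/`"M"`), `birth_year` (integer), `reg_start`, `reg_end`,
#'   `death_date` (`Date`, `NA` when absent), sorted by `patient_id`.
#' @export
read_patients <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("patient_id", "sex", "birth_year", "reg_start", "reg_end",
            "death_date")
  if (!all(need %in% names(raw)))
    stopf("patient file %s lacks columns: %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  validate_patients(data.frame(
    patient_id = raw$patient_id,
    sex = raw$sex,
    birth_year = suppressWarnings(as.integer(raw$birth_year)),
    reg_start = as_date_strict(raw$reg_start, "reg_start"),
    reg_end = as_date_strict(raw$reg_end, "reg_end"),
    death_date = as_date_strict(raw$death_date, "death_date"),
    stringsAsFactors = FALSE
  ))
}

validate_patients <- function(p) {
  bad <- which(!p$sex %in% c("F", "M"))
  if (length(bad))
    stopf("unknown sex value %s at row %d", dQuote(p$sex[bad[1L]]), bad[1L])
  bad <- which(is.na(p$birth_year) | p$birth_year < 1880L | p$birth_year > 2016L)
  if (length(bad)) stopf("implausible birth_year at row %d", bad[1L])
  bad <- which(is.na(p$reg_start) | is.na(p$reg_end) | p$reg_start >= p$reg_end)
  if (length(bad)) stopf("reg_start must precede reg_end (row %d)", bad[1L])
  bad <- which(!is.na(p$death_date) & p$death_date < p$reg_start)
  if (length(bad)) stopf("death_date before reg_start at row %d", bad[1L])
  if (anyDuplicated(p$patient_id))
    stopf("duplicated patient_id %s",
          dQuote(p$patient_id[anyDuplicated(p$patient_id)]))
  p[order(p$patient_id), , drop = FALSE]
}

#' Write a patient registry table
#'
#' Inverse of [read_patients()]: ISO-8601 dates, empty string for a missing
#' death date. Reading the file back yields the same table.
#'
#' @param patients Patient table as returned by [read_patients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  out <- data.frame(
    patient_id = patients$patient_id,
    sex = patients$sex,
    birth_year = patients$birth_year,
    reg_start = format(patients$reg_start, "%Y-%m-%d"),
    reg_end = format(patients$reg_end, "%Y-%m-%d"),
    death_date = ifelse(is.na(patients$death_date), "",
                        format(patients$death_date, "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coded clinical event table
#'
#' Expects comma-delimited text with header
#' `patient_id,event_date,code,vocabulary,setting`. Secondary-care events
#' must carry ICD-10 codes and primary-care events Read codes; ICD-10 codes
#' are normalized to dotted form on read. Events are returned in the
#' canonical order `(patient_id, event_date, setting, code)` so downstream
#' results do not depend on storage order.
#'
#' @param path Path to the file.
#' @return A `data.frame` with columns `patient_id`, `event_date` (`Date`),
#'   `code`, `vocabulary` (`"ICD10"`/`"READ2"`), `setting`
#'   (`"primary"`/`"secondary"`).
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("patient_id", "event_date", "code", "vocabulary", "setting")
  if (!all(need %in% names(raw)))
    stopf("event file %s lacks columns: %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  validate_events(data.frame(
    patient_id = raw$patient_id,
    event_date = as_date_strict(raw$event_date, "event_date"),
    code = raw$code,
    vocabulary = raw$vocabulary,
    setting = raw$setting,
    stringsAsFactors = FALSE
  ))
}

validate_events <- function(ev) {
  bad <- which(is.na(ev$event_date))
  if (length(bad)) stopf("missing event_date at row %d", bad[1L])
  bad <- which(!nzchar(ev$code))
  if (length(bad)) stopf("empty code at row %d", bad[1L])
  bad <- which(!ev$vocabulary %in% c("ICD10", "READ2"))
  if (length(bad))
    stopf("unknown vocabulary %s at row %d", dQuote(ev$vocabulary[bad[1L]]),
          bad[1L])
  bad <- which(!ev$setting %in% c("primary", "secondary"))
  if (length(bad))
    stopf("unknown setting %s at row %d", dQuote(ev$setting[bad[1L]]), bad[1L])
  bad <- which(ev$setting == "secondary" & ev$vocabulary != "ICD10")
  if (length(bad))
    stopf("secondary-care events must be ICD10-coded (row %d)", bad[1L])
  bad <- which(ev$setting == "primary" & ev$vocabulary != "READ2")
  if (length(bad))
    stopf("primary-care events must be READ2-coded (row %d)", bad[1L])
  icd <- ev$vocabulary == "ICD10"
  ev$code[icd] <- normalize_icd10(ev$code[icd])
  ev[order(ev$patient_id, ev$event_date, ev$setting, ev$code), ,
     drop = FALSE]
}

#' Write a coded clinical event table
#'
#' @param events Event table as returned by [read_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    patient_id = events$patient_id,
    event_date = format(events$event_date, "%Y-%m-%d"),
    code = events$code,
    vocabulary = events$vocabulary,
    setting = events$setting,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Code lists
#'
#' A code list names a clinical phenotype as a set of `(code, vocabulary)`
#' pairs. [af_code_list()] returns the shipped atrial-fibrillation
#' phenotype: ICD-10 `I48` (matched as a prefix, so `I48.0` ... qualify)
#' from hospital records plus seven terminal Read codes from primary care
#' (matched verbatim, dots included). One Read code circulates both with and
#' without a thousands-separator comma; both spellings are included.
#'
#' @param name List name.
#' @param codes Character vector of codes.
#' @param vocabulary Vocabulary per code (recycled).
#' @param description Free-text description.
#' @return An object of class `code_list`.
#' @export
code_list <- function(name, codes, vocabulary, description = "") {
  codes <- as.character(codes)
  vocabulary <- rep_len(as.character(vocabulary), length(codes))
  if (!length(codes)) stopf("code list %s is empty", dQuote(name))
  if (!all(vocabulary %in% c("ICD10", "READ2")))
    stopf("vocabulary must be ICD10 or READ2")
  key <- paste(codes, vocabulary)
  if (anyDuplicated(key)) stopf("duplicate (code, vocabulary) pair in %s", name)
  structure(
    list(name = name,
         entries = data.frame(code = codes, vocabulary = vocabulary,
                              stringsAsFactors = FALSE),
         description = description),
    class = "code_list"
  )
}

#' @rdname code_list
#' @export
af_code_list <- function() {
  path <- system.file("extdata", "af_codes.csv", package = "ehrwas",
                      mustWork = TRUE)
  read_code_list(path, name = "atrial_fibrillation",
                 description = "New-onset atrial fibrillation phenotype")
}

#' @rdname code_list
#' @param path Delimited file with columns `code,vocabulary`.
#' @export
read_code_list <- function(path, name = basename(path), description = "") {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  code_list(name, raw$code, raw$vocabulary, description)
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("code list %s (%d entries)\n", dQuote(x$name),
              nrow(x$entries)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

# logical vector: does each event match the phenotype? ICD-10 entries match
# by prefix (category and all subdivisions), Read entries verbatim.
matches_code_list <- function(events, cl) {
  hit <- rep(FALSE, nrow(events))
  icd_entries <- cl$entries$code[cl$entries$vocabulary == "ICD10"]
  read_entries <- cl$entries$code[cl$entries$vocabulary == "READ2"]
  if (length(icd_entries)) {
    is_icd <- events$vocabulary == "ICD10"
    for (code in normalize_icd10(icd_entries)) {
      hit <- hit | (is_icd & startsWith(events$code, code))
    }
  }
  if (length(read_entries)) {
    hit <- hit | (events$vocabulary == "READ2" &
                    events$code %in% read_entries)
  }
  hit
}

# earliest phenotype event date per patient (named Date vector)
first_phenotype_date <- function(events, cl) {
  af <- events[matches_code_list(events, cl), c("patient_id", "event_date")]
  if (!nrow(af)) {
    out <- as.Date(numeric(0), origin = "1970-01-01")
    names(out) <- character(0)
    return(out)
  }
  tapply_date <- tapply(af$event_date, af$patient_id, min)
  out <- as.Date(as.vector(tapply_date), origin = "1970-01-01")
  names(out) <- names(tapply_date)
  out
}
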