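# internal helpers shared across modules

# whole calendar days for a span expressed in years (CPRD-style granularity:
# dates only, no times)
year_days <- function(years) as.integer(round(years * 365.25))

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so pipeline stages cannot perturb each other
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage seed from the study seed; kept well inside 32-bit range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97L * offset) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_strict <- function(x, what = "date", row = NULL) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonblank <- !is.na(x) & nzchar(trimws(as.character(x)))
  if (any(nonblank)) {
    parsed <- as.Date(as.character(x[nonblank]), format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(nonblank)[which(is.na(parsed))[1L]]
      stopf("malformed %s %s at row %d", what, dQuote(as.character(x)[bad]),
            if (is.null(row)) bad else row[bad])
    }
    out[nonblank] <- parsed
  }
  out
}
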