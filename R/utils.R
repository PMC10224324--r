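#' Normalize an ICPC diagnosis code
#'
#' Trims whitespace and upper-cases. ICPC codes are one letter and two digits,
#' optionally followed by a dot and a two-digit sub-code (e.g. `"R75.01"`).
#'
#' @param code Character vector of raw codes.
#' @param strict If `TRUE`, codes that do not match the ICPC pattern raise an
#'   error; otherwise they are returned normalized as-is.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_icpc(" r75.01 ")  # "R75.01"
normalize_icpc <- function(code, strict = FALSE) {
  out <- toupper(trimws(as.character(code)))
  if (strict) {
    bad <- out[!is.na(out) & !grepl("^[A-Z][0-9]{2}(\\.[0-9]{2})?$", out)]
    if (length(bad) > 0) {
      abort(paste0("Invalid ICPC code(s): ", paste(unique(bad), collapse = ", ")))
    }
  }
  out
}

#' Normalize an ATC prescription code
#'
#' Trims and upper-cases; ATC level-5 codes are 7 characters
#' (e.g. `"J01CA04"`).
#'
#' @inheritParams normalize_icpc
#' @return Character vector of normalized codes.
#' @export
normalize_atc <- function(code, strict = FALSE) {
  out <- toupper(trimws(as.character(code)))
  if (strict) {
    bad <- out[!is.na(out) & !grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", out)]
    if (length(bad) > 0) {
      abort(paste0("Invalid ATC code(s): ", paste(unique(bad), collapse = ", ")))
    }
  }
  out
}

#' Age in whole years at a reference date
#'
#' Birthday-anniversary convention: the age increments on the calendar
#' anniversary of the birth date, matching routine clinical age.
#'
#' @param birth_date,ref_date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @export
#' @examples
#' age_at(as.Date("2000-06-15"), as.Date("2012-06-14"))  # 11
#' age_at(as.Date("2000-06-15"), as.Date("2012-06-15"))  # 12
age_at <- function(birth_date, ref_date) {
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(ref_date)
  years <- r$year - b$year
  before_anniv <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(years - before_anniv)
}

#' Anniversary of a birth date (handles Feb 29 birthdays)
#' @noRd
nth_birthday <- function(birth_date, n) {
  b <- as.POSIXlt(birth_date)
  b$year <- b$year + n
  out <- as.Date(b)
  # Feb 29 in a non-leap year rolls over to Mar 1 via POSIXlt arithmetic,
  # which is the convention we keep.
  out
}

#' Is a date inside the half-open window (end - days, end]?
#' @noRd
in_window <- function(date, end, days) {
  date > (end - days) & date <= end
}

as_date_strict <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    abort(paste0(
      "Unparseable date(s) in ", what, ": ",
      paste(head(unique(as.character(x)[bad]), 5), collapse = ", "),
      " (expected ISO-8601 YYYY-MM-DD)"
    ))
  }
  out
}
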