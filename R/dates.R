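#' Parse dates in dd/mm/yyyy format
#'
#' Converts character dates in the strict `dd/mm/yyyy` format used by the
#' climate and biological input tables into integer day ordinals (days since
#' 1970-01-01). Parsing is strict: two-digit day and month, four-digit year,
#' and the calendar date must exist (so `"31/02/2015"` is rejected rather
#' than rolled over).
#'
#' @param x character vector of dates in `dd/mm/yyyy` format.
#' @return integer vector of day ordinals; ordering matches calendar order
#'   and [format_ddmmyyyy()] round-trips back to the input.
#' @seealso [format_ddmmyyyy()], [apply_reference()]
#' @examples
#' parse_ddmmyyyy(c("01/01/2015", "02/02/2015"))
#' @export
parse_ddmmyyyy <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]{2}/[0-9]{2}/[0-9]{4}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%d/%m/%Y")
  bad <- which(is.na(d) | !ok)
  if (length(bad)) {
    stop("malformed or invalid dd/mm/yyyy date(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": ", paste(utils::head(x[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  as.integer(d)
}

#' Format day ordinals back to dd/mm/yyyy
#'
#' @param ord integer day ordinals (days since 1970-01-01).
#' @return character vector in `dd/mm/yyyy` format.
#' @export
format_ddmmyyyy <- function(ord) {
  format(as.Date(ord, origin = "1970-01-01"), "%d/%m/%Y")
}

#' Adjust biological dates to a reference day (absolute windows)
#'
#' For an absolute window analysis all records are assumed to respond to
#' climate anchored at the same calendar date each year: each record's date
#' is replaced by the reference day and month, keeping its year. For a
#' relative analysis dates are returned unchanged and windows count back
#' from each record's own measurement date.
#'
#' The replacement is applied verbatim even when the reference date falls
#' after the measurement date within that year; a warning is emitted because
#' such records are then regressed against climate they could not have
#' experienced, which is a biological-design problem rather than a
#' computational one.
#'
#' @param dates integer day ordinals (see [parse_ddmmyyyy()]).
#' @param type `"absolute"` or `"relative"`.
#' @param refday integer vector `c(day, month)`; required for absolute.
#' @return integer vector of adjusted day ordinals.
#' @export
apply_reference <- function(dates, type = c("relative", "absolute"),
                            refday = NULL) {
  type <- match.arg(type)
  dates <- as.integer(dates)
  if (type == "relative") return(dates)
  if (is.null(refday) || length(refday) != 2L || anyNA(refday)) {
    stop("absolute windows require refday = c(day, month)", call. = FALSE)
  }
  yr <- as.integer(format(as.Date(dates, origin = "1970-01-01"), "%Y"))
  adj <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", yr, refday[2L],
                                  refday[1L])),
                  error = function(e) as.Date(NA))
  if (anyNA(adj)) {
    stop("refday c(", refday[1L], ", ", refday[2L],
         ") is not a valid calendar date in every year of the data",
         call. = FALSE)
  }
  adj <- as.integer(adj)
  n_after <- sum(adj > dates)
  if (n_after > 0L) {
    warning(n_after, " record(s) measured before the reference date in ",
            "their year; their climate window extends past the measurement",
            call. = FALSE)
  }
  adj
}
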