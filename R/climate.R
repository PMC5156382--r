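#' Construct a daily climate series
#'
#' @param dates dates of the daily climate observations: `Date`, integer
#'   day ordinals, or character in `dd/mm/yyyy`.
#' @param values numeric climate measurements (one per date).
#' @param varname name of the climate variable (used in output labels).
#' @return a `climate_series`: a data frame with integer column `date` and
#'   numeric column `value`, sorted and validated to hold at most one value
#'   per day.
#' @export
climate_series <- function(dates, values, varname = "climate") {
  date <- coerce_ordinal(dates)
  values <- as.numeric(values)
  if (length(date) != length(values)) {
    stop("dates and values must have equal length", call. = FALSE)
  }
  if (anyNA(values)) stop("climate values contain NA", call. = FALSE)
  o <- order(date)
  date <- date[o]; values <- values[o]
  if (anyDuplicated(date)) {
    stop("duplicate climate dates: ",
         paste(utils::head(format_ddmmyyyy(date[duplicated(date)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  structure(data.frame(date = date, value = values),
            varname = varname, class = c("climate_series", "data.frame"))
}

#' Construct a biological response table
#'
#' @param dates measurement dates (`Date`, day ordinals, or `dd/mm/yyyy`).
#' @param response numeric, count, or 0/1 response values; no missing
#'   values allowed.
#' @param covariates optional data frame of numeric covariate columns.
#' @param group optional grouping labels (site, year, ...) used by
#'   within-group centring.
#' @return a `biol_table` data frame with columns `date`, `response`,
#'   covariates, and optionally `group`.
#' @export
biol_table <- function(dates, response, covariates = NULL, group = NULL) {
  date <- coerce_ordinal(dates)
  if (anyNA(response)) stop("response contains missing values", call. = FALSE)
  out <- data.frame(date = date, response = response)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(out)) {
      stop("covariates must have one row per record", call. = FALSE)
    }
    out <- cbind(out, covariates)
  }
  if (!is.null(group)) {
    if (anyNA(group)) stop("group labels contain missing values", call. = FALSE)
    out$group <- group
  }
  structure(out, class = c("biol_table", "data.frame"))
}

coerce_ordinal <- function(dates) {
  if (inherits(dates, "Date")) return(as.integer(dates))
  if (is.numeric(dates)) return(as.integer(dates))
  parse_ddmmyyyy(dates)
}

#' Build the lagged climate matrix
#'
#' Row r, column j holds the climate value observed j days before record
#' r's (possibly reference-adjusted) date, for offsets 0..`range_max`.
#' Column 0 is the adjusted date itself.
#'
#' @param series a [climate_series()].
#' @param adjusted integer day ordinals of the (adjusted) biological
#'   records.
#' @param range_max largest offset (days before the adjusted date).
#' @return numeric matrix with `length(adjusted)` rows and `range_max + 1`
#'   columns; attribute `offsets` holds `0:range_max`.
#' @export
climate_matrix <- function(series, adjusted, range_max) {
  stopifnot(inherits(series, "climate_series"))
  adjusted <- as.integer(adjusted)
  range_max <- as.integer(range_max)
  if (range_max < 0L) stop("range_max must be >= 0", call. = FALSE)
  lo <- min(adjusted) - range_max
  hi <- max(adjusted)
  if (min(series$date) > lo || max(series$date) < hi) {
    stop("climate series does not span the required period ",
         format_ddmmyyyy(lo), " to ", format_ddmmyyyy(hi), call. = FALSE)
  }
  offsets <- 0:range_max
  need <- outer(adjusted, offsets, `-`)
  idx <- match(need, series$date)
  if (anyNA(idx)) {
    miss <- sort(unique(need[is.na(idx)]))
    stop("missing climate day(s) in required span: ",
         paste(utils::head(format_ddmmyyyy(miss), 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L),
         call. = FALSE)
  }
  m <- matrix(series$value[idx], nrow = length(adjusted))
  attr(m, "offsets") <- offsets
  m
}

#' Collapse a daily climate matrix to week or month blocks
#'
#' Blocks are counted backwards from each record's adjusted date: block 0
#' is the 7-day (or calendar-month) period ending on the adjusted date,
#' block 1 the period before that, and so on. The block value is the mean
#' of its member days, so windowing on blocks preserves the "time before
#' measurement" semantics of the daily matrix at a coarser resolution.
#'
#' @param cmat daily climate matrix from [climate_matrix()].
#' @param cinterval `"week"` or `"month"`.
#' @param adjusted adjusted day ordinals (needed for calendar months).
#' @return matrix of block means, one column per whole block that fits in
#'   the daily range.
#' @export
collapse_cinterval <- function(cmat, cinterval = c("week", "month"),
                               adjusted = NULL) {
  cinterval <- match.arg(cinterval)
  nd <- ncol(cmat)
  if (cinterval == "week") {
    nb <- nd %/% 7L
    if (nb < 1L) stop("daily range too short for one week block", call. = FALSE)
    out <- sapply(seq_len(nb) - 1L, function(b) {
      rowMeans(cmat[, (7L * b + 1L):(7L * b + 7L), drop = FALSE])
    })
    out <- matrix(out, nrow = nrow(cmat))
  } else {
    if (is.null(adjusted)) stop("month blocks need the adjusted dates", call. = FALSE)
    # per-record calendar months: block b covers (d0 - (b+1) months,
    # d0 - b months], with month-end days clamped (not rolled over)
    nb_max <- nd %/% 31L
    if (nb_max < 1L) stop("daily range too short for one month block", call. = FALSE)
    out <- matrix(NA_real_, nrow = nrow(cmat), ncol = nb_max)
    for (r in seq_len(nrow(cmat))) {
      d0 <- as.Date(adjusted[r], origin = "1970-01-01")
      for (b in seq_len(nb_max) - 1L) {
        hi <- shift_months(d0, b)
        lo <- shift_months(d0, b + 1L)
        o_from <- as.integer(d0 - hi)
        o_to <- as.integer(d0 - lo) - 1L
        if (o_to >= nd) next
        out[r, b + 1L] <- mean(cmat[r, (o_from + 1L):(o_to + 1L)])
      }
    }
    if (anyNA(out)) {
      keep <- !apply(is.na(out), 2L, any)
      out <- out[, keep, drop = FALSE]
    }
  }
  attr(out, "offsets") <- 0:(ncol(out) - 1L)
  out
}

# shift a date back by b calendar months, clamping to the last day of the
# target month instead of rolling over
shift_months <- function(d, b) {
  lt <- as.POSIXlt(d)
  tot <- lt$year * 12L + lt$mon - as.integer(b)
  y <- tot %/% 12L + 1900L
  m <- tot %% 12L + 1L
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  if (m == 2L && ((y %% 4L == 0L && y %% 100L != 0L) || y %% 400L == 0L)) {
    last <- 29L
  }
  as.Date(sprintf("%04d-%02d-%02d", y, m, min(lt$mday, last)))
}

#' Aggregate climate over one window
#'
#' Applies the aggregate statistic row-wise over the columns of the climate
#' matrix between offsets `end` and `start` (inclusive; `start` is further
#' in the past). `stat = "slope"` is the least-squares slope of climate
#' against calendar time within the window, in climate units per day, so a
#' positive slope means climate increasing towards the measurement date. A
#' single-day window has slope 0 by convention.
#'
#' @param cmat climate matrix ([climate_matrix()] or block matrix).
#' @param start,end integer window offsets, `start >= end >= 0`.
#' @param stat one of `"mean"`, `"max"`, `"min"`, `"sum"`, `"slope"`.
#' @return numeric vector with one aggregate per record.
#' @export
aggregate_window <- function(cmat, start, end,
                             stat = c("mean", "max", "min", "sum", "slope")) {
  stat <- match.arg(stat)
  start <- as.integer(start); end <- as.integer(end)
  if (start < end) stop("invalid window: start < end", call. = FALSE)
  if (end < 0L || start > ncol(cmat) - 1L) {
    stop("window outside matrix offsets 0..", ncol(cmat) - 1L, call. = FALSE)
  }
  sub <- cmat[, (end + 1L):(start + 1L), drop = FALSE]
  switch(stat,
    mean = rowMeans(sub),
    sum  = rowSums(sub),
    max  = do.call(pmax, as.data.frame(sub)),
    min  = do.call(pmin, as.data.frame(sub)),
    slope = {
      k <- ncol(sub)
      if (k == 1L) return(rep(0, nrow(sub)))
      tt <- -(end:start)                 # calendar time, days
      tc <- tt - mean(tt)
      drop(sub %*% tc) / sum(tc^2)
    })
}

#' Within-group centring of a climate aggregate
#'
#' Splits an aggregated climate vector into group means and within-group
#' deviations, so between- and within-group climatic effects can be
#' estimated separately. Deviation plus group mean reconstructs the input
#' exactly and deviations sum to zero within each group.
#'
#' @param x numeric aggregate vector.
#' @param group group labels, one per element, no missing values.
#' @return list with components `deviation` and `mean` (both length of `x`).
#' @export
centre_split <- function(x, group) {
  if (missing(group) || is.null(group)) stop("group labels required", call. = FALSE)
  if (length(group) != length(x)) stop("group must match x in length", call. = FALSE)
  if (anyNA(group)) stop("missing group label(s)", call. = FALSE)
  gm <- stats::ave(x, group)
  list(deviation = x - gm, mean = gm)
}
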