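#' Partial calendar dates
#'
#' Spontaneous-report databases record dates at whatever precision the
#' reporter supplied: a full day, a year-month, a year alone, or nothing.
#' Dates are carried through the package as compact digit strings
#' (\code{"YYYYMMDD"}, \code{"YYYYMM"}, \code{"YYYY"}, or \code{""}),
#' and parsed on demand into year/month/day components plus a precision
#' level. Parsing never fails: a malformed component degrades the
#' precision (an impossible day drops the string to month precision, an
#' impossible month to year precision) rather than raising an error,
#' because the time-to-onset stage -- not the reader -- decides whether a
#' reduced-precision date is usable.
#'
#' @param x character vector of date strings. Separators (\code{-},
#'   \code{/}, \code{.}) are tolerated and stripped.
#' @return a data.frame with one row per input and columns \code{year},
#'   \code{month}, \code{day} (integer, \code{NA} when absent),
#'   \code{precision} (one of \code{"day"}, \code{"month"},
#'   \code{"year"}, \code{"missing"}) and \code{date} (a \code{Date},
#'   \code{NA} unless precision is \code{"day"}).
#' @examples
#' parsePartialDate(c("20200110", "202001", "2020", "", "20200230"))
#' @export
parsePartialDate <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  digits <- gsub("[-/. ]", "", x)
  digits[!grepl("^[0-9]*$", digits)] <- ""

  n <- length(digits)
  year <- month <- day <- rep(NA_integer_, n)
  nc <- nchar(digits)

  hasY <- nc >= 4
  year[hasY] <- as.integer(substr(digits[hasY], 1, 4))
  hasM <- nc >= 6
  month[hasM] <- as.integer(substr(digits[hasM], 5, 6))
  hasD <- nc >= 8
  day[hasD] <- as.integer(substr(digits[hasD], 7, 8))

  # degrade rather than error: bad day -> month precision, bad month -> year
  badMonth <- !is.na(month) & (month < 1 | month > 12)
  month[badMonth] <- NA_integer_
  day[badMonth] <- NA_integer_
  badDay <- !is.na(day) & (day < 1 | day > 31)
  day[badDay] <- NA_integer_

  date <- rep(as.Date(NA), n)
  full <- !is.na(day)
  if (any(full)) {
    cand <- as.Date(sprintf("%04d-%02d-%02d", year[full], month[full],
                            day[full]), format = "%Y-%m-%d")
    # as.Date returns NA for impossible calendar dates (e.g. Feb 30)
    day[full][is.na(cand)] <- NA_integer_
    date[full] <- cand
  }

  precision <- rep("missing", n)
  precision[!is.na(year)] <- "year"
  precision[!is.na(year) & !is.na(month)] <- "month"
  precision[!is.na(date)] <- "day"

  data.frame(year = year, month = month, day = day,
             precision = precision, date = date,
             stringsAsFactors = FALSE)
}

#' Format partial-date components back to the compact string form
#'
#' Inverse of [parsePartialDate()] at the precision retained, so that a
#' read/write round trip preserves every date field-for-field.
#'
#' @param parsed a data.frame as returned by [parsePartialDate()].
#' @return character vector of compact date strings.
#' @export
formatPartialDate <- function(parsed) {
  out <- character(nrow(parsed))
  p <- parsed$precision
  out[p == "year"] <- sprintf("%04d", parsed$year[p == "year"])
  out[p == "month"] <- sprintf("%04d%02d", parsed$year[p == "month"],
                               parsed$month[p == "month"])
  out[p == "day"] <- sprintf("%04d%02d%02d", parsed$year[p == "day"],
                             parsed$month[p == "day"], parsed$day[p == "day"])
  out
}

# canonicalize raw date strings: parse and re-format, so downstream code
# can rely on the compact representation
normalizeDateString <- function(x) formatPartialDate(parsePartialDate(x))
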