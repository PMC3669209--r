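#' Calendar-month time stamps
#'
#' The claims system records every event at calendar-month resolution, so all
#' dates in this package are month stamps: a year plus a month 1--12.  A
#' `ym` object is an integer vector counting months since January of year 0,
#' which makes ordering and whole-month differences ordinary integer
#' arithmetic.
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of months (1--12), recycled against `year`.
#' @return An integer vector of class `"ym"`.
#' @examples
#' ym(2009, 8) - ym(2009, 1)   # 7 whole months
#' ym_parse("2005-01") < ym(2009, 8)
#' @export
ym <- function(year, month) {
  if (any(month < 1 | month > 12, na.rm = TRUE))
    stop("month must be between 1 and 12", call. = FALSE)
  new_ym(as.integer(year) * 12L + as.integer(month) - 1L)
}

new_ym <- function(x) structure(as.integer(x), class = "ym")

#' Parse "YYYY-MM" strings into month stamps
#'
#' Day-level dates ("YYYY-MM-DD") are truncated to the month, with a message,
#' since the claims system is monthly.  Blank strings and `NA` parse to `NA`.
#'
#' @param x character vector.
#' @return A `ym` vector with `NA` for blank/missing input.
#' @export
ym_parse <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  x2 <- trimws(x[!blank])
  daylevel <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x2)
  if (any(daylevel)) {
    message(sum(daylevel), " day-level date(s) truncated to month")
    x2[daylevel] <- substr(x2[daylevel], 1, 7)
  }
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", x2)
  if (any(!ok))
    stop("unparseable month stamp(s): ",
         paste(utils::head(x2[!ok], 5), collapse = ", "), call. = FALSE)
  out[!blank] <- as.integer(substr(x2, 1, 4)) * 12L +
    as.integer(substr(x2, 6, 7)) - 1L
  new_ym(out)
}

#' @export
format.ym <- function(x, ...) {
  ifelse(is.na(unclass(x)), NA_character_,
         sprintf("%04d-%02d", unclass(x) %/% 12L, unclass(x) %% 12L + 1L))
}

#' @export
print.ym <- function(x, ...) {
  print(format(x), ...)
  invisible(x)
}

#' @export
as.character.ym <- function(x, ...) format(x)

#' @export
`[.ym` <- function(x, i) new_ym(unclass(x)[i])

#' @export
c.ym <- function(...) new_ym(unlist(lapply(list(...), unclass)))

#' @export
Ops.ym <- function(e1, e2) {
  out <- get(.Generic)(unclass(e1), unclass(e2))
  # sums/differences are plain month counts, comparisons are logical
  out
}

#' Extract the calendar year or month from a month stamp
#' @param x a `ym` vector.
#' @return Integer vector of years (`ym_year`) or months 1--12 (`ym_month`).
#' @export
ym_year <- function(x) unclass(x) %/% 12L

#' @rdname ym_year
#' @export
ym_month <- function(x) unclass(x) %% 12L + 1L
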