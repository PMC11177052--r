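# Timestamp conventions
#
# All clock times in the package are timezone-naive local times at second
# resolution (EHR exports carry date-shifted local timestamps; the phenomenon
# under study is anchored to local clock time). Internally they are POSIXct
# in UTC so that arithmetic is immune to DST; UTC is an implementation
# carrier, not a claim about the wall clock.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Parse ISO-8601 timestamps (`YYYY-MM-DDTHH:MM:SS`)
#'
#' @param x Character vector. `NA` and empty strings give `NA`.
#' @return POSIXct vector (timezone-naive convention, carried as UTC).
#' @export
#' @examples
#' parse_timestamp("2120-03-01T10:00:00")
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(
      sprintf(
        "unparseable timestamp(s) at position(s) %s (expected %s): e.g. '%s'",
        paste(head(which(bad), 5L), collapse = ", "),
        "YYYY-MM-DDTHH:MM:SS", x[which(bad)[1L]]
      ),
      class = "glucirc_timestamp_error"
    )
  }
  out
}

#' Format POSIXct as ISO-8601 `YYYY-MM-DDTHH:MM:SS`
#' @param x POSIXct vector.
#' @return Character vector.
#' @export
format_timestamp <- function(x) {
  format(x, format = TS_FORMAT, tz = "UTC")
}

#' Hour of day (0-23) by rounding down to the whole hour
#'
#' Time of day is binned by flooring the timestamp to the integer hour on a
#' 0-23 scale.
#'
#' @param x POSIXct vector.
#' @return Integer vector in 0..23.
#' @export
#' @examples
#' hour_of_day(as.POSIXct("2120-01-01 10:59:59", tz = "UTC"))
hour_of_day <- function(x) {
  as.integer(format(x, "%H", tz = "UTC"))
}

#' Difference between timestamps in hours
#' @noRd
diff_hours <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

#' Difference between timestamps in days
#' @noRd
diff_days <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days"))
}
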