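#' Parse clock times to minutes from midnight
#'
#' Clock times are held internally as integer minutes from midnight in
#' `[0, 1440)`. Inputs may be `"HH:MM"` strings (24-hour), numeric hours in
#' `[0, 24)`, or already-integer minutes when `units = "minutes"`.
#'
#' @param x character `"HH:MM"` vector or numeric vector.
#' @param units for numeric input, `"hours"` (default) or `"minutes"`.
#' @return integer minutes from midnight.
#' @examples
#' parseClockTime("23:30")
#' parseClockTime(c("07:00", "00:15"))
#' @export
parseClockTime <- function(x, units = c("hours", "minutes")) {
  units <- match.arg(units)
  if (is.numeric(x)) {
    m <- if (units == "hours") x * 60 else x
    m <- round(m)
  } else {
    x <- as.character(x)
    ok <- is.na(x) | grepl("^\\s*([01]?[0-9]|2[0-3]):[0-5][0-9]\\s*$", x)
    if (!all(ok)) {
      stop("malformed clock time(s): ",
           paste(utils::head(x[!ok], 5L), collapse = ", "))
    }
    hh <- as.integer(sub(":.*", "", x))
    mm <- as.integer(sub(".*:", "", x))
    m <- hh * 60L + mm
  }
  out <- as.integer(m %% 1440)
  out
}

#' Format minutes from midnight as "HH:MM"
#'
#' @param m integer minutes from midnight (reduced modulo 24 h first).
#' @return character vector of `"HH:MM"` strings.
#' @export
formatClockTime <- function(m) {
  m <- as.integer(round(m)) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# Signed circular difference b - a in minutes, representative in (-720, 720].
circularDiffMinutes <- function(a, b) {
  d <- (b - a) %% 1440
  ifelse(d > 720, d - 1440, d)
}
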