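#' Incremental area under a postprandial curve
#'
#' Baseline-subtracted trapezoidal area over `[0, horizon]` minutes. In
#' `positive_only` mode (Wolever-style, the default) segments below baseline
#' contribute zero, with baseline crossings located by linear interpolation;
#' in `net` mode the signed area is returned.
#'
#' @param minutes sampling times in minutes, strictly increasing, including 0.
#' @param values concentrations at `minutes`.
#' @param horizon minutes; 120 for 2 h or 360 for 6 h areas (any positive
#'   horizon not beyond the last sample is accepted).
#' @param mode `"positive_only"` or `"net"`.
#' @param baseline baseline concentration; defaults to the value at t = 0.
#' @return area in concentration x minutes.
#' @examples
#' incrementalAuc(c(0, 60, 120), c(5, 7, 5), horizon = 120)     # 120
#' incrementalAuc(c(0, 60, 120), c(5, 3, 5), 120, mode = "net") # -120
#' @export
incrementalAuc <- function(minutes, values, horizon = 120,
                           mode = c("positive_only", "net"),
                           baseline = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(minutes) == length(values))
  o <- order(minutes)
  minutes <- minutes[o]; values <- values[o]
  if (anyDuplicated(minutes)) stop("duplicate time points")
  if (minutes[1L] != 0) stop("series must include a t = 0 baseline sample")
  if (horizon <= 0) stop("horizon must be positive")
  if (horizon > max(minutes)) stop("horizon beyond last sample")
  keep <- minutes <= horizon
  if (sum(keep) < 2L) stop("need at least two samples within the horizon")
  t <- minutes[keep]
  y <- values[keep]
  if (max(t) < horizon) {  # interpolate the horizon endpoint
    yh <- stats::approx(minutes, values, xout = horizon)$y
    t <- c(t, horizon); y <- c(y, yh)
  }
  if (is.null(baseline)) baseline <- y[1L]
  d <- y - baseline
  area <- 0
  for (i in seq_len(length(t) - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]; d1 <- d[i]; d2 <- d[i + 1L]
    if (mode == "net") {
      area <- area + (d1 + d2) / 2 * (t2 - t1)
    } else {
      if (d1 >= 0 && d2 >= 0) {
        area <- area + (d1 + d2) / 2 * (t2 - t1)
      } else if (d1 <= 0 && d2 <= 0) {
        # fully below baseline: contributes nothing
      } else {
        tc <- t1 + (t2 - t1) * d1 / (d1 - d2)  # baseline crossing
        if (d1 > 0) area <- area + d1 / 2 * (tc - t1)
        else area <- area + d2 / 2 * (t2 - tc)
      }
    }
  }
  area
}

#' Postprandial GlycA rise
#'
#' The 6 h rise of the NMR inflammation marker GlycA: the 6 h value minus
#' the fasting value; negative when GlycA falls below fasting.
#'
#' @param fasting,value6h concentrations, mmol/L.
#' @return mmol/L.
#' @export
glycaRise <- function(fasting, value6h) {
  value6h - fasting
}

#' Glycemic variability and time-in-range from a CGM trace
#'
#' Readings within `discardHours` (default 12 h) of the device-fit time are
#' discarded (sensor calibration); over the retained readings, CV is
#' `100 * SD / mean` (sample SD) and TIR the percentage within the closed
#' range `[rangeLow, rangeHigh]` (defaults 3.9-5.6 mmol/L). Missing readings
#' are skipped, not imputed.
#'
#' @param timestamps reading times, `POSIXct` or numeric hours from device
#'   fit.
#' @param glucose readings, mmol/L.
#' @param deviceFit device-fit time; defaults to the first timestamp.
#' @param rangeLow,rangeHigh mmol/L bounds of the target range.
#' @param discardHours hours discarded after device fit.
#' @return data.frame with `cv_pct`, `tir_pct`, `n_used`.
#' @examples
#' cgmMetrics(seq(0, 48, by = 0.25), rep(5, 193))
#' @export
cgmMetrics <- function(timestamps, glucose, deviceFit = NULL,
                       rangeLow = 3.9, rangeHigh = 5.6, discardHours = 12) {
  stopifnot(length(timestamps) == length(glucose))
  if (inherits(timestamps, "POSIXt")) {
    if (is.null(deviceFit)) deviceFit <- min(timestamps)
    hrs <- as.numeric(difftime(timestamps, deviceFit, units = "hours"))
  } else {
    if (is.null(deviceFit)) deviceFit <- min(timestamps, na.rm = TRUE)
    hrs <- as.numeric(timestamps) - as.numeric(deviceFit)
  }
  keep <- hrs >= discardHours & !is.na(glucose)
  g <- glucose[keep]
  if (length(g) == 0L)
    stop("no usable CGM data: all readings fall within the ",
         discardHours, " h discard window")
  if (any(g <= 0)) stop("glucose readings must be positive")
  cv <- if (length(g) >= 2L) 100 * stats::sd(g) / mean(g) else 0
  tir <- 100 * mean(g >= rangeLow & g <= rangeHigh)
  data.frame(cv_pct = cv, tir_pct = tir, n_used = length(g))
}
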