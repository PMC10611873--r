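#' Mid-sleep point of a bed/wake interval
#'
#' The mid-sleep point is the clock time halfway between sleep onset (bed
#' time) and offset (wake time). When the wake time is at or before the bed
#' time on the clock, the wake time is taken to fall on the next day; the
#' midpoint is then reduced modulo 24 h.
#'
#' @param bed,wake clock times (`"HH:MM"` strings or numeric hours).
#' @return numeric hours in `[0, 24)`; the mid-sleep clock time.
#' @examples
#' midSleep("23:00", "07:00")  # 3
#' midSleep("01:00", "09:30")  # 5.25
#' @seealso [sleepDuration()], [socialJetlag()], [chronotype()]
#' @export
midSleep <- function(bed, wake) {
  b <- parseClockTime(bed)
  w <- parseClockTime(wake)
  w <- ifelse(w <= b, w + 1440L, w)
  (((b + w) / 2) %% 1440) / 60
}

#' Time in bed between bed and wake times
#'
#' @inheritParams midSleep
#' @return numeric hours in `(0, 24]`. Duration is time in bed; sleep
#'   latency is not modelled.
#' @export
sleepDuration <- function(bed, wake) {
  b <- parseClockTime(bed)
  w <- parseClockTime(wake)
  w <- ifelse(w <= b, w + 1440L, w)
  (w - b) / 60
}

#' Social jetlag from weekday and weekend mid-sleep points
#'
#' Social jetlag (SJL) is the difference between the weekend and weekday
#' mid-sleep points, in hours, computed on the circular clock scale with the
#' representative chosen in `(-12, +12]`. Participants at or above the
#' `threshold` (default 1.5 h) are flagged as having SJL. Negative values
#' (weekday mid-sleep later than weekend) are returned as-is and are meant
#' to be excluded, not truncated.
#'
#' @param weekMid,weekendMid mid-sleep clock times (hours or `"HH:MM"`).
#' @param threshold hours; SJL flag cut-off (inclusive). Default 1.5.
#' @return data.frame with columns `sjl` (hours, signed) and `sjl_flag`.
#' @examples
#' socialJetlag(3, 5.25)     # 2.25 h, flagged
#' socialJetlag(4, 3)        # -1 h: to be excluded downstream
#' @export
socialJetlag <- function(weekMid, weekendMid, threshold = 1.5) {
  a <- parseClockTime(weekMid)
  b <- parseClockTime(weekendMid)
  d <- circularDiffMinutes(a, b) / 60
  data.frame(sjl = d, sjl_flag = d >= threshold)
}

#' Habitual sleep duration and its category
#'
#' The unweighted mean of weekday and weekend durations; short sleep is
#' < 7 h per night, average 7-9 h, long > 9 h.
#'
#' @param weekHours,weekendHours sleep durations in hours.
#' @return data.frame with `habitual_h` and `duration_category`
#'   (factor: short / average / long).
#' @examples
#' habitualDuration(8.1, 8.7)  # 8.4 h, average
#' @export
habitualDuration <- function(weekHours, weekendHours) {
  stopifnot(all(weekHours > 0, na.rm = TRUE),
            all(weekendHours > 0, na.rm = TRUE))
  h <- (weekHours + weekendHours) / 2
  cat_ <- cut(h, breaks = c(-Inf, 7, 9, Inf), labels = c("short", "average", "long"),
              right = FALSE)
  cat_[!is.na(h) & h == 9] <- "average"  # 7-9 h inclusive on both ends
  data.frame(habitual_h = h, duration_category = cat_)
}

#' Chronotype as the weekend mid-sleep time
#'
#' Later values indicate later chronotypes ("night types").
#'
#' @param weekendBed,weekendWake weekend bed and wake clock times.
#' @return numeric hours in `[0, 24)`.
#' @examples
#' chronotype("01:00", "08:00")  # 4.5 -> 04:30
#' @export
chronotype <- function(weekendBed, weekendWake) {
  midSleep(weekendBed, weekendWake)
}

# Exclusion rules, applied in the order the cohort pipeline uses them.
.sleepExclusionLevels <- c("missing", "daytime_onset", "late_offset",
                           "implausible_duration", "negative_sjl")

#' Derive sleep metrics from questionnaire records, applying exclusions
#'
#' From weekday/weekend bed and wake times computes mid-sleep points, time
#' in bed, social jetlag, chronotype and the habitual-duration category,
#' removing records in order when (1) any time is missing, (2) sleep onset
#' falls in daytime (`[08:00, 17:00)`), (3) sleep offset falls after noon,
#' (4) time in bed is < 2 h or > 15 h on either day type, or (5) SJL is
#' negative. Excluded records are retained in the output with an
#' `exclusion_reason` and no SJL flag.
#'
#' @param sleep data.frame with columns `participant_id`,
#'   `bed_week`, `wake_week`, `bed_weekend`, `wake_weekend` (clock times)
#'   and optionally `psqi`.
#' @param sjlThreshold hours; SJL categorisation cut-off. Default 1.5.
#' @return list with `derived` (one row per input record; retained rows have
#'   `included = TRUE`) and `exclusions` (data.frame of per-rule counts, in
#'   rule order, with remaining n).
#' @examples
#' q <- data.frame(participant_id = "p1", bed_week = "23:30",
#'                 wake_week = "07:30", bed_weekend = "01:00",
#'                 wake_weekend = "09:30")
#' deriveSleep(q)$derived[, c("sjl", "sjl_flag")]
#' @export
deriveSleep <- function(sleep, sjlThreshold = 1.5) {
  need <- c("participant_id", "bed_week", "wake_week", "bed_weekend",
            "wake_weekend")
  miss <- setdiff(need, names(sleep))
  if (length(miss)) stop("sleep table lacks column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(sleep)
  reason <- rep(NA_character_, n)

  timecols <- need[-1]
  missing_any <- Reduce(`|`, lapply(sleep[timecols], function(x)
    is.na(x) | (!is.numeric(x) & !nzchar(as.character(x)))))
  reason[missing_any] <- "missing"

  # parse only parseable rows; keep vectors full length
  pt <- function(col) {
    out <- rep(NA_integer_, n)
    idx <- !missing_any
    out[idx] <- parseClockTime(sleep[[col]][idx])
    out
  }
  bw <- pt("bed_week"); ww <- pt("wake_week")
  be <- pt("bed_weekend"); we <- pt("wake_weekend")

  onset_day <- (bw >= 480L & bw < 1020L) | (be >= 480L & be < 1020L)
  idx <- is.na(reason) & !is.na(onset_day) & onset_day
  reason[idx] <- "daytime_onset"

  # offset after 12:00 noon on the 24 h clock; early-morning wake times
  # past midnight map below noon and are retained
  offset_late <- (ww > 720L) | (we > 720L)
  idx <- is.na(reason) & !is.na(offset_late) & offset_late
  reason[idx] <- "late_offset"

  dur_wk <- sleepDuration(bw / 60, ww / 60)
  dur_we <- sleepDuration(be / 60, we / 60)
  implaus <- (dur_wk < 2 | dur_wk > 15) | (dur_we < 2 | dur_we > 15)
  idx <- is.na(reason) & !is.na(implaus) & implaus
  reason[idx] <- "implausible_duration"

  mid_wk <- midSleep(bw / 60, ww / 60)
  mid_we <- midSleep(be / 60, we / 60)
  sj <- socialJetlag(mid_wk, mid_we, threshold = sjlThreshold)
  idx <- is.na(reason) & !is.na(sj$sjl) & sj$sjl < 0
  reason[idx] <- "negative_sjl"

  included <- is.na(reason)
  hab <- habitualDuration(pmax(dur_wk, 1e-9), pmax(dur_we, 1e-9))

  derived <- data.frame(
    participant_id = sleep$participant_id,
    mid_sleep_week = ifelse(included, mid_wk, NA_real_),
    mid_sleep_weekend = ifelse(included, mid_we, NA_real_),
    sjl = ifelse(included, sj$sjl, NA_real_),
    sjl_flag = ifelse(included, sj$sjl_flag, NA),
    chronotype = ifelse(included, mid_we, NA_real_),
    duration_week_h = ifelse(included, dur_wk, NA_real_),
    duration_weekend_h = ifelse(included, dur_we, NA_real_),
    habitual_h = ifelse(included, hab$habitual_h, NA_real_),
    duration_category = ifelse(included,
                               as.character(hab$duration_category),
                               NA_character_),
    included = included,
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  if ("psqi" %in% names(sleep)) derived$psqi <- sleep$psqi

  counts <- vapply(.sleepExclusionLevels, function(r)
    sum(reason == r, na.rm = TRUE), integer(1))
  exclusions <- data.frame(rule = .sleepExclusionLevels,
                           n_removed = counts,
                           n_remaining = n - cumsum(counts))
  list(derived = derived, exclusions = exclusions)
}
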