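#' Segment time-stamped meal events into eating occasions
#'
#' Consecutive logged intake events separated by less than `gapMin` minutes
#' are chained into one eating occasion (EO). After chaining, occasions whose
#' merged energy is below `kcalFloor` are discarded. Surviving occasions are
#' classified as main meals when their energy reaches the sex-specific
#' threshold (>= 400 kcal for females, >= 500 kcal for males), else snacks.
#'
#' Events must belong to one participant-day and are sorted by time. Times
#' are clock times; an event stream is treated on the unwrapped axis of the
#' day it is given (no cross-midnight chaining).
#'
#' @param times event clock times (`"HH:MM"` or numeric hours).
#' @param kcal event energies, kcal, non-negative.
#' @param sex `"female"` or `"male"` (codes `"F"`/`"M"` accepted).
#' @param gapMin minutes; minimum separation defining a new occasion.
#'   Default 30.
#' @param kcalFloor kcal; minimum merged occasion energy. Default 50.
#' @param mainKcal named vector of main-meal thresholds,
#'   `c(female = 400, male = 500)`.
#' @return data.frame with one row per occasion: `start_h`, `end_h`,
#'   `kcal`, `n_events`, `class` (`main_meal` / `snack`).
#' @examples
#' segmentEatingOccasions(c("08:00", "08:20", "13:00"),
#'                        c(300, 150, 600), sex = "female")
#' @export
segmentEatingOccasions <- function(times, kcal, sex,
                                   gapMin = 30, kcalFloor = 50,
                                   mainKcal = c(female = 400, male = 500)) {
  sex <- .normalizeSex(sex)
  stopifnot(length(times) == length(kcal), all(kcal >= 0))
  if (length(times) == 0L)
    return(data.frame(start_h = numeric(), end_h = numeric(),
                      kcal = numeric(), n_events = integer(),
                      class = character()))
  t_min <- as.numeric(parseClockTime(times))
  o <- order(t_min)
  t_min <- t_min[o]; kcal <- kcal[o]
  newocc <- c(TRUE, diff(t_min) >= gapMin)
  occ <- cumsum(newocc)
  agg <- data.frame(
    start_h = tapply(t_min, occ, min) / 60,
    end_h = tapply(t_min, occ, max) / 60,
    kcal = as.numeric(tapply(kcal, occ, sum)),
    n_events = as.integer(tapply(kcal, occ, length))
  )
  agg <- agg[agg$kcal >= kcalFloor, , drop = FALSE]
  thr <- mainKcal[[sex]]
  agg$class <- c("snack", "main_meal")[(agg$kcal >= thr) + 1L]
  rownames(agg) <- NULL
  agg
}

.normalizeSex <- function(sex) {
  s <- tolower(as.character(sex[1L]))
  if (s %in% c("f", "female")) return("female")
  if (s %in% c("m", "male")) return("male")
  stop("unknown sex code: ", sex)
}

#' Per-day eating-timing features from segmented occasions
#'
#' First and last eating-occasion times are the start times of the first and
#' last occasion; the eating window is their difference, the fasting window
#' its 24 h complement, and the eating midpoint lies halfway between them.
#'
#' @param occasions data.frame as returned by [segmentEatingOccasions()].
#' @return one-row data.frame of day features; if no occasions survive, the
#'   day is marked invalid (`valid_day = FALSE`, features `NA`).
#' @examples
#' occ <- segmentEatingOccasions(c("08:00", "20:00"), c(500, 700), "male")
#' dayFeatures(occ)
#' @export
dayFeatures <- function(occasions) {
  if (nrow(occasions) == 0L) {
    return(data.frame(n_eo = 0L, n_main = 0L, n_snack = 0L,
                      first_eo_h = NA_real_, last_eo_h = NA_real_,
                      eating_window_h = NA_real_, fasting_window_h = NA_real_,
                      eating_midpoint_h = NA_real_, total_kcal = NA_real_,
                      valid_day = FALSE))
  }
  first_h <- min(occasions$start_h)
  last_h <- max(occasions$start_h)
  win <- last_h - first_h
  data.frame(
    n_eo = nrow(occasions),
    n_main = sum(occasions$class == "main_meal"),
    n_snack = sum(occasions$class == "snack"),
    first_eo_h = first_h,
    last_eo_h = last_h,
    eating_window_h = win,
    fasting_window_h = 24 - win,
    eating_midpoint_h = first_h + win / 2,
    total_kcal = sum(occasions$kcal),
    valid_day = TRUE
  )
}

#' Energy-plausibility screen for free-living days
#'
#' A day is retained when its total logged energy lies within the
#' sex-specific closed interval: 500-5000 kcal for females, 500-8000 kcal
#' for males.
#'
#' @param kcal total day energy, kcal.
#' @param sex `"female"` or `"male"`.
#' @return logical vector, `TRUE` for valid days.
#' @export
filterFreeLivingDays <- function(kcal, sex) {
  sex <- .normalizeSex(sex)
  hi <- if (sex == "female") 5000 else 8000
  kcal >= 500 & kcal <= hi
}

#' Average per-day features to participant level
#'
#' Arithmetic mean of each numeric feature over valid days. Clock-time
#' features (first/last occasion, midpoint) are averaged on the unwrapped
#' axis: times before `wrapBefore_h` (default 04:00) are treated as past
#' midnight (+24 h), so a 23:30/00:30 pair averages to midnight, and the
#' mean is reduced back to `[0, 24)`.
#'
#' @param days data.frame of per-day features ([dayFeatures()] rows), only
#'   valid days are used.
#' @param wrapBefore_h clock-hour below which times are unwrapped (+24 h).
#' @return one-row data.frame of participant-level means, or `NULL` when no
#'   valid day exists.
#' @export
meanOverValidDays <- function(days, wrapBefore_h = 4) {
  days <- days[days$valid_day %in% TRUE, , drop = FALSE]
  if (nrow(days) == 0L) return(NULL)
  clockcols <- intersect(c("first_eo_h", "last_eo_h", "eating_midpoint_h"),
                         names(days))
  out <- as.data.frame(lapply(days[setdiff(names(days), c(clockcols, "valid_day"))],
                              function(x) mean(x, na.rm = TRUE)))
  for (cc in clockcols) {
    x <- days[[cc]]
    x <- ifelse(x < wrapBefore_h, x + 24, x)
    out[[cc]] <- mean(x, na.rm = TRUE) %% 24
  }
  out$n_valid_days <- nrow(days)
  out
}

#' Basal metabolic rate by the Harris-Benedict equation
#'
#' Original coefficients: males
#' `66.4730 + 13.7516 W + 5.0033 H - 6.7550 A`, females
#' `655.0955 + 9.5634 W + 1.8496 H - 4.6756 A`, with weight W in kg, height
#' H in cm and age A in years.
#'
#' @param sex `"female"` or `"male"`.
#' @param weightKg,heightCm,ageY positive anthropometrics.
#' @return kcal/day.
#' @examples
#' harrisBenedictBmr("male", 70, 175, 30)
#' @export
harrisBenedictBmr <- function(sex, weightKg, heightCm, ageY) {
  if (any(weightKg <= 0) || any(heightCm <= 0) || any(ageY <= 0))
    stop("anthropometrics must be positive")
  sex <- vapply(sex, .normalizeSex, character(1))
  unname(ifelse(sex == "male",
         66.4730 + 13.7516 * weightKg + 5.0033 * heightCm - 6.7550 * ageY,
         655.0955 + 9.5634 * weightKg + 1.8496 * heightCm - 4.6756 * ageY))
}

#' Plausibility screen for FFQ records
#'
#' A record is excluded when the ratio of reported energy intake to basal
#' metabolic rate falls outside `[0.52, 2.58]` or when more than ten FFQ
#' items were left unanswered.
#'
#' @param energyKcal reported total energy intake, kcal/day.
#' @param bmr basal metabolic rate, kcal/day (> 0).
#' @param nUnanswered number of unanswered FFQ items. Default 0.
#' @return data.frame with `ratio` and logical `valid`.
#' @export
ffqExclusion <- function(energyKcal, bmr, nUnanswered = 0) {
  stopifnot(all(bmr > 0))
  ratio <- energyKcal / bmr
  data.frame(ratio = ratio,
             valid = ratio >= 0.52 & ratio <= 2.58 & nUnanswered <= 10)
}
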