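#' Configuration for the synthetic PREDICT-like cohort
#'
#' Defaults emulate the published cohort structure: 934 participants, 16
#' percent social-jetlag (SJL) prevalence, an SJL group 8.4 years younger
#' with a higher male fraction (39 vs 25 percent), lower nut and fruit and
#' higher sugar-sweetened-beverage and potato intakes in SJL, a 50-species
#' compositional abundance table with most species above 20 percent
#' prevalence, six species carrying a planted direct SJL effect of
#' standardized size 0.8 on the arcsine-square-root scale, and two species
#' whose SJL effect runs partly through nut intake with a planted proportion
#' mediated of 0.15.
#'
#' @param n_participants cohort size.
#' @param sjl_prevalence fraction with SJL.
#' @param age_shift_sjl years added to SJL-group ages (negative = younger).
#' @param male_frac_by_group named fractions `c(no_sjl = , sjl = )`.
#' @param diet_effects named additive g/day shifts for the SJL group.
#' @param n_species,n_direct_species,n_mediated_species species counts.
#' @param effect_size_d standardized direct effect on transformed abundance.
#' @param mediated_fraction planted proportion mediated, in (0, 1); must be
#'   `NULL` when `n_mediated_species = 0`.
#' @param family_sd between-family random-intercept SD on the transformed
#'   abundance scale.
#' @param twin_frac fraction of participants assigned to two-member
#'   families.
#' @param n_negative_sjl planted negative-SJL participants (exercise the
#'   exclusion rule).
#' @param meal_days free-living meal-log days per participant.
#' @param cgm_days CGM wear days (0 skips CGM generation).
#' @param postprandial generate the postprandial series tables.
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @return validated config list (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(n_participants = 934,
                            sjl_prevalence = 0.16,
                            age_shift_sjl = -8.4,
                            male_frac_by_group = c(no_sjl = 0.25, sjl = 0.39),
                            diet_effects = c(nuts = -3.5, fruits = -36,
                                             sugar_sweetened_beverages = 25.2,
                                             potatoes = 5.3,
                                             fish_seafood = 7.2),
                            n_species = 50,
                            n_direct_species = 6,
                            n_mediated_species = 2,
                            effect_size_d = 0.8,
                            mediated_fraction = if (n_mediated_species > 0) 0.15,
                            family_sd = 0.02,
                            twin_frac = 0.4,
                            n_negative_sjl = 0,
                            meal_days = 3,
                            cgm_days = 14,
                            postprandial = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 10, n_species >= 1,
            n_direct_species >= 0, n_mediated_species >= 0,
            meal_days >= 1, cgm_days >= 0, n_negative_sjl >= 0)
  if (sjl_prevalence < 0 || sjl_prevalence > 1)
    stop("sjl_prevalence must lie in [0, 1]")
  if (any(male_frac_by_group < 0 | male_frac_by_group > 1))
    stop("male fractions must lie in [0, 1]")
  if (twin_frac < 0 || twin_frac > 1) stop("twin_frac must lie in [0, 1]")
  if (n_direct_species + n_mediated_species > n_species)
    stop("n_direct_species + n_mediated_species must not exceed n_species")
  if (n_mediated_species == 0 && !is.null(mediated_fraction))
    stop("mediated_fraction given but n_mediated_species is 0")
  if (n_mediated_species > 0 &&
      (is.null(mediated_fraction) || mediated_fraction <= 0 ||
       mediated_fraction >= 1))
    stop("mediated_fraction must lie in (0, 1)")
  if (family_sd < 0) stop("family_sd must be non-negative")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# truncated-normal draws by inverse CDF (vectorised, no rejection)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort with planted, recoverable effects
#'
#' Builds every input table of the analysis pipeline for one cohort:
#' demographics, sleep questionnaire, meal log, FFQ food groups, CGM traces,
#' postprandial series and a compositional species abundance table. SJL
#' status is assigned first; bed and wake times are then sampled so that
#' re-deriving SJL from the questionnaire reproduces the assigned status.
#' Direct-effect species receive an additive group shift of
#' `effect_size_d` within-species SDs on the arcsine-square-root scale;
#' mediated species depend on SJL through nut intake (the planted mediator)
#' plus a direct path sized so that the proportion mediated equals
#' `mediated_fraction`. Zeros come from per-species Bernoulli detection and
#' compositional closure is applied last.
#'
#' @param config a [syntheticConfig()] list.
#' @return a [CohortBundle-class] object; see [groundTruth()].
#' @examples
#' cb <- generateCohort(syntheticConfig(n_participants = 60, cgm_days = 0,
#'                                      postprandial = FALSE, seed = 42))
#' cb
#' @export
generateCohort <- function(config = syntheticConfig()) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  rng <- .seededRng(config$seed)
  .withRng(rng, function() .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  n <- cfg$n_participants
  ids <- sprintf("P%04d", seq_len(n))

  ## --- group assignment first ------------------------------------------
  sjl <- stats::rbinom(n, 1L, cfg$sjl_prevalence)
  neg_sjl <- rep(FALSE, n)
  if (cfg$n_negative_sjl > 0) {
    cand <- which(sjl == 0L)
    neg_sjl[sample(cand, min(cfg$n_negative_sjl, length(cand)))] <- TRUE
  }

  ## --- demographics ----------------------------------------------------
  p_male <- ifelse(sjl == 1L, cfg$male_frac_by_group[["sjl"]],
                   cfg$male_frac_by_group[["no_sjl"]])
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")
  age <- .rtruncnorm(n, 46.8 + cfg$age_shift_sjl * sjl, 11.5, 18, 65)
  bmi <- .rtruncnorm(n, 25.6, 5.0, 16.5, 45)
  height <- ifelse(sex == "male", stats::rnorm(n, 176, 7),
                   stats::rnorm(n, 163, 7))
  weight <- bmi * (height / 100)^2
  ethnicity <- sample(c("white", "asian", "black", "mixed", "other"), n,
                      replace = TRUE, prob = c(0.90, 0.014, 0.016, 0.025, 0.045))
  education <- sample(c("below_university", "university_or_higher"), n,
                      replace = TRUE, prob = c(0.38, 0.62))
  menopause <- rep("not_applicable", n)
  fem <- sex == "female"
  menopause[fem] <- ifelse(age[fem] < 45 - stats::runif(sum(fem), 0, 4), "pre",
                           ifelse(age[fem] > 52 + stats::runif(sum(fem), 0, 3),
                                  "post", "peri"))
  n_pairs <- floor(cfg$twin_frac * n / 2)
  fam <- sprintf("F%04d", seq_len(n))  # singletons by default
  if (n_pairs > 0) {
    paired <- sample(n, 2 * n_pairs)
    fam[paired] <- rep(sprintf("T%04d", seq_len(n_pairs)), each = 2)
  }
  demographics <- data.frame(participant_id = ids, sex = sex,
                             age = round(age, 1), bmi = round(bmi, 1),
                             height_cm = round(height, 1),
                             weight_kg = round(weight, 1),
                             ethnicity = ethnicity, education = education,
                             menopause = menopause, family_id = fam,
                             stringsAsFactors = FALSE)

  ## --- sleep questionnaire so recomputed SJL matches assignment --------
  sjl_h <- numeric(n)
  sjl_h[sjl == 1L] <- .rtruncnorm(sum(sjl), 2.0, 0.45, 1.55, 3.5)
  sjl_h[sjl == 0L] <- .rtruncnorm(sum(sjl == 0L), 0.7, 0.4, 0.02, 1.45)
  sjl_h[neg_sjl] <- -stats::runif(sum(neg_sjl), 0.3, 1.2)
  mid_wk <- .rtruncnorm(n, 3.4, 0.75, 1.0, pmin(6.5, 6.6 - pmax(sjl_h, 0)))
  mid_we <- mid_wk + sjl_h
  dur_wk <- .rtruncnorm(n, 8.1 - 0.3 * sjl, 0.85, 4.5,
                        pmin(11, 2 * (12 - mid_wk) - 0.1))
  dur_we <- .rtruncnorm(n, 8.6 + 0.4 * sjl, 0.9, 4.5,
                        pmin(11, 2 * (12 - mid_we) - 0.1))
  sleep <- data.frame(
    participant_id = ids,
    bed_week = formatClockTime((mid_wk - dur_wk / 2) * 60),
    wake_week = formatClockTime((mid_wk + dur_wk / 2) * 60),
    bed_weekend = formatClockTime((mid_we - dur_we / 2) * 60),
    wake_weekend = formatClockTime((mid_we + dur_we / 2) * 60),
    psqi = pmin(21L, pmax(0L, round(stats::rnorm(n, 4, 2.5)))),
    stringsAsFactors = FALSE)

  ## --- FFQ food groups: baseline + group shift + noise -----------------
  base <- list(
    fruits = c(211, 120), nuts = c(18, 9),
    sugar_sweetened_beverages = c(62.5, 60), potatoes = c(71, 40),
    fish_seafood = c(45, 30), whole_grains = c(150, 80),
    vegetables = c(250, 120), legumes = c(40, 30),
    vegetable_oils = c(15, 9), tea_coffee = c(500, 250),
    fruit_juices = c(80, 70), refined_grains = c(180, 90),
    sweets_desserts = c(80, 55), animal_fat = c(10, 7),
    dairy = c(250, 140), eggs = c(25, 18), meat = c(90, 55))
  ffq <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (gname in names(base)) {
    mu <- base[[gname]][1]
    shift <- if (gname %in% names(cfg$diet_effects))
      cfg$diet_effects[[gname]] else 0
    ffq[[gname]] <- pmax(0, stats::rnorm(n, mu + shift * sjl,
                                         base[[gname]][2]))
  }
  ffq$energy_kcal <- pmax(600, stats::rnorm(n, 2000, 350))
  ffq$alcohol_g <- pmax(0, stats::rnorm(n, 8, 10))
  ffq$n_unanswered <- stats::rpois(n, 0.6)

  ## --- abundance table: planted effects on asin-sqrt scale -------------
  ns <- cfg$n_species
  spnames <- sprintf("SGB%05d", sample(10000:99999, ns))
  w <- exp(stats::rnorm(ns, 0, 1.2)); m_mean <- w / sum(w)
  mu_s <- asin(sqrt(m_mean))
  s_s <- 0.3 * mu_s + 0.005
  detect <- stats::runif(ns, 0.35, 0.95)
  # planted and structural roles go to sub-dominant taxa (mean relative
  # abundance <= 2%), as in real screens where differential species are
  # rare SGBs; this also keeps closure spillover of planted shifts into
  # null species negligible
  n_roles <- cfg$n_direct_species + cfg$n_mediated_species + 7
  eligible <- which(m_mean <= 0.02)
  if (length(eligible) < n_roles)
    eligible <- order(m_mean)[seq_len(min(ns, max(n_roles, ns - 3)))]
  roles <- sample(eligible, n_roles)
  direct_idx <- utils::head(roles, cfg$n_direct_species)
  mediated_idx <- roles[cfg$n_direct_species + seq_len(cfg$n_mediated_species)]
  rest <- utils::tail(roles, 7)
  lowprev_idx <- rest[1:4]
  onegroup_idx <- rest[5:7]
  detect[direct_idx] <- 0.9
  detect[mediated_idx] <- 1.0
  detect[lowprev_idx] <- stats::runif(4, 0.05, 0.15)

  u_fam <- stats::rnorm(length(unique(fam)), 0, cfg$family_sd)
  names(u_fam) <- unique(fam)
  u <- u_fam[fam]

  tmat <- matrix(rep(mu_s, each = n), nrow = n) +
    matrix(stats::rnorm(n * ns, 0, rep(s_s, each = n)), nrow = n) + u
  # effect_size_d is meant on the observed (zero-inflated) transformed
  # scale the screen sees: a detection probability pi dilutes the group
  # mean difference by pi and inflates the observed SD, so the latent shift
  # is scaled up accordingly.
  for (j in direct_idx) {
    pi_j <- detect[j]
    sd_obs <- sqrt(pi_j * (s_s[j]^2 + (1 - pi_j) * mu_s[j]^2))
    tmat[, j] <- tmat[, j] + cfg$effect_size_d * (sd_obs / pi_j) * sjl
  }
  gt_coef <- NULL
  if (cfg$n_mediated_species > 0) {
    a <- cfg$diet_effects[["nuts"]]
    if (is.null(a) || a == 0) stop("mediated species need a non-zero nut shift")
    f <- cfg$mediated_fraction
    nuts_c <- ffq$nuts - base$nuts[1]
    gt_coef <- do.call(rbind, lapply(mediated_idx, function(j) {
      acme <- -0.15 * s_s[j]            # indirect effect, transformed scale
      b <- acme / a
      cprime <- acme * (1 - f) / f
      tmat[, j] <<- tmat[, j] + b * nuts_c + cprime * sjl
      data.frame(species = spnames[j], mediator = "nuts", a = a, b = b,
                 cprime = cprime, prop_mediated = f)
    }))
  }
  tmat[tmat < 0] <- 0
  tmat[tmat > pi / 2] <- pi / 2
  p <- sin(tmat)^2
  z <- matrix(stats::rbinom(n * ns, 1L, rep(detect, each = n)), nrow = n)
  # one-group prevalence structure: present in no-SJL only
  for (j in onegroup_idx) {
    pr <- ifelse(sjl == 1L, 0.08, 0.28)
    z[, j] <- stats::rbinom(n, 1L, pr)
  }
  p <- p * z
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / rs
  abund <- t(p)
  dimnames(abund) <- list(spnames, ids)
  se <- sjlAbundance(abund, sjl = sjl == 1L)

  ## --- meal log --------------------------------------------------------
  meals <- .generateMeals(ids, sex, sjl, cfg$meal_days)

  ## --- CGM and postprandial -------------------------------------------
  cgm <- if (cfg$cgm_days > 0) {
    sub <- sample.int(.Machine$integer.max - 1L, n)
    do.call(rbind, lapply(seq_len(n), function(i)
      generateCgmTrace(ids[i], days = cfg$cgm_days, seed = sub[i])))
  } else data.frame(participant_id = character(), timestamp = character(),
                    glucose_mmol_l = numeric())
  postprandial <- if (isTRUE(cfg$postprandial)) {
    sub <- sample.int(.Machine$integer.max - 1L, n)
    do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(c("glucose", "insulin", "triglyceride", "GlycA"),
        function(an) generatePostprandialSeries(ids[i], an,
                                                seed = sub[i] %% 2000000000L + match(an, c("glucose", "insulin", "triglyceride", "GlycA")))))
    }))
  } else data.frame(participant_id = character(), analyte = character(),
                    minute = numeric(), value = numeric())

  gt <- list(direct_species = spnames[direct_idx],
             mediated_species = spnames[mediated_idx],
             low_prevalence_species = spnames[lowprev_idx],
             group_prevalence_species = spnames[onegroup_idx],
             effect_size_d = cfg$effect_size_d,
             coefficients = gt_coef,
             sjl_assigned = stats::setNames(sjl == 1L, ids),
             negative_sjl = ids[neg_sjl],
             seed = cfg$seed)
  methods::new("CohortBundle", demographics = demographics, sleep = sleep,
               meals = meals, ffq = ffq, cgm = cgm,
               postprandial = postprandial, abundance = se,
               groundTruth = gt, config = unclass(cfg))
}

.generateMeals <- function(ids, sex, sjl, days) {
  n <- length(ids)
  rows <- vector("list", n)
  dates <- sprintf("2018-06-%02d", seq_len(days))
  for (i in seq_len(n)) {
    kcal_scale <- if (sex[i] == "male") 1.2 else 1.0
    ev <- list()
    for (d in seq_len(days)) {
      tt <- c(stats::rnorm(1, 8 + 0.4 * sjl[i], 0.7),
              stats::rnorm(1, 13, 0.7),
              stats::rnorm(1, 19, 0.9))
      kc <- kcal_scale * c(stats::rnorm(1, 420, 120),
                           stats::rnorm(1, 550, 150),
                           stats::rnorm(1, 650, 180))
      if (stats::runif(1) < 0.7) {
        tt <- c(tt, stats::rnorm(1, 16, 1.2))
        kc <- c(kc, stats::rnorm(1, 180, 80))
      }
      if (stats::runif(1) < 0.25) {  # sub-threshold nibble
        tt <- c(tt, stats::rnorm(1, 21.5, 0.6))
        kc <- c(kc, stats::runif(1, 10, 45))
      }
      keep <- tt > 5 & tt < 23.9
      tt <- tt[keep]; kc <- pmax(20, kc[keep])
      ev[[d]] <- data.frame(
        participant_id = ids[i],
        timestamp = paste(dates[d], formatClockTime(tt * 60)),
        kcal = round(kc, 1), stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, ev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate one participant's CGM trace
#'
#' Interstitial glucose every 15 minutes for `days` days: a participant
#' baseline, a circadian sinusoid, meal-time bumps and AR(1) sensor noise.
#' The first reading carries the device-fit timestamp, so the 12 h discard
#' rule is exercisable downstream.
#'
#' @param participant participant ID.
#' @param days wear days, >= 1.
#' @param seed integer seed.
#' @param constant if `TRUE`, a flat trace at `baseline` (zero variability).
#' @param baseline mmol/L; participant mean when `constant`.
#' @return data.frame: `participant_id`, `timestamp` (ISO-8601 character),
#'   `glucose_mmol_l`.
#' @export
generateCgmTrace <- function(participant, days = 14, seed = 1,
                             constant = FALSE, baseline = 5.1) {
  if (days <= 0) stop("days must be >= 1")
  rng <- .seededRng(seed)
  .withRng(rng, function() {
    n <- as.integer(96 * days)
    hrs <- (seq_len(n) - 1L) * 0.25
    if (constant) {
      g <- rep(baseline, n)
    } else {
      b <- stats::rnorm(1, baseline, 0.35)
      circ <- 0.25 * sin(2 * pi * (hrs - 4) / 24)
      bump <- 0.9 * (abs(((hrs + 10) %% 24) - 12) < 1) *
        exp(-((hrs %% 1) * 4))
      ar <- stats::filter(stats::rnorm(n, 0, 0.22), 0.8, method = "recursive")
      g <- pmax(2.5, b + circ + bump + as.numeric(ar))
    }
    t0 <- as.POSIXct("2018-06-01 10:00:00", tz = "UTC")
    data.frame(participant_id = participant,
               timestamp = format(t0 + hrs * 3600, "%Y-%m-%dT%H:%M:%S"),
               glucose_mmol_l = round(g, 2), stringsAsFactors = FALSE)
  })
}

.ppTimes <- c(0, 15, 30, 60, 120, 180, 240, 270, 300, 360)

#' Generate one participant's postprandial series
#'
#' Concentrations at the ten protocol time points (0, 15, 30, 60, 120, 180,
#' 240, 270, 300, 360 min) after a standardised mixed meal, with
#' analyte-specific baseline, excursion shape and noise.
#'
#' @param participant participant ID.
#' @param analyte one of `"glucose"`, `"insulin"`, `"triglyceride"`,
#'   `"GlycA"`.
#' @param seed integer seed.
#' @param flat if `TRUE`, the series stays at baseline (zero iAUC).
#' @return data.frame: `participant_id`, `analyte`, `minute`, `value`.
#' @export
generatePostprandialSeries <- function(participant, analyte, seed = 1,
                                       flat = FALSE) {
  pars <- switch(analyte,
    glucose = list(b = 5.0, bsd = 0.4, amp = 2.2, tp = 35, noise = 0.12),
    insulin = list(b = 6, bsd = 2, amp = 45, tp = 45, noise = 2),
    triglyceride = list(b = 1.1, bsd = 0.4, amp = 0.8, tp = 240, noise = 0.05),
    GlycA = list(b = 1.33, bsd = 0.18, amp = -0.035, tp = 300, noise = 0.01),
    stop("unknown analyte: ", analyte))
  rng <- .seededRng(seed)
  .withRng(rng, function() {
    b <- max(0.1, stats::rnorm(1, pars$b, pars$bsd))
    tt <- .ppTimes
    if (flat) {
      v <- rep(b, length(tt))
    } else {
      shape <- (tt / pars$tp) * exp(1 - tt / pars$tp)
      v <- b + pars$amp * shape + c(0, stats::rnorm(length(tt) - 1L, 0,
                                                    pars$noise))
      v <- pmax(0.05, v)
    }
    data.frame(participant_id = participant, analyte = analyte,
               minute = tt, value = round(v, 3), stringsAsFactors = FALSE)
  })
}
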