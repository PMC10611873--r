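#' Pipeline configuration
#'
#' Collects all stage parameters with their study defaults: SJL threshold
#' 1.5 h; eating occasions >= 50 kcal merged at 30 min gaps with 400/500
#' kcal main-meal thresholds; CGM target range 3.9-5.6 mmol/L with a 12 h
#' discard; screen thresholds prevalence 0.20, q < 0.2, |d| > 0.2;
#' mediation via nut intake with 1000 quasi-Bayesian draws.
#'
#' @param sjl_threshold hours. @param eo_gap_min minutes.
#' @param eo_kcal_floor kcal. @param main_meal_kcal named kcal thresholds.
#' @param cgm_range mmol/L, length 2. @param cgm_discard_h hours.
#' @param screen_prevalence,screen_q,screen_d screen thresholds.
#' @param mediators mediator column names for the mediation stage.
#' @param mediation_nsims quasi-Bayesian draws.
#' @param covariates adjustment set for comparisons and mediation.
#' @param seed integer.
#' @return config list (class `PipelineConfig`).
#' @export
pipelineConfig <- function(sjl_threshold = 1.5, eo_gap_min = 30,
                           eo_kcal_floor = 50,
                           main_meal_kcal = c(female = 400, male = 500),
                           cgm_range = c(3.9, 5.6), cgm_discard_h = 12,
                           screen_prevalence = 0.20, screen_q = 0.2,
                           screen_d = 0.2, mediators = "nuts",
                           mediation_nsims = 1000,
                           covariates = c("sex", "age", "bmi", "ethnicity",
                                          "education"),
                           seed = 1) {
  cfg <- as.list(environment())
  stopifnot(sjl_threshold > 0, eo_gap_min > 0, eo_kcal_floor > 0,
            all(main_meal_kcal > 0), length(cgm_range) == 2L,
            cgm_range[1] < cgm_range[2], cgm_discard_h >= 0,
            screen_prevalence > 0, screen_q > 0, screen_d > 0,
            mediation_nsims >= 100)
  class(cfg) <- "PipelineConfig"
  cfg
}

# participant-level diet-timing features from the meal log
.dietStage <- function(meals, demographics, config) {
  if (nrow(meals) == 0L) return(NULL)
  sex_of <- stats::setNames(demographics$sex, demographics$participant_id)
  day <- sub(" .*", "", meals$timestamp)
  tod <- sub(".* ", "", meals$timestamp)
  key <- paste(meals$participant_id, day)
  feats <- lapply(split(seq_len(nrow(meals)), key), function(ix) {
    pid <- meals$participant_id[ix[1]]
    occ <- segmentEatingOccasions(tod[ix], meals$kcal[ix],
                                  sex = sex_of[[pid]],
                                  gapMin = config$eo_gap_min,
                                  kcalFloor = config$eo_kcal_floor,
                                  mainKcal = config$main_meal_kcal)
    df <- dayFeatures(occ)
    df$valid_day <- df$valid_day &&
      !is.na(df$total_kcal) &&
      filterFreeLivingDays(df$total_kcal, sex_of[[pid]])
    df$participant_id <- pid
    df
  })
  days <- do.call(rbind, feats)
  out <- lapply(split(days, days$participant_id), function(d) {
    m <- meanOverValidDays(d[setdiff(names(d), "participant_id")])
    if (is.null(m)) return(NULL)
    m$participant_id <- d$participant_id[1]
    m
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.metabolicStage <- function(cgm, postprandial, config) {
  cgm_tab <- NULL
  if (!is.null(cgm) && nrow(cgm) > 0) {
    cgm_tab <- do.call(rbind, lapply(split(cgm, cgm$participant_id),
      function(d) {
        ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC")
        m <- cgmMetrics(ts, d$glucose_mmol_l,
                        rangeLow = config$cgm_range[1],
                        rangeHigh = config$cgm_range[2],
                        discardHours = config$cgm_discard_h)
        m$participant_id <- d$participant_id[1]
        m
      }))
    rownames(cgm_tab) <- NULL
  }
  pp_tab <- NULL
  if (!is.null(postprandial) && nrow(postprandial) > 0) {
    pp_tab <- do.call(rbind, lapply(
      split(postprandial, list(postprandial$participant_id,
                               postprandial$analyte), drop = TRUE),
      function(d) {
        an <- d$analyte[1]
        horizon <- if (an %in% c("glucose", "insulin")) 120 else 360
        row <- data.frame(participant_id = d$participant_id[1],
                          analyte = an,
                          iauc = incrementalAuc(d$minute, d$value,
                                                horizon = horizon))
        if (an == "GlycA")
          row$rise_6h <- glycaRise(d$value[d$minute == 0],
                                   d$value[d$minute == 360])
        else row$rise_6h <- NA_real_
        row
      }))
    rownames(pp_tab) <- NULL
  }
  list(cgm = cgm_tab, postprandial = pp_tab)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes derive (sleep, diet, metabolic) -> compare -> screen -> mediate
#' on a [CohortBundle-class] (or a directory written by
#' [writeCohortBundle()]), using the SJL groups re-derived from the sleep
#' questionnaire. Optionally writes every stage table as CSV plus an
#' exclusion-flow summary and a run manifest (config hash, seed, versions).
#'
#' @param input a [CohortBundle-class] or a bundle directory path.
#' @param config a [pipelineConfig()].
#' @param outdir optional output directory.
#' @return named list of stage results: `sleep`, `exclusions`, `diet`,
#'   `pdi`, `metabolic`, `compare`, `screen`, `prevalence_diff`,
#'   `mediation`, `manifest`.
#' @export
runPipeline <- function(input, config = pipelineConfig(), outdir = NULL) {
  bundle <- if (methods::is(input, "CohortBundle")) input
            else readCohortBundle(input)

  sl <- deriveSleep(bundle@sleep, sjlThreshold = config$sjl_threshold)
  derived <- sl$derived
  kept <- derived[derived$included, ]

  diet <- .dietStage(bundle@meals, bundle@demographics, config)
  dem <- bundle@demographics
  bmr <- harrisBenedictBmr(dem$sex, dem$weight_kg, dem$height_cm, dem$age)
  ffqv <- ffqExclusion(bundle@ffq$energy_kcal, bmr,
                       bundle@ffq$n_unanswered)
  pdi <- cbind(participant_id = bundle@ffq$participant_id,
               scorePdiFamily(bundle@ffq[
                 intersect(names(defaultPdiClassification()),
                           names(bundle@ffq))]),
               ffq_valid = ffqv$valid, ei_bmr_ratio = ffqv$ratio)

  metab <- .metabolicStage(bundle@cgm, bundle@postprandial, config)

  # analysis frame: demographics + derived sleep + diet quality
  frame <- merge(dem, kept[, c("participant_id", "sjl", "sjl_flag",
                               "habitual_h", "chronotype", "psqi")],
                 by = "participant_id")
  frame <- merge(frame, pdi[, c("participant_id", "PDI", "hPDI", "uPDI")],
                 by = "participant_id", all.x = TRUE)
  frame <- merge(frame, bundle@ffq[, c("participant_id", "nuts", "fruits",
                                       "alcohol_g")],
                 by = "participant_id", all.x = TRUE)

  compare <- ancovaTable(frame,
                         outcomes = c("hPDI", "uPDI", "nuts", "fruits"),
                         group = "sjl_flag", covariates = config$covariates)

  ab <- bundle@abundance[, colnames(bundle@abundance) %in%
                           kept$participant_id]
  grp <- stats::setNames(kept$sjl_flag, kept$participant_id)
  se <- sjlAbundance(SummarizedExperiment::assay(ab, "relabund"),
                     sjl = unname(grp[colnames(ab)]))
  screen <- screenSpecies(se, prevalenceMin = config$screen_prevalence,
                          qMax = config$screen_q, dMin = config$screen_d)
  prevdiff <- prevalenceDifferenceScreen(se,
                                         threshold = config$screen_prevalence)

  sig <- screenTable(screen)
  sig <- sig$species[sig$significant]
  mediation <- NULL
  if (length(sig)) {
    tr <- t(asinSqrt(relAbundance(se)[sig, , drop = FALSE]))
    colnames(tr) <- paste0("y_", colnames(tr))
    mdat <- cbind(frame[match(rownames(tr), frame$participant_id), ],
                  as.data.frame(tr))
    mediation <- batchMediate(mdat, mediators = config$mediators,
                              outcomes = colnames(tr),
                              exposure = "sjl_flag",
                              covariates = config$covariates,
                              cluster = "family_id",
                              nSims = config$mediation_nsims,
                              seed = config$seed)
    mediation$outcome <- sub("^y_", "", mediation$outcome)
  }

  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed,
                   n_input = nrow(bundle@demographics),
                   n_analysed = nrow(kept),
                   package_version = as.character(utils::packageVersion("chronogut")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  report <- list(sleep = derived, exclusions = sl$exclusions, diet = diet,
                 pdi = pdi, metabolic = metab, compare = compare,
                 screen = screenTable(screen), prevalence_diff = prevdiff,
                 mediation = mediation, manifest = manifest)
  if (!is.null(outdir)) .writeReport(report, outdir)
  report
}

.writeReport <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) if (!is.null(df))
    utils::write.csv(df, file.path(outdir, f), row.names = FALSE)
  w(report$sleep, "sleep_derived.csv")
  w(exclusionFlow(list(sleep = report$exclusions)), "exclusion_flow.csv")
  w(report$diet, "diet_features.csv")
  w(report$pdi, "diet_indices.csv")
  w(report$metabolic$cgm, "cgm_metrics.csv")
  w(report$metabolic$postprandial, "postprandial_iauc.csv")
  w(report$compare, "group_comparisons.csv")
  w(report$screen, "species_screen.csv")
  w(report$prevalence_diff, "prevalence_differences.csv")
  w(report$mediation, "mediation_results.csv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
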