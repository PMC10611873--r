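smallCfg <- function(...) {
  args <- list(n_participants = 120, cgm_days = 0, postprandial = FALSE,
               meal_days = 1)
  dots <- list(...)
  for (nm in names(dots)) args[nm] <- dots[nm]
  do.call(syntheticConfig, args)
}

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(sjl_prevalence = 1.2), "sjl_prevalence")
  expect_error(syntheticConfig(n_species = 5, n_direct_species = 4,
                               n_mediated_species = 2), "exceed")
  expect_error(syntheticConfig(n_mediated_species = 0,
                               mediated_fraction = 0.2), "mediated")
  expect_error(syntheticConfig(mediated_fraction = 1.5), "\\(0, 1\\)")
  expect_silent(syntheticConfig(n_mediated_species = 0))
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- generateCohort(smallCfg(seed = 101))
  b <- generateCohort(smallCfg(seed = 101))
  expect_identical(a@demographics, b@demographics)
  expect_identical(a@sleep, b@sleep)
  expect_identical(a@ffq, b@ffq)
  expect_identical(a@meals, b@meals)
  expect_identical(relAbundance(a@abundance), relAbundance(b@abundance))
  expect_identical(groundTruth(a), groundTruth(b))
  c_ <- generateCohort(smallCfg(seed = 102))
  expect_false(identical(a@demographics$age, c_@demographics$age))
})

test_that("cohort generation leaves the caller's RNG stream untouched", {
  set.seed(500)
  before <- .Random.seed
  invisible(generateCohort(smallCfg(seed = 7)))
  expect_identical(before, .Random.seed)
})

test_that("abundance rows close to one and ground truth lists the plants", {
  cb <- generateCohort(smallCfg(seed = 8))
  cs <- colSums(relAbundance(cb@abundance))
  expect_true(all(abs(cs - 1) < 1e-9))
  gt <- groundTruth(cb)
  expect_length(gt$direct_species, 6L)
  expect_length(gt$mediated_species, 2L)
  expect_equal(nrow(gt$coefficients), 2L)
  expect_equal(gt$coefficients$prop_mediated, rep(0.15, 2))
  # planted decomposition: prop = acme / (acme + cprime)
  with(gt$coefficients, expect_equal(a * b / (a * b + cprime),
                                     prop_mediated, tolerance = 1e-12))
  expect_true(all(gt$mediated_species %in%
                    rownames(relAbundance(cb@abundance))))
})

test_that("SJL counts follow the configured prevalence and sleep times reproduce the assignment", {
  cb <- generateCohort(syntheticConfig(seed = 21, cgm_days = 0,
                                       postprandial = FALSE, meal_days = 1))
  gt <- groundTruth(cb)
  n_sjl <- sum(gt$sjl_assigned)
  band <- qbinom(c(0.025, 0.975), 934, 0.16)
  expect_gte(n_sjl, band[1])
  expect_lte(n_sjl, band[2])
  sl <- deriveSleep(cb@sleep)
  d <- sl$derived[sl$derived$included, ]
  agree <- mean(d$sjl_flag == unname(gt$sjl_assigned[d$participant_id]))
  expect_gte(agree, 0.99)
  # group structure: SJL younger, more male
  dem <- cb@demographics
  sjl <- unname(gt$sjl_assigned[dem$participant_id])
  expect_lt(mean(dem$age[sjl]), mean(dem$age[!sjl]))
  expect_gt(mean(dem$sex[sjl] == "male"), mean(dem$sex[!sjl] == "male"))
})

test_that("planted negative-SJL records are generated and excluded downstream", {
  cb <- generateCohort(smallCfg(seed = 31, n_negative_sjl = 5))
  sl <- deriveSleep(cb@sleep)
  excl <- sl$exclusions
  expect_equal(excl$n_removed[excl$rule == "negative_sjl"], 5L)
  expect_setequal(
    sl$derived$participant_id[
      sl$derived$exclusion_reason %in% "negative_sjl"],
    groundTruth(cb)$negative_sjl)
})

test_that("a null cohort yields essentially no screen hits", {
  cb <- generateCohort(smallCfg(seed = 77, n_participants = 400,
                                effect_size_d = 0, n_mediated_species = 0,
                                mediated_fraction = NULL))
  tb <- screenTable(screenSpecies(cb@abundance))
  expect_lte(sum(tb$significant), 2L)
})

test_that("CGM traces: cadence, device-fit origin, determinism, flat option", {
  tr <- generateCgmTrace("P1", days = 14, seed = 3)
  expect_equal(nrow(tr), 96 * 14)
  expect_true(all(tr$glucose_mmol_l > 0))
  expect_identical(tr, generateCgmTrace("P1", days = 14, seed = 3))
  expect_error(generateCgmTrace("P1", days = 0), "days")
  flat <- generateCgmTrace("P1", days = 2, seed = 3, constant = TRUE)
  ts <- as.POSIXct(flat$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  m <- cgmMetrics(ts, flat$glucose_mmol_l)
  expect_equal(m$cv_pct, 0)
  expect_equal(m$tir_pct, 100)
})

test_that("postprandial series use the protocol grid; flat series have zero iAUC", {
  s <- generatePostprandialSeries("P1", "glucose", seed = 4)
  expect_equal(s$minute, c(0, 15, 30, 60, 120, 180, 240, 270, 300, 360))
  expect_identical(s, generatePostprandialSeries("P1", "glucose", seed = 4))
  expect_error(generatePostprandialSeries("P1", "cortisol"), "analyte")
  f <- generatePostprandialSeries("P1", "insulin", seed = 4, flat = TRUE)
  expect_equal(incrementalAuc(f$minute, f$value, 120), 0)
  expect_equal(incrementalAuc(f$minute, f$value, 360, mode = "net"), 0)
})
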