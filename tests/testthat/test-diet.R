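test_that("eating-occasion segmentation merges, floors and classifies", {
  occ <- segmentEatingOccasions(c("08:00", "08:20", "13:00"),
                                c(300, 150, 600), sex = "female")
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$kcal, c(450, 600))
  expect_equal(occ$class, c("main_meal", "main_meal"))
  # isolated sub-threshold event is dropped
  expect_equal(nrow(segmentEatingOccasions("10:00", 40, "female")), 0L)
  # sex-specific main-meal threshold: 450 kcal
  expect_equal(segmentEatingOccasions("12:00", 450, "male")$class, "snack")
  expect_equal(segmentEatingOccasions("12:00", 450, "female")$class,
               "main_meal")
  expect_error(segmentEatingOccasions("12:00", 450, "x"), "sex")
})

test_that("segmentation equals the exhaustive-partition oracle", {
  set.seed(11)
  for (rep in 1:150) {
    n <- sample(1:10, 1)
    hours <- sort(sample(360:1380, n)) / 60  # minute resolution
    kcal <- round(runif(n, 10, 700))
    sex <- sample(c("female", "male"), 1)
    got <- segmentEatingOccasions(hours, kcal, sex)
    want <- oracleSegment(hours, kcal, sex)
    expect_equal(got$start_h, want$start_h)
    expect_equal(got$kcal, want$kcal)
    expect_equal(got$class, want$class)
  }
})

test_that("day features: windows, midpoint, degenerate single occasion", {
  occ <- segmentEatingOccasions(c("08:00", "20:00"), c(500, 700), "male")
  f <- dayFeatures(occ)
  expect_equal(f$eating_window_h, 12)
  expect_equal(f$fasting_window_h, 12)
  expect_equal(f$eating_midpoint_h, 14)
  one <- dayFeatures(segmentEatingOccasions("12:00", 400, "male"))
  expect_equal(one$eating_window_h, 0)
  expect_equal(one$fasting_window_h, 24)
  expect_equal(one$eating_midpoint_h, 12)
  three <- dayFeatures(segmentEatingOccasions(c("07:00", "12:30", "19:00"),
                                              c(400, 500, 600), "female"))
  expect_equal(three$first_eo_h, 7)
  expect_equal(three$last_eo_h, 19)
  expect_equal(three$eating_midpoint_h, 13)
  none <- dayFeatures(segmentEatingOccasions("10:00", 30, "female"))
  expect_false(none$valid_day)
  expect_true(is.na(none$eating_window_h))
})

test_that("eating + fasting windows always sum to 24 h", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    occ <- segmentEatingOccasions(sort(runif(n, 5, 23)),
                                  runif(n, 60, 800), "female")
    f <- dayFeatures(occ)
    if (isTRUE(f$valid_day))
      expect_equal(f$eating_window_h + f$fasting_window_h, 24)
  }
})

test_that("free-living day energy screen uses sex-specific closed bounds", {
  expect_false(filterFreeLivingDays(450, "female"))
  expect_true(filterFreeLivingDays(500, "female"))
  expect_true(filterFreeLivingDays(5000, "female"))
  expect_false(filterFreeLivingDays(5200, "female"))
  expect_true(filterFreeLivingDays(7500, "male"))
  expect_false(filterFreeLivingDays(8100, "male"))
})

test_that("participant means average clock times on the unwrapped axis", {
  d1 <- data.frame(eating_window_h = 10, eating_midpoint_h = 23.5,
                   valid_day = TRUE)
  d2 <- data.frame(eating_window_h = 12, eating_midpoint_h = 0.5,
                   valid_day = TRUE)
  m <- meanOverValidDays(rbind(d1, d2))
  expect_equal(m$eating_window_h, 11)
  expect_equal(m$eating_midpoint_h, 0)  # 23:30 and 00:30 average midnight
  # identical days are a fixed point
  mm <- meanOverValidDays(rbind(d1, d1))
  expect_equal(mm$eating_window_h, d1$eating_window_h)
  expect_equal(mm$eating_midpoint_h, d1$eating_midpoint_h)
  expect_null(meanOverValidDays(data.frame(eating_window_h = 1,
                                           valid_day = FALSE)))
})

test_that("Harris-Benedict BMR matches hand evaluation of the coefficients", {
  expect_equal(harrisBenedictBmr("male", 70, 175, 30),
               66.4730 + 13.7516 * 70 + 5.0033 * 175 - 6.7550 * 30)
  expect_equal(unname(harrisBenedictBmr("male", 70, 175, 30)), 1702.0125)
  expect_equal(unname(harrisBenedictBmr("female", 60, 165, 40)), 1347.0595)
  expect_error(harrisBenedictBmr("male", 0, 175, 30), "positive")
})

test_that("FFQ exclusion applies the EI/BMR band and unanswered-item rule", {
  expect_false(ffqExclusion(0.50 * 1500, 1500)$valid)
  expect_true(ffqExclusion(0.52 * 1500, 1500)$valid)
  expect_true(ffqExclusion(1500, 1500, nUnanswered = 0)$valid)
  expect_false(ffqExclusion(1500, 1500, nUnanswered = 11)$valid)
  expect_true(ffqExclusion(1500, 1500, nUnanswered = 10)$valid)
  expect_false(ffqExclusion(2.60 * 1500, 1500)$valid)
})
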