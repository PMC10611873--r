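test_that("ANCOVA group estimate equals an independent normal-equations solve", {
  set.seed(19)
  n <- 40
  d <- data.frame(g = rep(c(0, 1), each = n / 2), age = runif(n, 20, 60),
                  bmi = rnorm(n, 25, 4))
  d$y <- 2 + 0.8 * d$g + 0.05 * d$age - 0.1 * d$bmi + rnorm(n)
  got <- ancovaCompare(d, "y", "g", c("age", "bmi"), transform = "none")
  X <- cbind(1, d$g, d$age, d$bmi)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(got$estimate, beta[2, 1], tolerance = 1e-10)
  expect_equal(got$n, n)
})

test_that("ANCOVA recovers a planted covariate-adjusted group effect", {
  set.seed(23)
  n <- 900
  d <- data.frame(g = rbinom(n, 1, 0.16), age = runif(n, 20, 60))
  d$y <- 0.05 * d$age + 0.5 * d$g + rnorm(n)   # delta = 0.5 SD
  got <- ancovaCompare(d, "y", "g", "age")
  expect_equal(got$estimate, 0.5, tolerance = 3 * got$se)
  expect_lt(got$p, 0.001)
  # a covariate that is pure noise leaves the estimate essentially unchanged
  d$z <- rnorm(n)
  got2 <- ancovaCompare(d, "y", "g", c("age", "z"))
  expect_equal(got2$estimate, got$estimate, tolerance = 0.02)
})

test_that("transform selection follows Shapiro-Wilk and domain rules", {
  set.seed(10)
  n <- 300
  d <- data.frame(g = rbinom(n, 1, 0.3))
  d$y <- exp(rnorm(n))             # log-normal, strictly positive
  expect_equal(ancovaCompare(d, "y", "g")$transform, "log")
  d$y2 <- rnorm(n, 10)             # normal: no transform
  expect_equal(ancovaCompare(d, "y2", "g")$transform, "none")
  d$y3 <- c(0, rexp(n - 1))^2      # skewed with zeros: log unavailable
  expect_equal(ancovaCompare(d, "y3", "g")$transform, "sqrt")
  expect_error(ancovaCompare(transform = "none",
                             data.frame(g = c(0, 1, 0, 1), y = rep(1, 4)),
                             "y", "g"), "constant")
})

test_that("permuted labels keep the ANCOVA false-positive rate nominal", {
  set.seed(61)
  n <- 200
  d <- data.frame(age = runif(n, 20, 60))
  d$y <- 0.05 * d$age + rnorm(n)
  hits <- 0L
  for (i in 1:200) {
    d$g <- sample(rep(c(0, 1), c(168, 32)))
    if (ancovaCompare(d, "y", "g", "age", transform = "none")$p < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("BH q-values across an outcome family match the hand oracle", {
  set.seed(15)
  n <- 60
  d <- data.frame(g = rep(c(0, 1), each = n / 2))
  d$y1 <- rnorm(n) + d$g
  d$y2 <- rnorm(n)
  d$y3 <- rnorm(n)
  tab <- ancovaTable(d, c("y1", "y2", "y3"), "g")
  expect_equal(tab$q, oracleBH(tab$p))
  expect_equal(oracleBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
})

test_that("interaction models detect a male-only group effect", {
  set.seed(33)
  n <- 900
  d <- data.frame(g = rbinom(n, 1, 0.16),
                  sex = sample(c("female", "male"), n, replace = TRUE),
                  age = runif(n, 20, 60))
  d$y <- 0.02 * d$age + ifelse(d$sex == "male", 0.5, 0) * d$g + rnorm(n)
  r <- interactionModel(d, "y", "g", "sex", covariates = "age")
  expect_lt(r$interaction$p[1], 0.05)
  expect_equal(nrow(r$simple_effects), 2L)  # one contrast per sex
  # null interaction is centred at zero
  d$y0 <- 0.02 * d$age + 0.3 * d$g + rnorm(n)
  r0 <- interactionModel(d, "y0", "g", "sex", covariates = "age")
  expect_lt(abs(r0$interaction$estimate[1]), 0.35)
  # degenerate moderators are refused with a named error
  d1 <- d; d1$mono <- "female"
  expect_error(interactionModel(d1, "y", "g", "mono"), "one level")
  d2 <- d; d2$sex[d2$g == 1] <- "female"
  expect_error(interactionModel(d2, "y", "g", "sex"), "empty cell")
})

test_that("partial correlation matches its construction and the t-test df", {
  set.seed(56)
  n <- 5000
  z <- rnorm(n)
  u <- rnorm(n); v <- rnorm(n)
  rho <- 0.30
  x <- z + u
  y <- z + rho * u + sqrt(1 - rho^2) * v
  got <- partialCorrelation(x, y, data.frame(z = z))
  expect_lt(abs(got$r - rho), 0.03)
  expect_equal(got$df, n - 1L - 2L)
  # exact dependence survives any independent covariates
  got2 <- partialCorrelation(x, x, data.frame(z = z))
  expect_equal(got2$r, 1)
  # independent triple: near-zero partial correlation
  got3 <- partialCorrelation(rnorm(n), rnorm(n), data.frame(z = rnorm(n)))
  expect_lt(abs(got3$r), 0.05)
  expect_error(partialCorrelation(x, y, data.frame(z = z, z2 = z)),
               "collinear")
})

test_that("age matching restricts, pairs greedily, and never reuses controls", {
  d <- data.frame(participant_id = paste0("p", 1:8),
                  sjl_flag = c(1, 1, 0, 0, 0, 0, 0, 0),
                  age = c(30, 40, 29, 31, 50, 33, 45, 70))
  m <- matchByAge(d, caliper = 12, seed = 1)
  expect_equal(nrow(m$pairs), 2L)
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
  expect_true(all(abs(m$pairs$age_sjl - m$pairs$age_control) <= 12))
  expect_true(m$pairs$age_control[m$pairs$age_sjl == 30] %in% c(29, 31))
  # identical age lists match exactly
  d2 <- data.frame(participant_id = paste0("q", 1:10),
                   sjl_flag = rep(c(1, 0), each = 5),
                   age = c(30:34, 30:34))
  m2 <- matchByAge(d2, seed = 2)
  expect_equal(m2$post_mean_diff, 0)
  # shifted distributions shrink the mean difference
  set.seed(26)
  d3 <- data.frame(participant_id = paste0("r", 1:300),
                   sjl_flag = rep(c(1, 0), c(50, 250)),
                   age = c(rnorm(50, 38, 10), rnorm(250, 47, 11)))
  m3 <- matchByAge(d3, caliper = 3, seed = 3)
  expect_lt(abs(m3$post_mean_diff), abs(m3$pre_mean_diff))
  expect_error(matchByAge(data.frame(participant_id = 1:4,
                                     sjl_flag = c(1, 1, 0, 0),
                                     age = c(20, 21, 60, 61))),
               "overlap")
})

test_that("chi-square group test reproduces hand-computed statistics", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  r0 <- categoricalGroupTest(t0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- categoricalGroupTest(matrix(c(30, 10, 10, 30), 2))
  expect_equal(r1$statistic, 20)   # sum (O-E)^2/E with E = 20 everywhere
  expect_error(categoricalGroupTest(matrix(c(0, 0, 5, 5), 2)), "margin")
})
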