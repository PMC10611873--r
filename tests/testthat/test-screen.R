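test_that("prevalence is the positive-abundance fraction, per group", {
  m <- matrix(0, nrow = 1, ncol = 10,
              dimnames = list("sp1", paste0("s", 1:10)))
  m[1, 1:2] <- 0.5
  expect_equal(unname(speciesPrevalence(m)), 0.2)
  expect_equal(unname(speciesPrevalence(matrix(0, 1, 5))), 0)
  # brute-force count oracle on a random table
  set.seed(2)
  r <- matrix(rbinom(20 * 30, 1, 0.4) * runif(600), nrow = 20)
  got <- speciesPrevalence(r)
  want <- apply(r, 1, function(v) sum(v > 0) / length(v))
  expect_equal(unname(got), unname(want))
  expect_error(speciesPrevalence(r, group = rep(FALSE, 30)), "empty")
})

test_that("Cohen's d matches the pooled-SD hand formula", {
  expect_equal(cohensD(c(2, 4), c(0, 2)), sqrt(2))
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(cohensD(x, y), -cohensD(y, x))
  expect_warning(d0 <- cohensD(c(1, 1), c(1, 1)), "pooled")
  expect_true(is.na(d0))
})

test_that("screen p-values equal exhaustive permutation for small groups", {
  # canonical 2v2 separation: U = 0, p = 2/6
  m <- rbind(sp1 = c(0.01, 0.02, 0.03, 0.04))
  m <- rbind(m, other = 1 - m[1, ])  # keep column sums at 1
  se <- sjlAbundance(m, sjl = c(TRUE, TRUE, FALSE, FALSE))
  tb <- screenTable(screenSpecies(se, prevalenceMin = 0))
  r1 <- tb[tb$species == "sp1", ]
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 1 / 3, tolerance = 1e-12)
  # randomized group sizes <= 5, no ties
  set.seed(17)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq(0.01, 0.96, by = 0.01), n1 + n2)
    w <- suppressWarnings(stats::wilcox.test(x[1:n1], x[-(1:n1)]))
    expect_equal(w$p.value, oracleMwuP(x[1:n1], x[-(1:n1)]),
                 tolerance = 1e-12)
  }
})

test_that("q-values use the prevalence-filtered family only", {
  set.seed(8)
  n <- 40
  sjl <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(runif(6 * n, 0.01, 0.1), nrow = 6,
              dimnames = list(paste0("sp", 1:6), paste0("s", 1:n)))
  m[5, ] <- ifelse(runif(n) < 0.05, 0.05, 0)  # ~5% prevalence: filtered
  m[6, ] <- 0
  m <- closedMatrix(rbind(m, filler = 1 - colSums(m)))
  m <- m[1:6, , drop = FALSE]
  se <- sjlAbundance(m, sjl = sjl)
  res <- screenSpecies(se)
  tb <- screenTable(res)
  expect_false(any(c("sp5", "sp6") %in% tb$species))
  expect_equal(res@nFiltered, 2L)  # sp5 (rare) and sp6 (absent) are out
  expect_equal(tb$q, oracleBH(tb$p))
  expect_true(all(tb$q >= tb$p - 1e-12))
})

test_that("identical groups give zero effect sizes and no hits", {
  set.seed(4)
  v <- runif(10, 0.01, 0.2)
  m <- rbind(sp1 = c(v, v))
  m <- rbind(m, rest = 1 - m[1, ])
  se <- sjlAbundance(m, sjl = rep(c(TRUE, FALSE), each = 10))
  tb <- screenTable(screenSpecies(se, prevalenceMin = 0))
  expect_equal(tb$d[tb$species == "sp1"], 0)
  expect_false(any(tb$significant))
})

test_that("screen is invariant to species order and per-species scaling", {
  se <- nullTable(nSamples = 60, nSpecies = 12, seed = 31)
  tb <- screenTable(screenSpecies(se))
  m <- relAbundance(se)
  perm <- sample(nrow(m))
  se2 <- sjlAbundance(m[perm, ], sjl = sjlStatus(se))
  tb2 <- screenTable(screenSpecies(se2))
  tb2 <- tb2[match(tb$species, tb2$species), ]
  expect_equal(tb$p, tb2$p)
  expect_equal(tb$q, tb2$q)
  # scaling one species by a positive constant leaves its rank test alone
  m3 <- m
  m3[tb$species[1], ] <- 0.5 * m3[tb$species[1], ]
  se3 <- sjlAbundance(m3, sjl = sjlStatus(se))
  tb3 <- screenTable(screenSpecies(se3))
  expect_equal(tb3$p[tb3$species == tb$species[1]], tb$p[1])
})

test_that("one-group prevalence screen matches a brute-force recount", {
  se <- nullTable(nSamples = 80, nSpecies = 30, seed = 12)
  got <- prevalenceDifferenceScreen(se, threshold = 0.2)
  m <- relAbundance(se)
  grp <- sjlStatus(se) == "sjl"
  p1 <- rowMeans(m[, grp] > 0); p0 <- rowMeans(m[, !grp] > 0)
  want <- names(p1)[xor(p1 >= 0.2, p0 >= 0.2)]
  expect_setequal(got$species, want)
  expect_equal(got$delta_prevalence,
               unname(sort(abs(p1 - p0)[want], decreasing = TRUE)))
  # boundary behaviour
  m2 <- rbind(a = c(rep(0.3, 5), rep(0, 15), rep(0.3, 2), rep(0, 18)),
              b = c(rep(0.3, 5), rep(0, 15), rep(0.3, 5), rep(0, 15)))
  m2 <- rbind(m2, rest = 1 - colSums(m2))
  se2 <- sjlAbundance(m2, sjl = rep(c(TRUE, FALSE), each = 20))
  out <- prevalenceDifferenceScreen(se2, threshold = 0.2)
  expect_true("a" %in% out$species)    # 0.25 vs 0.10
  expect_false("b" %in% out$species)   # 0.25 vs 0.25
})

test_that("random-forest discrimination separates a planted feature and stays at chance under the null", {
  set.seed(6)
  n <- 120
  sjl <- rep(c(TRUE, FALSE), each = n / 2)
  base <- matrix(runif(8 * n, 0.01, 0.1), nrow = 8)
  sep <- ifelse(sjl, 0.4, 0.05) + runif(n, 0, 0.01)  # separating species
  m <- closedMatrix(rbind(base, sep))
  rownames(m) <- paste0("sp", 1:9)
  se <- sjlAbundance(m, sjl = sjl)
  r <- bootstrapDiscrimination(se, nIter = 20, seed = 9)
  expect_gt(r$median_auc, 0.95)
  # same features, labels shuffled independently of them
  se0 <- sjlAbundance(m, sjl = sample(sjl))
  r0 <- bootstrapDiscrimination(se0, nIter = 20, seed = 9)
  expect_gt(r0$median_auc, 0.3)
  expect_lt(r0$median_auc, 0.7)
  # determinism under a fixed seed
  r2 <- bootstrapDiscrimination(se, nIter = 20, seed = 9)
  expect_identical(r$auc, r2$auc)
})
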