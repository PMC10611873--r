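# Independent oracles used across the suite. These re-derive expected
# results by enumeration or closed form, never by calling the package path
# they check.

# Eating-occasion oracle: enumerate every contiguous partition of the
# (sorted) event stream into blocks; the valid partition is the one where
# within-block gaps are < gapMin and between-block gaps are >= gapMin.
# Then apply the kcal floor and sex thresholds.
oracleSegment <- function(hours, kcal, sex, gapMin = 30, kcalFloor = 50) {
  o <- order(hours)
  hours <- hours[o]; kcal <- kcal[o]
  n <- length(hours)
  gaps_min <- round(diff(hours) * 60, 6)
  valid <- NULL
  # each of the n-1 gaps is either a cut (TRUE) or not; enumerate all
  cuts_choices <- if (n == 1L) list(logical(0)) else {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), n - 1L))
    lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
  }
  for (cuts in cuts_choices) {
    ok <- all((gaps_min >= gapMin) == cuts)
    if (ok) { valid <- cuts; break }
  }
  stopifnot(!is.null(valid))
  block <- cumsum(c(TRUE, valid))
  thr <- if (sex == "female") 400 else 500
  out <- do.call(rbind, lapply(split(seq_len(n), block), function(ix) {
    e <- sum(kcal[ix])
    data.frame(start_h = min(hours[ix]), end_h = max(hours[ix]), kcal = e,
               n_events = length(ix),
               class = if (e >= thr) "main_meal" else "snack")
  }))
  out <- out[out$kcal >= kcalFloor, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive two-sided Mann-Whitney permutation p-value (no ties assumed):
# the proportion of label assignments whose U deviates from n1*n2/2 at
# least as much as the observed U.
oracleMwuP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  uStat <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- uStat(seq_len(n1))
  mid <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, uStat)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# Hand Benjamini-Hochberg: q_i = min over j >= i of p_(j) * m / j.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small helper: abundance matrix (species x samples) closed to sum 1
closedMatrix <- function(m) sweep(m, 2L, colSums(m), "/")

# random SjlAbundance table with all-null species
nullTable <- function(nSamples = 200, nSpecies = 50, seed = 1,
                      sjlFrac = 0.16) {
  set.seed(seed)
  w <- exp(rnorm(nSpecies, 0, 1))
  m <- sapply(seq_len(nSamples), function(i) {
    v <- w * exp(rnorm(nSpecies, 0, 0.6))
    v[runif(nSpecies) < 0.25] <- 0
    v
  })
  keepable <- colSums(m) > 0
  m <- closedMatrix(m[, keepable, drop = FALSE])
  rownames(m) <- sprintf("sp%03d", seq_len(nSpecies))
  sjlAbundance(m, sjl = runif(ncol(m)) < sjlFrac)
}
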