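#' Arcsine square-root transform for relative abundances
#'
#' The variance-stabilising transform `asin(sqrt(p))` (radians) for
#' proportions in `[0, 1]`.
#'
#' @param p relative abundances in `[0, 1]`.
#' @return transformed values in `[0, pi/2]`.
#' @examples
#' asinSqrt(c(0, 0.25, 1))
#' @export
asinSqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("relative abundances must lie in [0, 1]")
  asin(sqrt(p))
}

#' Per-group species prevalence
#'
#' Prevalence of a species in a group is the fraction of the group's samples
#' in which its relative abundance is strictly positive.
#'
#' @param x an [SjlAbundance-class] object or a species-by-sample matrix.
#' @param group optional; restrict to samples with this `sjl` label
#'   (`"sjl"` / `"no_sjl"`). For a matrix input, a logical/character vector
#'   selecting columns.
#' @return named numeric vector, one prevalence per species.
#' @export
speciesPrevalence <- function(x, group = NULL) {
  if (methods::is(x, "SjlAbundance")) {
    m <- relAbundance(x)
    if (!is.null(group)) m <- m[, sjlStatus(x) == group, drop = FALSE]
  } else {
    m <- as.matrix(x)
    if (!is.null(group)) m <- m[, group, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("empty group")
  rowMeans(m > 0)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with the pooled SD weighted by `n - 1`.
#' Returns `NA` (with a warning) when the pooled SD is zero.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return standardized mean difference.
#' @examples
#' cohensD(c(2, 4), c(0, 2))  # sqrt(2)
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Prevalence-filtered Mann-Whitney differential-abundance screen
#'
#' Species prevalent (abundance > 0) in at least `prevalenceMin` of BOTH
#' groups are compared between social-jetlag groups with a two-sided
#' Mann-Whitney U test on relative abundances (exact p for combined
#' n <= 20 without ties, otherwise normal approximation with tie and
#' continuity correction). Benjamini-Hochberg q-values are computed across
#' the retained species only. Cohen's d is computed on arcsine-square-root
#' transformed abundances (SJL minus no-SJL) with pooled SD; a species is
#' significant when `q < qMax` and `|d| > dMin`.
#'
#' @param x an [SjlAbundance-class] object.
#' @param prevalenceMin minimum per-group prevalence. Default 0.20.
#' @param qMax FDR cut-off. Default 0.2.
#' @param dMin absolute effect-size cut-off. Default 0.2.
#' @param dScale `"asinsqrt"` (default) or `"raw"`: scale on which Cohen's d
#'   is computed.
#' @return a [ScreenResult-class]; see [screenTable()].
#' @export
screenSpecies <- function(x, prevalenceMin = 0.20, qMax = 0.2, dMin = 0.2,
                          dScale = c("asinsqrt", "raw")) {
  dScale <- match.arg(dScale)
  stopifnot(methods::is(x, "SjlAbundance"))
  grp <- sjlStatus(x)
  if (sum(grp == "sjl") < 2L || sum(grp == "no_sjl") < 2L)
    stop("both groups need at least 2 samples")
  m <- relAbundance(x)
  prev_sjl <- speciesPrevalence(x, "sjl")
  prev_no <- speciesPrevalence(x, "no_sjl")
  keep <- prev_sjl >= prevalenceMin & prev_no >= prevalenceMin
  nFiltered <- sum(!keep)
  if (!any(keep)) {
    warning("no species pass the prevalence filter")
    tb <- S4Vectors::DataFrame(species = character(), prev_sjl = numeric(),
                               prev_no_sjl = numeric(), U = numeric(),
                               p = numeric(), q = numeric(), d = numeric(),
                               significant = logical(),
                               direction = character())
    return(methods::new("ScreenResult", table = tb,
                        nFiltered = as.integer(nFiltered),
                        thresholds = list(prevalence = prevalenceMin,
                                          q = qMax, d = dMin,
                                          dScale = dScale)))
  }
  mk <- m[keep, , drop = FALSE]
  is_sjl <- grp == "sjl"
  res <- t(apply(mk, 1L, function(v) {
    xs <- v[is_sjl]; ys <- v[!is_sjl]
    wt <- suppressWarnings(stats::wilcox.test(xs, ys, exact = NULL,
                                              correct = TRUE))
    dv <- if (dScale == "asinsqrt") {
      cohensD(asinSqrt(xs), asinSqrt(ys))
    } else cohensD(xs, ys)
    c(U = unname(wt$statistic), p = wt$p.value, d = dv)
  }))
  q <- stats::p.adjust(res[, "p"], method = "BH")
  dvec <- res[, "d"]
  sig <- q < qMax & !is.na(dvec) & abs(dvec) > dMin
  tb <- S4Vectors::DataFrame(
    species = rownames(mk),
    prev_sjl = unname(prev_sjl[keep]),
    prev_no_sjl = unname(prev_no[keep]),
    U = unname(res[, "U"]),
    p = unname(res[, "p"]),
    q = unname(q),
    d = unname(dvec),
    significant = unname(sig),
    direction = ifelse(is.na(dvec) | dvec == 0, NA_character_,
                       ifelse(dvec > 0, "up_in_SJL", "down_in_SJL"))
  )
  methods::new("ScreenResult", table = tb, nFiltered = as.integer(nFiltered),
               thresholds = list(prevalence = prevalenceMin, q = qMax,
                                 d = dMin, dScale = dScale))
}

#' Species prevalent in exactly one group
#'
#' Reports species whose prevalence reaches `threshold` in one group but not
#' the other, with the absolute prevalence difference, sorted descending.
#'
#' @param x an [SjlAbundance-class] object.
#' @param threshold prevalence cut-off. Default 0.20.
#' @return data.frame: species, per-group prevalences, `delta_prevalence`,
#'   `prevalent_in`.
#' @export
prevalenceDifferenceScreen <- function(x, threshold = 0.20) {
  prev_sjl <- speciesPrevalence(x, "sjl")
  prev_no <- speciesPrevalence(x, "no_sjl")
  one_only <- xor(prev_sjl >= threshold, prev_no >= threshold)
  out <- data.frame(species = names(prev_sjl)[one_only],
                    prev_sjl = unname(prev_sjl[one_only]),
                    prev_no_sjl = unname(prev_no[one_only]),
                    delta_prevalence = abs(prev_sjl - prev_no)[one_only],
                    prevalent_in = ifelse(prev_sjl[one_only] >= threshold,
                                          "sjl", "no_sjl"))
  out <- out[order(-out$delta_prevalence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rank-based AUC of scores for a binary label (Mann-Whitney formula).
.rankAuc <- function(score, label) {
  pos <- label == levels(factor(label))[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap evaluation of whole-microbiome group discrimination
#'
#' Trains a random-forest classifier (all species as features) on stratified
#' 80/20 train/test splits over `nIter` bootstrap iterations and reports the
#' median test AUC. A split that leaves one class absent from the test set
#' is resampled (and counted).
#'
#' @param x an [SjlAbundance-class] object.
#' @param nIter iterations. Default 100.
#' @param split training fraction. Default 0.8.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param numTrees trees per forest. Default 200.
#' @return list with `median_auc`, `auc` (per-iteration vector) and
#'   `n_resampled`.
#' @export
bootstrapDiscrimination <- function(x, nIter = 100, split = 0.8, seed = 1,
                                    numTrees = 200) {
  stopifnot(methods::is(x, "SjlAbundance"))
  grp <- factor(sjlStatus(x), levels = c("no_sjl", "sjl"))
  if (nlevels(droplevels(grp)) < 2L) stop("both classes must be present")
  feat <- t(relAbundance(x))
  colnames(feat) <- make.names(colnames(feat))
  df <- data.frame(feat, check.names = FALSE)
  rng <- .seededRng(seed)
  aucs <- numeric(nIter)
  n_res <- 0L
  idx_by_class <- split(seq_along(grp), grp)
  for (it in seq_len(nIter)) {
    repeat {
      tr <- unlist(lapply(idx_by_class, function(ix)
        .rngSample(rng, ix, size = max(1L, round(split * length(ix))))))
      te <- setdiff(seq_along(grp), tr)
      if (length(unique(grp[te])) == 2L) break
      n_res <- n_res + 1L
    }
    fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = grp[tr],
                          probability = TRUE, num.trees = numTrees,
                          seed = .rngInt(rng), num.threads = 1L,
                          verbose = FALSE)
    pr <- stats::predict(fit, df[te, , drop = FALSE],
                         num.threads = 1L)$predictions[, "sjl"]
    aucs[it] <- .rankAuc(pr, grp[te])
  }
  list(median_auc = stats::median(aucs), auc = aucs, n_resampled = n_res)
}
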