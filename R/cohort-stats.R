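# Transform selection: Shapiro-Wilk on the raw outcome; when non-normal,
# log (positive data) and sqrt (non-negative data) candidates are tried and
# the one with the larger Shapiro-Wilk W wins.
.selectTransform <- function(y, alpha = 0.05) {
  ys <- y[!is.na(y)]
  if (length(unique(ys)) < 3L) stop("outcome is (near-)constant")
  sw <- function(v) {
    if (length(v) > 5000) v <- v[seq(1L, length(v), length.out = 5000)]
    suppressWarnings(stats::shapiro.test(v))
  }
  raw <- sw(ys)
  if (raw$p.value >= alpha)
    return(list(name = "none", f = identity, note = ""))
  cand <- list()
  note <- ""
  if (all(ys > 0)) cand$log <- sw(log(ys))$statistic
  else note <- "log skipped (non-positive values)"
  if (all(ys >= 0)) cand$sqrt <- sw(sqrt(ys))$statistic
  if (length(cand) == 0L)
    return(list(name = "none", f = identity,
                note = "no applicable transform"))
  best <- names(cand)[which.max(unlist(cand))]
  list(name = best, f = if (best == "log") log else sqrt, note = note)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Tests a group difference in a continuous outcome adjusted for covariates
#' with a linear model `outcome ~ group + covariates`. The raw outcome is
#' checked for normality (Shapiro-Wilk); when p < 0.05 a log or sqrt
#' transform is applied (whichever yields the larger W, subject to domain).
#' The reported difference is the group coefficient (SJL minus no-SJL) on
#' the analysis scale.
#'
#' @param data data.frame.
#' @param outcome name of the outcome column.
#' @param group name of the binary group column (logical, 0/1 or two-level
#'   factor; second level / `TRUE` is the SJL group).
#' @param covariates character vector of covariate names.
#' @param familyId optional column name; when given, cluster-robust
#'   (CR-type) standard errors on this ID are used for the group test.
#' @param transform `"auto"` (default), `"none"`, `"log"` or `"sqrt"`.
#' @return one-row data.frame: `outcome`, `estimate`, `se`, `p`,
#'   `transform`, `n`.
#' @export
ancovaCompare <- function(data, outcome, group, covariates = character(),
                          familyId = NULL, transform = "auto") {
  vars <- c(outcome, group, covariates, familyId)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  g <- d[[group]]
  if (is.logical(g)) g <- as.integer(g)
  if (is.factor(g) || is.character(g)) g <- as.integer(factor(g)) - 1L
  if (!all(g %in% c(0, 1))) stop("group must be binary")
  y <- d[[outcome]]
  if (length(unique(y[!is.na(y)])) < 3L) stop("outcome is (near-)constant")
  tr <- if (transform == "auto") .selectTransform(y)
        else list(name = transform,
                  f = switch(transform, none = identity, log = log,
                             sqrt = sqrt,
                             stop("unknown transform: ", transform)),
                  note = "")
  md <- data.frame(.y = tr$f(y), .g = g)
  for (cv in covariates) {
    v <- d[[cv]]
    md[[cv]] <- if (is.character(v)) factor(v) else v
  }
  fml <- stats::as.formula(paste(".y ~ .g",
    if (length(covariates))
      paste("+", paste(sprintf("`%s`", covariates), collapse = " + "))
    else ""))
  fit <- stats::lm(fml, data = md)
  if (!is.null(familyId)) {
    vc <- sandwich::vcovCL(fit, cluster = factor(d[[familyId]]))
    ct <- lmtest::coeftest(fit, vcov. = vc)
    est <- ct[".g", "Estimate"]; se <- ct[".g", "Std. Error"]
    p <- ct[".g", "Pr(>|t|)"]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[".g", "Estimate"]; se <- sm[".g", "Std. Error"]
    p <- sm[".g", "Pr(>|t|)"]
  }
  data.frame(outcome = outcome, estimate = est, se = se, p = p,
             transform = tr$name, n = nrow(md))
}

#' ANCOVA over a family of outcomes with BH correction
#'
#' Applies [ancovaCompare()] to each outcome and appends Benjamini-Hochberg
#' q-values across the family.
#'
#' @inheritParams ancovaCompare
#' @param outcomes character vector of outcome column names forming one
#'   multiple-testing family (e.g. the fasting-biomarker panel).
#' @return data.frame with one row per outcome plus a `q` column.
#' @export
ancovaTable <- function(data, outcomes, group, covariates = character(),
                        familyId = NULL) {
  rows <- lapply(outcomes, function(oc)
    ancovaCompare(data, oc, group, covariates, familyId))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Group-by-moderator interaction model
#'
#' Fits `outcome ~ group * moderator + covariates` and reports the
#' interaction term(s) with simple-effects contrasts of group within each
#' moderator level (continuous moderators are tested at the mean +/- 1 SD).
#'
#' @inheritParams ancovaCompare
#' @param moderator name of the moderator column (e.g. sex, age, menopause).
#' @return list with `interaction` (coefficient table rows for the
#'   interaction terms) and `simple_effects` (an emmeans contrast
#'   data.frame).
#' @export
interactionModel <- function(data, outcome, group, moderator,
                             covariates = character()) {
  vars <- c(outcome, group, moderator, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  g <- d[[group]]
  if (is.logical(g) || is.numeric(g))
    g <- ifelse(as.numeric(g) > 0, "sjl", "no_sjl")
  g <- droplevels(factor(g))
  if (nlevels(g) != 2L) stop("group must have two levels")
  mo <- d[[moderator]]
  if (is.character(mo)) mo <- factor(mo)
  if (is.factor(mo)) {
    mo <- droplevels(mo)
    if (nlevels(mo) < 2L) stop("moderator '", moderator, "' has one level")
    tb <- table(g, mo)
    if (any(tb == 0L)) {
      empty <- which(tb == 0L, arr.ind = TRUE)[1L, ]
      stop(sprintf("empty cell: group %s x %s %s", rownames(tb)[empty[1L]],
                   moderator, colnames(tb)[empty[2L]]))
    }
  }
  md <- data.frame(.y = d[[outcome]], .g = g, .mo = mo)
  for (cv in covariates) {
    v <- d[[cv]]
    md[[cv]] <- if (is.character(v)) factor(v) else v
  }
  fml <- stats::as.formula(paste(".y ~ .g * .mo",
    if (length(covariates))
      paste("+", paste(sprintf("`%s`", covariates), collapse = " + "))
    else ""))
  fit <- stats::lm(fml, data = md)
  sm <- summary(fit)$coefficients
  int_rows <- grepl("^\\.g.*:", rownames(sm))
  interaction <- data.frame(term = rownames(sm)[int_rows],
                            estimate = sm[int_rows, "Estimate"],
                            se = sm[int_rows, "Std. Error"],
                            p = sm[int_rows, "Pr(>|t|)"],
                            row.names = NULL)
  emm <- if (is.factor(mo)) {
    emmeans::emmeans(fit, ~ .g | .mo)
  } else {
    mvals <- c(mean(mo) - stats::sd(mo), mean(mo) + stats::sd(mo))
    emmeans::emmeans(fit, ~ .g | .mo, at = list(.mo = mvals))
  }
  se_df <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  list(interaction = interaction, simple_effects = se_df)
}

#' Pearson partial correlation via double residualisation
#'
#' Residualises `x` and `y` on the covariates with linear models and
#' correlates the residuals; the p-value uses the t distribution with
#' `n - k - 2` degrees of freedom, `k` the number of covariate columns
#' after expansion.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or vector) of covariates.
#' @return data.frame with `r`, `p`, `n`, `df`.
#' @export
partialCorrelation <- function(x, y, covariates) {
  cv <- as.data.frame(covariates)
  ok <- stats::complete.cases(cbind(x, y, cv))
  x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  n <- length(x)
  X <- stats::model.matrix(~ ., data = cv)
  k <- ncol(X) - 1L
  if (n <= k + 2L) stop("need n > n_covariates + 2")
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.frame(r = r, p = p, n = n, df = df)
}

#' Greedy nearest-neighbour age matching of SJL to control participants
#'
#' Controls are restricted to the overlapping age range of the two groups;
#' each SJL participant, in seeded random order, is matched to the nearest
#' unused control by age. SJL participants whose nearest available control
#' is farther than `caliper` years are dropped and logged.
#'
#' @param data data.frame with an ID, group and age column.
#' @param idCol,groupCol,ageCol column names. `groupCol` is logical / 0-1 /
#'   two-level, second level = SJL.
#' @param caliper years; maximum allowed age difference. Default `Inf`.
#' @param seed integer; order in which SJL participants are matched.
#' @return list with `pairs` (data.frame sjl_id, control_id, age_sjl,
#'   age_control), `unmatched` (dropped SJL IDs), `pre_mean_diff` and
#'   `post_mean_diff` (years, SJL minus control means).
#' @export
matchByAge <- function(data, idCol = "participant_id", groupCol = "sjl_flag",
                       ageCol = "age", caliper = Inf, seed = 1) {
  g <- data[[groupCol]]
  if (is.logical(g)) g <- as.integer(g)
  if (is.factor(g) || is.character(g)) g <- as.integer(factor(g)) - 1L
  sjl <- data[g == 1, c(idCol, ageCol)]
  ctl <- data[g == 0, c(idCol, ageCol)]
  if (nrow(sjl) == 0L || nrow(ctl) == 0L) stop("both groups must be non-empty")
  lo <- max(min(sjl[[ageCol]]), min(ctl[[ageCol]]))
  hi <- min(max(sjl[[ageCol]]), max(ctl[[ageCol]]))
  if (lo > hi) stop("no overlapping age range between groups")
  ctl <- ctl[ctl[[ageCol]] >= lo & ctl[[ageCol]] <= hi, , drop = FALSE]
  if (nrow(ctl) == 0L) stop("no controls in the overlapping age range")
  pre <- mean(sjl[[ageCol]]) - mean(data[g == 0, ageCol])
  rng <- .seededRng(seed)
  ord <- .rngSample(rng, seq_len(nrow(sjl)), nrow(sjl))
  used <- rep(FALSE, nrow(ctl))
  pairs <- list(); unmatched <- character()
  for (i in ord) {
    a <- sjl[[ageCol]][i]
    dist <- abs(ctl[[ageCol]] - a)
    dist[used] <- Inf
    j <- which.min(dist)
    if (!is.finite(dist[j]) || dist[j] > caliper) {
      unmatched <- c(unmatched, as.character(sjl[[idCol]][i]))
      next
    }
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      sjl_id = sjl[[idCol]][i], control_id = ctl[[idCol]][j],
      age_sjl = a, age_control = ctl[[ageCol]][j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sjl_id = character(), control_id = character(),
               age_sjl = numeric(), age_control = numeric())
  post <- if (nrow(pairs)) mean(pairs$age_sjl) - mean(pairs$age_control)
          else NA_real_
  list(pairs = pairs, unmatched = unmatched,
       pre_mean_diff = pre, post_mean_diff = post)
}

#' Chi-square test on a group-by-level contingency table
#'
#' Pearson chi-square without Yates continuity correction by default.
#'
#' @param counts matrix or table of non-negative counts.
#' @param correct apply the continuity correction (2x2 only).
#' @return data.frame with `statistic`, `df`, `p`.
#' @export
categoricalGroupTest <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero-margin row or column")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  data.frame(statistic = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value)
}
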