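#' Causal mediation of a binary exposure through a continuous mediator
#'
#' Fits the mediator model `M ~ X + covariates` and the outcome model
#' `Y ~ X + M + covariates`, each with a family random intercept when
#' `cluster` is given (via [lme4::lmer]) and as plain linear models
#' otherwise. Point estimates are the product-of-coefficients decomposition
#' without exposure-mediator interaction: ACME `= a b`, ADE `= c'`, total
#' `= c' + a b`. Inference is quasi-Bayesian: `nSims` draws of the
#' coefficients from their asymptotic joint normal distributions, the
#' effects recomputed per draw; 95 percent intervals are percentile
#' intervals and two-sided p-values are simulation tail probabilities. The
#' proportion mediated is summarised by the median of `a b / (c' + a b)`
#' over draws; values outside `[0, 1]` are retained, and the proportion is
#' flagged unstable when the total-effect interval covers zero.
#'
#' The intended outcome scale for species abundances is
#' arcsine-square-root transformed relative abundance ([asinSqrt()]).
#'
#' @param data data.frame with all referenced columns.
#' @param exposure name of the binary exposure column (logical, 0/1 or
#'   two-level factor; e.g. the SJL flag).
#' @param mediator name of the mediator column (e.g. hPDI or nut intake).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names (e.g. sex,
#'   age, BMI, ethnicity, education). Categorical covariates enter as
#'   treatment-coded factors.
#' @param cluster optional name of the family-ID column for the random
#'   intercept.
#' @param nSims quasi-Bayesian draws, >= 100. Default 1000.
#' @param seed integer seed for the draws.
#' @return a [MediationResult-class] object.
#' @examples
#' set.seed(7)
#' n <- 400
#' x <- rbinom(n, 1, 0.3)
#' m <- 0.5 * x + rnorm(n)
#' y <- 0.8 * x + 0.4 * m + rnorm(n)
#' fitMediation(data.frame(x = x, m = m, y = y), "x", "m", "y", nSims = 200)
#' @export
fitMediation <- function(data, exposure, mediator, outcome,
                         covariates = character(), cluster = NULL,
                         nSims = 1000, seed = 1) {
  if (nSims < 100) stop("nSims must be >= 100")
  vars <- c(exposure, mediator, outcome, covariates, cluster)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  x <- d[[exposure]]
  if (is.logical(x)) x <- as.integer(x)
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    if (nlevels(x) != 2L) stop("exposure must be binary")
    x <- as.integer(x) - 1L
  }
  if (!all(x %in% c(0, 1))) stop("exposure must be binary (0/1)")
  md <- data.frame(.x = x, .m = d[[mediator]], .y = d[[outcome]])
  for (cv in covariates) {
    v <- d[[cv]]
    md[[cv]] <- if (is.character(v)) factor(v) else v
  }
  covTerm <- if (length(covariates))
    paste("+", paste(sprintf("`%s`", covariates), collapse = " + ")) else ""
  if (!is.null(cluster)) {
    md$.cluster <- factor(d[[cluster]])
    fm <- stats::as.formula(paste(".m ~ .x", covTerm, "+ (1 | .cluster)"))
    fy <- stats::as.formula(paste(".y ~ .x + .m", covTerm, "+ (1 | .cluster)"))
    mod_m <- lme4::lmer(fm, data = md)
    mod_y <- lme4::lmer(fy, data = md)
    cf_m <- lme4::fixef(mod_m); vc_m <- as.matrix(stats::vcov(mod_m))
    cf_y <- lme4::fixef(mod_y); vc_y <- as.matrix(stats::vcov(mod_y))
  } else {
    fm <- stats::as.formula(paste(".m ~ .x", covTerm))
    fy <- stats::as.formula(paste(".y ~ .x + .m", covTerm))
    mod_m <- stats::lm(fm, data = md)
    mod_y <- stats::lm(fy, data = md)
    cf_m <- stats::coef(mod_m)
    cf_y <- stats::coef(mod_y)
    if (anyNA(cf_m) || anyNA(cf_y)) {
      bad <- unique(c(names(cf_m)[is.na(cf_m)], names(cf_y)[is.na(cf_y)]))
      stop("singular fit; aliased term(s): ", paste(bad, collapse = ", "))
    }
    vc_m <- stats::vcov(mod_m); vc_y <- stats::vcov(mod_y)
  }
  a <- unname(cf_m[".x"])
  b <- unname(cf_y[".m"])
  cprime <- unname(cf_y[".x"])

  rng <- .seededRng(seed)
  draws_m <- .withRng(rng, function() MASS::mvrnorm(nSims, cf_m, vc_m))
  draws_y <- .withRng(rng, function() MASS::mvrnorm(nSims, cf_y, vc_y))
  a_s <- draws_m[, ".x"]
  b_s <- draws_y[, ".m"]
  c_s <- draws_y[, ".x"]
  acme_s <- a_s * b_s
  total_s <- acme_s + c_s
  prop_s <- acme_s / total_s

  tail_p <- function(s) min(1, 2 * min(mean(s <= 0), mean(s >= 0)))
  qs <- function(s) stats::quantile(s, c(0.025, 0.975), names = FALSE)
  ci <- rbind(acme = qs(acme_s), ade = qs(c_s), total = qs(total_s),
              propMediated = qs(prop_s))
  colnames(ci) <- c("lower", "upper")
  flags <- character()
  if (ci["total", 1] <= 0 && ci["total", 2] >= 0)
    flags <- c(flags, "unstable_proportion")
  methods::new("MediationResult",
    estimates = c(acme = a * b, ade = cprime, total = cprime + a * b,
                  propMediated = stats::median(prop_s)),
    ci = ci,
    pvalues = c(acme = tail_p(acme_s), ade = tail_p(c_s),
                total = tail_p(total_s), propMediated = tail_p(acme_s)),
    spec = list(exposure = exposure, mediator = mediator, outcome = outcome,
                covariates = covariates, cluster = cluster),
    nobs = nrow(md), nSims = as.integer(nSims), flags = flags)
}

#' Mediation over a grid of mediator-outcome pairs
#'
#' Runs [fitMediation()] for every combination of `mediators` and
#' `outcomes` with a shared exposure, covariate set and seed; identical
#' specifications therefore give identical rows. Failures of individual
#' pairs are recorded and do not stop the batch.
#'
#' @inheritParams fitMediation
#' @param mediators,outcomes character vectors of column names.
#' @return data.frame with one row per pair: estimates, 95 percent CIs,
#'   p-values, n, flags (`error` column carries any failure message).
#' @export
batchMediate <- function(data, mediators, outcomes, exposure,
                         covariates = character(), cluster = NULL,
                         nSims = 1000, seed = 1) {
  grid <- expand.grid(mediator = mediators, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mi <- grid$mediator[i]; oi <- grid$outcome[i]
    res <- tryCatch(
      fitMediation(data, exposure, mi, oi, covariates, cluster,
                   nSims = nSims, seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(mediator = mi, outcome = oi, acme = NA_real_,
                        acme_lower = NA_real_, acme_upper = NA_real_,
                        acme_p = NA_real_, ade = NA_real_, total = NA_real_,
                        total_p = NA_real_, prop_mediated = NA_real_,
                        prop_p = NA_real_, n = NA_integer_, flags = "",
                        error = conditionMessage(res)))
    }
    e <- res@estimates; ci <- res@ci; p <- res@pvalues
    data.frame(mediator = mi, outcome = oi, acme = e[["acme"]],
               acme_lower = ci["acme", 1], acme_upper = ci["acme", 2],
               acme_p = p[["acme"]], ade = e[["ade"]], total = e[["total"]],
               total_p = p[["total"]], prop_mediated = e[["propMediated"]],
               prop_p = p[["propMediated"]], n = res@nobs,
               flags = paste(res@flags, collapse = ";"), error = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
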