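#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' SjlAbundance: species relative abundances with social-jetlag labels
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' species-by-sample relative-abundance matrix (assay `"relabund"`, fractions
#' in `[0, 1]`) together with a per-sample social-jetlag group label in
#' `colData(x)$sjl` (factor with levels `no_sjl`, `sjl`).
#'
#' @slot .Data inherited `SummarizedExperiment` structure.
#' @seealso [sjlAbundance()], [relAbundance()], [sjlStatus()]
#' @export
setClass("SjlAbundance", contains = "SummarizedExperiment")

setValidity("SjlAbundance", function(object) {
  msg <- character()
  if (!"relabund" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'relabund' is required")
  else {
    a <- SummarizedExperiment::assay(object, "relabund")
    if (anyNA(a)) msg <- c(msg, "abundances must not contain NA")
    else {
      if (any(a < 0)) msg <- c(msg, "abundances must be non-negative")
      cs <- colSums(a)
      if (any(cs > 1 + 1e-6))
        msg <- c(msg, "per-sample abundances must sum to <= 1 + 1e-6")
    }
  }
  if (!"sjl" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'sjl' (group label) is required")
  else {
    g <- SummarizedExperiment::colData(object)$sjl
    if (!all(levels(factor(g)) %in% c("no_sjl", "sjl")))
      msg <- c(msg, "sjl labels must be 'sjl' or 'no_sjl'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SjlAbundance object
#'
#' @param abundance numeric matrix, species in rows, samples in columns,
#'   relative abundances in `[0, 1]`.
#' @param sjl per-sample group label; logical (`TRUE` = social jetlag) or a
#'   character/factor with values `"sjl"` / `"no_sjl"`.
#' @param ... further per-sample columns appended to `colData`.
#' @return an [SjlAbundance-class] object.
#' @examples
#' a <- matrix(c(0.6, 0.4, 0.3, 0.7), nrow = 2,
#'             dimnames = list(c("sp1", "sp2"), c("s1", "s2")))
#' se <- sjlAbundance(a, sjl = c(TRUE, FALSE))
#' sjlStatus(se)
#' @export
sjlAbundance <- function(abundance, sjl, ...) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("species_%03d", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("sample_%04d", seq_len(ncol(abundance)))
  if (is.logical(sjl)) sjl <- ifelse(sjl, "sjl", "no_sjl")
  sjl <- factor(as.character(sjl), levels = c("no_sjl", "sjl"))
  if (length(sjl) != ncol(abundance))
    stop("length(sjl) must equal ncol(abundance)")
  cd <- S4Vectors::DataFrame(sjl = sjl, ..., row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = abundance), colData = cd)
  methods::new("SjlAbundance", se)
}

#' ScreenResult: per-species differential-abundance screen
#'
#' Result container for the prevalence-filtered Mann-Whitney screen. The
#' per-species table is retrieved with [screenTable()]; thresholds used are
#' stored in `metadata`.
#'
#' @slot table `DataFrame` with one row per tested species (prevalence in
#'   each group, U, p, q, Cohen's d, significance, direction).
#' @slot nFiltered number of species removed by the prevalence filter.
#' @slot thresholds named list (prevalence, q, d cut-offs, d scale).
#' @export
setClass("ScreenResult",
  representation(table = "DataFrame", nFiltered = "integer",
                 thresholds = "list"))

#' MediationResult: causal mediation estimates for one exposure-mediator-outcome triple
#'
#' @slot estimates named numeric: `acme`, `ade`, `total`, `propMediated`.
#' @slot ci 4x2 matrix of simulation-based 95 percent intervals.
#' @slot pvalues named numeric simulation-based two-sided p-values.
#' @slot spec list recording exposure, mediator, outcome, covariates, cluster.
#' @slot nobs integer; complete cases used.
#' @slot nSims integer; quasi-Bayesian draws.
#' @slot flags character; e.g. `"unstable_proportion"` when the total effect
#'   is indistinguishable from zero.
#' @export
setClass("MediationResult",
  representation(estimates = "numeric", ci = "matrix", pvalues = "numeric",
                 spec = "list", nobs = "integer", nSims = "integer",
                 flags = "character"))

#' CohortBundle: a complete synthetic cohort with ground truth
#'
#' All tables are keyed by the shared `participant_id`. The `groundTruth`
#' list records exactly which species carry planted direct or diet-mediated
#' social-jetlag effects, with their true path coefficients.
#'
#' @slot demographics data.frame (sex, age, BMI, ethnicity, education,
#'   menopause, family_id, weight, height).
#' @slot sleep data.frame of questionnaire bed/wake times and PSQI.
#' @slot meals data.frame of time-stamped meal-log events (timestamp, kcal).
#' @slot ffq data.frame of food-group intakes (g/day) and total energy.
#' @slot cgm data.frame CGM trace (participant, timestamp, glucose mmol/L).
#' @slot postprandial data.frame (participant, analyte, minute, value).
#' @slot abundance [SjlAbundance-class] species x samples.
#' @slot groundTruth list of planted effects.
#' @slot config list; the generating configuration.
#' @export
setClass("CohortBundle",
  representation(demographics = "data.frame", sleep = "data.frame",
                 meals = "data.frame", ffq = "data.frame",
                 cgm = "data.frame", postprandial = "data.frame",
                 abundance = "SjlAbundance", groundTruth = "list",
                 config = "list"))

setValidity("CohortBundle", function(object) {
  ids <- object@demographics$participant_id
  msg <- character()
  if (is.null(ids)) return("demographics must carry participant_id")
  for (tab in c("sleep", "ffq")) {
    t_ids <- methods::slot(object, tab)$participant_id
    if (!setequal(t_ids, ids))
      msg <- c(msg, sprintf("%s IDs do not match demographics", tab))
  }
  cs <- colSums(SummarizedExperiment::assay(object@abundance, "relabund"))
  if (any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "abundance columns must sum to 1 +/- 1e-9")
  if (length(msg)) msg else TRUE
})
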