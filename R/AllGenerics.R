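#' Accessors for chronogut S4 containers
#'
#' `relAbundance()` returns the species-by-sample relative-abundance matrix;
#' `sjlStatus()` the per-sample social-jetlag factor; `screenTable()` the
#' per-species screen table as a data.frame; `groundTruth()` the planted
#' effects of a synthetic [CohortBundle-class].
#'
#' @param x an [SjlAbundance-class], [ScreenResult-class] or
#'   [CohortBundle-class] object.
#' @return see the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("sjlStatus", function(x) standardGeneric("sjlStatus"))

#' @rdname accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("relAbundance", "SjlAbundance", function(x)
  SummarizedExperiment::assay(x, "relabund"))

#' @rdname accessors
#' @export
setMethod("sjlStatus", "SjlAbundance", function(x)
  SummarizedExperiment::colData(x)$sjl)

#' @rdname accessors
#' @export
setMethod("screenTable", "ScreenResult", function(x) as.data.frame(x@table))

#' @rdname accessors
#' @export
setMethod("groundTruth", "CohortBundle", function(x) x@groundTruth)

setMethod("show", "SjlAbundance", function(object) {
  g <- table(sjlStatus(object))
  cat("SjlAbundance:", nrow(object), "species x", ncol(object), "samples\n")
  cat("  groups: sjl =", g[["sjl"]], "| no_sjl =", g[["no_sjl"]], "\n")
})

setMethod("show", "ScreenResult", function(object) {
  tb <- object@table
  cat("ScreenResult:", nrow(tb), "species tested (",
      object@nFiltered, "removed by prevalence filter )\n")
  cat(sprintf("  significant (q < %g & |d| > %g): %d\n",
              object@thresholds$q, object@thresholds$d,
              sum(tb$significant)))
})

setMethod("show", "MediationResult", function(object) {
  e <- object@estimates
  ci <- object@ci
  p <- object@pvalues
  cat("MediationResult:", object@spec$exposure, "->", object@spec$mediator,
      "->", object@spec$outcome, " (n =", object@nobs, ")\n")
  for (k in c("acme", "ade", "total", "propMediated")) {
    cat(sprintf("  %-13s % .4f  [% .4f, % .4f]  p = %.4f\n",
                k, e[[k]], ci[k, 1], ci[k, 2], p[[k]]))
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle:", nrow(object@demographics), "participants\n")
  cat("  sleep:", nrow(object@sleep), "records | meals:",
      nrow(object@meals), "events | ffq:", nrow(object@ffq), "rows\n")
  cat("  cgm:", nrow(object@cgm), "readings | postprandial:",
      nrow(object@postprandial), "points\n")
  cat("  abundance:", nrow(object@abundance), "species;",
      length(object@groundTruth$direct_species), "direct +",
      length(object@groundTruth$mediated_species), "mediated planted\n")
})
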