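#' Published summary counts from the PREDICT 1 sleep cohort
#'
#' The printed cohort-characteristic numerators and denominators of the
#' PREDICT 1 social-jetlag analysis (n = 934 with usable self-reported
#' sleep): SJL group size, male counts per group, sleeper-category counts
#' and the printed mean week/weekend sleep durations. Used for
#' worked-example arithmetic (prevalences, fractions, habitual duration)
#' without access to the restricted participant-level data.
#'
#' @return data.frame with columns `quantity`, `numerator`, `denominator`,
#'   `value`.
#' @examples
#' pc <- predict1Counts()
#' with(pc[pc$quantity == "sjl_n", ], 100 * numerator / denominator)
#' @export
predict1Counts <- function() {
  f <- system.file("extdata", "predict1_summary.csv", package = "chronogut",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
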