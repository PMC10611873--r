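#' Write a cohort bundle as a directory of CSV files
#'
#' One CSV per table, the species-by-sample abundance matrix as TSV, the
#' ground truth as JSON and the generating configuration as YAML.
#'
#' @param bundle a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortBundle <- function(bundle, dir) {
  stopifnot(methods::is(bundle, "CohortBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(bundle@demographics, "demographics.csv")
  w(bundle@sleep, "sleep.csv")
  w(bundle@meals, "meals.csv")
  w(bundle@ffq, "ffq.csv")
  w(bundle@cgm, "cgm.csv")
  w(bundle@postprandial, "postprandial.csv")
  ab <- relAbundance(bundle@abundance)
  utils::write.table(data.frame(species = rownames(ab), ab,
                                check.names = FALSE),
                     file.path(dir, "abundance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gt <- bundle@groundTruth
  gt$sjl_assigned <- as.list(gt$sjl_assigned)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- bundle@config
  cfg$male_frac_by_group <- as.list(cfg$male_frac_by_group)
  cfg$diet_effects <- as.list(cfg$diet_effects)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort bundle back from a directory
#'
#' @param dir directory written by [writeCohortBundle()].
#' @return a [CohortBundle-class].
#' @export
readCohortBundle <- function(dir) {
  r <- function(f) utils::read.csv(file.path(dir, f),
                                   stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  gt$sjl_assigned <- unlist(gt$sjl_assigned)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$male_frac_by_group <- unlist(cfg$male_frac_by_group)
  cfg$diet_effects <- unlist(cfg$diet_effects)
  ab <- readAbundance(file.path(dir, "abundance.tsv"),
                      dialect = "species_by_sample_tsv")
  se <- sjlAbundance(ab, sjl = unname(gt$sjl_assigned[colnames(ab)]))
  methods::new("CohortBundle",
               demographics = r("demographics.csv"), sleep = r("sleep.csv"),
               meals = r("meals.csv"), ffq = r("ffq.csv"),
               cgm = r("cgm.csv"), postprandial = r("postprandial.csv"),
               abundance = se, groundTruth = gt, config = cfg)
}

#' Read a relative-abundance table
#'
#' Two dialects: `species_by_sample_tsv` (first column `species`, one column
#' per sample, MetaPhlAn-style relative abundances) and `tidy_csv` (long
#' format with columns `sample`, `species`, `abundance`). Per-sample sums
#' within 1 percent of 1 are renormalised to exactly 1 (with a message);
#' sums further from 1, or negative abundances, are errors.
#'
#' @param path file path.
#' @param dialect `"species_by_sample_tsv"` or `"tidy_csv"`.
#' @return numeric matrix, species in rows, samples in columns.
#' @export
readAbundance <- function(path,
                          dialect = c("species_by_sample_tsv", "tidy_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "species_by_sample_tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample", "species", "abundance")
    if (!all(need %in% names(df)))
      stop("tidy abundance CSV needs columns: ",
           paste(need, collapse = ", "))
    m <- stats::xtabs(abundance ~ species + sample, data = df)
    m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  }
  if (any(m < 0)) stop("negative abundances in ", path)
  cs <- colSums(m)
  off <- abs(cs - 1) > 0.01
  if (any(off))
    stop(sum(off), " sample(s) with abundances summing outside 1 +/- 1%")
  if (any(abs(cs - 1) > 1e-12)) {
    message("renormalising ", sum(abs(cs - 1) > 1e-12),
            " sample(s) to sum exactly 1")
    m <- sweep(m, 2L, cs, "/")
  }
  m
}

#' CONSORT-style exclusion-flow table
#'
#' Combines per-stage exclusion logs into ordered counts removed per rule
#' and n remaining after each rule.
#'
#' @param logs a single exclusion data.frame (columns `rule`, `n_removed`)
#'   or a named list of them, applied in order.
#' @param nStart starting cohort size; defaults to the first log's implied
#'   total.
#' @return data.frame: `stage`, `rule`, `n_removed`, `n_remaining`.
#' @export
exclusionFlow <- function(logs, nStart = NULL) {
  if (is.data.frame(logs)) logs <- list(exclusions = logs)
  rows <- do.call(rbind, lapply(names(logs), function(nm) {
    lg <- logs[[nm]]
    data.frame(stage = nm, rule = lg$rule, n_removed = lg$n_removed)
  }))
  if (is.null(nStart)) {
    lg1 <- logs[[1]]
    nStart <- if ("n_remaining" %in% names(lg1))
      lg1$n_remaining[1] + lg1$n_removed[1]
    else sum(rows$n_removed)
  }
  rows$n_remaining <- nStart - cumsum(rows$n_removed)
  rows
}
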