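#' Default food-group classification for the plant-based diet indices
#'
#' Healthy plant, less-healthy plant and animal food groups. Names match the
#' columns the synthetic cohort generator writes; real data can supply its
#' own map (e.g. from YAML via [yaml::read_yaml]).
#'
#' @return named character vector mapping food group ->
#'   `healthy_plant` / `less_healthy_plant` / `animal`.
#' @export
defaultPdiClassification <- function() {
  c(whole_grains = "healthy_plant",
    fruits = "healthy_plant",
    vegetables = "healthy_plant",
    nuts = "healthy_plant",
    legumes = "healthy_plant",
    vegetable_oils = "healthy_plant",
    tea_coffee = "healthy_plant",
    fruit_juices = "less_healthy_plant",
    refined_grains = "less_healthy_plant",
    potatoes = "less_healthy_plant",
    sugar_sweetened_beverages = "less_healthy_plant",
    sweets_desserts = "less_healthy_plant",
    animal_fat = "animal",
    dairy = "animal",
    eggs = "animal",
    fish_seafood = "animal",
    meat = "animal")
}

# Cohort quintile score 1..5 from intakes; ties share the average rank and
# are floored to a quintile, so the scoring is deterministic and
# order-independent.
.quintileScore <- function(x) {
  r <- rank(x, ties.method = "average")
  q <- floor((r - 1) / length(x) * 5) + 1
  pmin(pmax(as.integer(q), 1L), 5L)
}

#' Score the plant-based diet index family (PDI, hPDI, uPDI)
#'
#' Each configured food group's cohort intakes are split into quintiles
#' (score 1-5). PDI scores all plant groups ascending (higher intake ->
#' higher score) and animal groups descending; hPDI scores healthy plant
#' groups ascending and all others descending; uPDI scores less-healthy
#' plant groups ascending and all others descending. Each index is the sum
#' of its per-group scores.
#'
#' @param ffq data.frame of food-group intakes (g/day), one column per
#'   group, one row per participant.
#' @param classification named vector mapping group ->
#'   `healthy_plant` / `less_healthy_plant` / `animal`; defaults to
#'   [defaultPdiClassification()]. Every scored group must be mapped.
#' @return data.frame with `PDI`, `hPDI`, `uPDI` and per-group quintile
#'   columns (`q_<group>`, the ascending score).
#' @examples
#' ffq <- data.frame(fruits = c(10, 50, 100, 200, 400),
#'                   meat = c(300, 200, 100, 50, 10))
#' scorePdiFamily(ffq, c(fruits = "healthy_plant", meat = "animal"))
#' @export
scorePdiFamily <- function(ffq, classification = defaultPdiClassification()) {
  groups <- intersect(names(classification), names(ffq))
  if (length(groups) == 0L) stop("no mapped food-group columns found")
  unmapped <- setdiff(setdiff(names(ffq), c("participant_id", "energy_kcal",
                                            "alcohol_g", "n_unanswered")),
                      names(classification))
  if (length(unmapped))
    stop("food group(s) without classification: ",
         paste(unmapped, collapse = ", "))
  asc <- vapply(ffq[groups], .quintileScore, integer(nrow(ffq)))
  asc <- matrix(asc, nrow = nrow(ffq),
                dimnames = list(NULL, groups))
  desc <- 6L - asc
  cls <- classification[groups]
  pick <- function(ascending) {
    m <- matrix(ifelse(rep(ascending, each = nrow(ffq)), asc, desc),
                nrow = nrow(ffq))
    as.integer(rowSums(m))
  }
  out <- data.frame(PDI = pick(cls != "animal"),
                    hPDI = pick(cls == "healthy_plant"),
                    uPDI = pick(cls == "less_healthy_plant"))
  colnames(asc) <- paste0("q_", groups)
  cbind(out, as.data.frame(asc))
}
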