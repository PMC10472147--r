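#' Slaughter-age and plausibility filters for phenotype records
#'
#' Removes records whose slaughter age falls outside `age_range` (strictly
#' below the lower bound or strictly above the upper bound; the bounds
#' themselves are retained), records with a missing age, and records whose
#' trait values fall outside configured plausibility bounds.
#'
#' @param phenotypes data frame with one row per animal record
#' @param age_range inclusive retention window in months (default `c(26, 36)`)
#' @param trait_bounds optional named list, `trait -> c(lo, hi)` inclusive
#' @param age_col name of the slaughter-age column
#' @return list with `phenotypes` (filtered) and `report` (counts per rule)
#' @export
apply_phenotype_filters <- function(phenotypes, age_range = c(26, 36),
                                    trait_bounds = NULL,
                                    age_col = "slaughter_age_months") {
  if (!age_col %in% names(phenotypes)) {
    stop("phenotype table lacks the slaughter-age column '", age_col, "'")
  }
  age <- phenotypes[[age_col]]
  rm_age <- is.na(age) | age < age_range[1] | age > age_range[2]
  rm_trait <- rep(FALSE, nrow(phenotypes))
  trait_counts <- integer(0)
  for (tr in names(trait_bounds)) {
    if (!tr %in% names(phenotypes)) next
    b <- trait_bounds[[tr]]
    bad <- !is.na(phenotypes[[tr]]) &
      (phenotypes[[tr]] < b[1] | phenotypes[[tr]] > b[2])
    trait_counts[tr] <- sum(bad & !rm_age)
    rm_trait <- rm_trait | bad
  }
  keep <- !(rm_age | rm_trait)
  if (!any(keep)) warning("all phenotype records removed by filters")
  list(
    phenotypes = phenotypes[keep, , drop = FALSE],
    report = list(n_in = nrow(phenotypes), n_removed_age = sum(rm_age),
                  n_removed_trait = trait_counts,
                  n_out = sum(keep), age_range = age_range)
  )
}
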