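#' Classify a pair of animals into relationship strata
#'
#' Strata follow the full-sib / half-sib / low-related partition used when
#' contrasting pedigree and genomic relationship distributions: `RT3` when the
#' two animals share both a recorded sire and a recorded dam, `RT2` when they
#' share exactly one recorded parent, `RT1` otherwise. An unknown parent
#' (`"0"`) never counts as shared, so pairs with partially unknown pedigree
#' default to `RT1` unless a recorded common parent forces `RT2`.
#'
#' @param ped a `pedigree`
#' @param i,j animal labels, `i != j`
#' @return `"RT1"`, `"RT2"` or `"RT3"`
#' @export
classify_pair <- function(ped, i, j) {
  if (identical(i, j)) stop("cannot classify an animal against itself")
  ix <- ped_index(ped, c(i, j))
  shared <- (ped$sire_i[ix[1]] > 0L && ped$sire_i[ix[1]] == ped$sire_i[ix[2]]) +
            (ped$dam_i[ix[1]] > 0L && ped$dam_i[ix[1]] == ped$dam_i[ix[2]])
  c("RT1", "RT2", "RT3")[shared + 1L]
}

# stratum code (1, 2, 3) for every unordered pair of `idx` (pedigree indices),
# returned as an n x n integer matrix (diagonal NA)
strata_matrix <- function(ped, idx) {
  s <- ped$sire_i[idx]
  d <- ped$dam_i[idx]
  shared <- (outer(s, s, "==") & s > 0L) + (outer(d, d, "==") & d > 0L)
  sm <- shared + 1L
  diag(sm) <- NA_integer_
  sm
}

#' Summarize relationship values by stratum
#'
#' Groups the off-diagonal entries of a relationship matrix by the RT1/RT2/RT3
#' classification of each pair and reports count, mean, min, max, SD and a
#' histogram per stratum. Empty strata are reported with count 0 and `NA`
#' statistics.
#'
#' @param M a `rel_matrix` whose ids all appear in `ped`
#' @param ped a `pedigree`
#' @param breaks passed to [graphics::hist()] binning via [base::cut()];
#'   default 20 equal-width bins over the observed range
#' @return a list with `summary` (data frame, one row per stratum) and
#'   `histograms` (named list of bin-count tables)
#' @export
summarize_strata <- function(M, ped, breaks = 20) {
  stopifnot(inherits(M, "rel_matrix"))
  idx <- ped_index(ped, M$ids)
  sm <- strata_matrix(ped, idx)
  v <- as.matrix(M$values)
  lt <- lower.tri(v)
  strat <- sm[lt]
  val <- v[lt]
  out <- lapply(1:3, function(k) {
    x <- val[strat == k]
    if (!length(x)) {
      data.frame(stratum = paste0("RT", k), count = 0L, mean = NA_real_,
                 min = NA_real_, max = NA_real_, sd = NA_real_)
    } else {
      data.frame(stratum = paste0("RT", k), count = length(x), mean = mean(x),
                 min = min(x), max = max(x),
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }
  })
  summary <- do.call(rbind, out)
  hists <- lapply(1:3, function(k) {
    x <- val[strat == k]
    if (!length(x)) return(table(factor(character(0))))
    table(cut(x, breaks = breaks))
  })
  names(hists) <- paste0("RT", 1:3)
  list(summary = summary, histograms = hists)
}
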