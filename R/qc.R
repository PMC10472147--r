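#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: the p-value is the sum of the
#' probabilities of all heterozygote counts (with the observed allele counts
#' fixed) whose conditional probability does not exceed that of the observed
#' count. Probabilities are evaluated in log space via `lgamma`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (second-allele homozygote,
#'   heterozygote, first-allele homozygote)
#' @return p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab            # second-allele count
  n_minor <- min(na, 2 * n - na)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_minor) up to a common constant
  lp <- h_logprob(hets, n, n_minor)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- which(hets == n_ab)
  if (!length(obs)) stop("inconsistent genotype counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# log multinomial-HWE probability of h heterozygotes given n genotypes and
# n_minor copies of the minor allele
h_logprob <- function(h, n, n_minor) {
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1) +
    h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
    lgamma(2 * n + 1)
}

#' Chi-square Hardy-Weinberg test
#'
#' One-degree-of-freedom goodness-of-fit test without continuity correction;
#' provided as an alternative to the exact test.
#'
#' @inheritParams hwe_exact_test
#' @return p-value
#' @export
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Removes SNPs failing any of three marker filters — minor allele frequency
#' below `maf_min`, missing-call fraction at or above `miss_max`, or
#' Hardy-Weinberg test p-value below `hwe_p_min` — then mean-imputes any
#' remaining missing dosages to `2 p_j`. SNPs with no non-missing calls are
#' removed by the missingness rule. The filter is idempotent: a second pass
#' removes nothing.
#'
#' @param g a `genotypes` object
#' @param maf_min exclusive lower MAF bound (default 0.01: "< 1%" removed)
#' @param miss_max inclusive upper missingness bound (default 0.10: ">= 10%"
#'   removed)
#' @param hwe_p_min exclusive lower HWE p bound (default 1e-6)
#' @param hwe_test `"exact"` (default) or `"chisq"`
#' @return list with `genotypes` (filtered, imputed, frequencies recomputed
#'   from the surviving calls before imputation) and `report` (a `qc_report`)
#' @export
qc_filter <- function(g, maf_min = 0.01, miss_max = 0.10, hwe_p_min = 1e-6,
                      hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosages
  n <- nrow(d)
  miss <- colSums(is.na(d)) / n
  p <- allele_freq(d)
  maf <- pmin(p, 1 - p)

  n_aa <- colSums(d == 2, na.rm = TRUE)
  n_ab <- colSums(d == 1, na.rm = TRUE)
  n_bb <- colSums(d == 0, na.rm = TRUE)
  hwe_fun <- if (hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  hwe_p <- vapply(seq_along(g$snp_ids), function(j) {
    if (n_aa[j] + n_ab[j] + n_bb[j] == 0) return(1)
    hwe_fun(n_aa[j], n_ab[j], n_bb[j])
  }, numeric(1))

  rm_maf <- !is.na(maf) & maf < maf_min
  rm_maf[is.nan(p)] <- TRUE          # all-missing: frequency undefined
  rm_miss <- miss >= miss_max
  rm_hwe <- hwe_p < hwe_p_min
  removed <- rm_maf | rm_miss | rm_hwe
  if (all(removed)) {
    stop("no SNPs survive QC; review thresholds (maf_min=", maf_min,
         ", miss_max=", miss_max, ", hwe_p_min=", hwe_p_min, ")")
  }

  keep <- which(!removed)
  dk <- d[, keep, drop = FALSE]
  pk <- allele_freq(dk)
  # mean imputation to 2 p_j
  for (j in which(colSums(is.na(dk)) > 0)) {
    dk[is.na(dk[, j]), j] <- 2 * pk[j]
  }
  out <- genotypes(dk, ids = g$ids, snp_ids = g$snp_ids[keep], freqs = pk,
                   imputed = TRUE)
  report <- structure(list(
    n_snp_in = length(g$snp_ids),
    n_removed_maf = sum(rm_maf),
    n_removed_missing = sum(rm_miss),
    n_removed_hwe = sum(rm_hwe),
    n_snp_out = length(keep),
    removed_maf = g$snp_ids[rm_maf],
    removed_missing = g$snp_ids[rm_miss],
    removed_hwe = g$snp_ids[rm_hwe],
    thresholds = list(maf_min = maf_min, miss_max = miss_max,
                      hwe_p_min = hwe_p_min, hwe_test = hwe_test)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  SNPs in:              ", x$n_snp_in, "\n",
      "  removed MAF < ", x$thresholds$maf_min, ":      ",
      x$n_removed_maf, "\n",
      "  removed missing >= ", x$thresholds$miss_max, ": ",
      x$n_removed_missing, "\n",
      "  removed HWE p < ", format(x$thresholds$hwe_p_min), ": ",
      x$n_removed_hwe, " (", x$thresholds$hwe_test, ")\n",
      "  SNPs out:             ", x$n_snp_out, "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV plus a readable log
#'
#' @param report a `qc_report`
#' @param path TSV path; a `.log` twin is written alongside
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_snp_in", "n_removed_maf", "n_removed_missing",
               "n_removed_hwe", "n_snp_out"),
    value = c(report$n_snp_in, report$n_removed_maf, report$n_removed_missing,
              report$n_removed_hwe, report$n_snp_out)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  log <- sub("\\.tsv$", "", path)
  log <- paste0(log, ".log")
  con <- file(log, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(path)
}
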