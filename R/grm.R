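#' VanRaden genomic relationship matrix
#'
#' Builds `G = Zc Zc' / (2 * sum_j p_j (1 - p_j))` where `Zc = M - P`, `M` is
#' the dosage matrix recoded to -1/0/1 (homozygote, heterozygote, homozygote)
#' and row `j` of `P` is `2 (p_j - 0.5)`; equivalently `Zc = dosage - 2 p_j`.
#' `Zc` is named after the centered marker matrix to avoid a clash with the
#' mixed-model incidence matrix `Z`.
#'
#' @param g a `genotypes` object, QC already applied (no missing calls;
#'   at least one SNP with `0 < p_j < 1`)
#' @param freq_source `"observed"` (default; frequencies carried by `g`,
#'   normally those of the combined genotyped set) or `"supplied"`
#' @param freqs per-SNP frequencies when `freq_source = "supplied"`
#' @return a `rel_matrix` of kind `"G"`, ids in the genotype order
#' @export
build_G <- function(g, freq_source = c("observed", "supplied"), freqs = NULL) {
  freq_source <- match.arg(freq_source)
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosages
  if (anyNA(d)) stop("missing dosages: run qc_filter() first")
  p <- if (freq_source == "observed") g$freqs else freqs
  if (is.null(p) || length(p) != ncol(d)) {
    stop("supplied frequencies must match the number of SNPs")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("all SNPs monomorphic at the chosen frequencies; G undefined")
  }
  Zc <- sweep(d, 2, 2 * p, "-")
  G <- tcrossprod(Zc) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(g$ids, g$ids)
  rel_matrix(G, "G", g$ids,
             meta = list(freq_source = freq_source, denom = denom,
                         n_snp = ncol(d)))
}
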