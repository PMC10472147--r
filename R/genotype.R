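#' Genotype container
#'
#' @param dosages integer/numeric matrix, animals x SNPs, values 0/1/2/NA
#'   (count of the second allele)
#' @param ids animal labels (rownames are set from this)
#' @param snp_ids marker labels
#' @param freqs optional per-SNP second-allele frequencies; computed from the
#'   non-missing calls when omitted
#' @param imputed set by [qc_filter()] after mean imputation: allows
#'   fractional dosages in `[0, 2]` instead of the raw 0/1/2/NA calls
#' @return object of class `genotypes`
#' @export
genotypes <- function(dosages, ids = rownames(dosages),
                      snp_ids = colnames(dosages), freqs = NULL,
                      imputed = FALSE) {
  dosages <- as.matrix(dosages)
  if (is.null(ids) || is.null(snp_ids)) {
    stop("animal ids and snp ids are required")
  }
  ok <- if (imputed) {
    is.na(dosages) | (dosages >= 0 & dosages <= 2)
  } else {
    is.na(dosages) | dosages == 0 | dosages == 1 | dosages == 2
  }
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid dosage at animal '", ids[bad[1]], "', SNP '",
         snp_ids[bad[2]], "': must be 0, 1, 2 or NA")
  }
  dimnames(dosages) <- list(ids, snp_ids)
  if (is.null(freqs)) freqs <- allele_freq(dosages)
  structure(list(dosages = dosages, ids = as.character(ids),
                 snp_ids = as.character(snp_ids), freqs = freqs),
            class = "genotypes")
}

# second-allele frequency per SNP: allele count / (2 x non-missing animals);
# NaN where all calls are missing
allele_freq <- function(dosages) {
  colSums(dosages, na.rm = TRUE) / (2 * colSums(!is.na(dosages)))
}

#' @export
print.genotypes <- function(x, ...) {
  cat("<genotypes> ", length(x$ids), " animals x ", length(x$snp_ids),
      " SNPs, ", sum(is.na(x$dosages)), " missing calls\n", sep = "")
  invisible(x)
}

#' Read an additive-coded genotype table
#'
#' Two dialects are supported and auto-detected from the header:
#' * simple TSV: first column `animal_id`, one column per SNP, cells
#'   0/1/2/NA;
#' * PLINK `.raw` additive export: header
#'   `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`, whitespace-separated; the
#'   `IID` column keys the animals, the six leading columns other than `IID`
#'   are ignored, count columns may be `NA`.
#'
#' @param source file path, or a matrix/data.frame already in animals-x-SNPs
#'   shape (first column `animal_id` for data frames)
#' @return a `genotypes` object with frequencies computed from non-missing
#'   calls
#' @export
read_genotypes <- function(source) {
  if (!is.character(source)) {
    if (is.data.frame(source)) {
      ids <- as.character(source[[1]])
      m <- as.matrix(source[, -1, drop = FALSE])
      storage.mode(m) <- "double"
      return(genotypes(m, ids = ids, snp_ids = colnames(source)[-1]))
    }
    return(genotypes(source))
  }
  header <- strsplit(readLines(source, n = 1), "[ \t,]+")[[1]]
  if (length(header) >= 6 &&
      identical(header[1:6], c("FID", "IID", "PAT", "MAT", "SEX",
                               "PHENOTYPE"))) {
    df <- utils::read.table(source, header = TRUE, check.names = FALSE,
                            na.strings = c("NA", "-9"))
    ids <- as.character(df$IID)
    m <- as.matrix(df[, -(1:6), drop = FALSE])
    storage.mode(m) <- "double"
    genotypes(m, ids = ids, snp_ids = colnames(df)[-(1:6)])
  } else {
    df <- utils::read.delim(source, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    genotypes(m, ids = ids, snp_ids = colnames(df)[-1])
  }
}

#' Write genotypes as simple TSV
#'
#' @param g a `genotypes` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(animal_id = g$ids, g$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset / reorder genotypes by animal
#'
#' @param g a `genotypes` object
#' @param ids animal labels to keep, in the desired order
#' @param recompute_freqs recompute allele frequencies on the subset
#'   (default keeps the frequencies of the full set)
#' @return a `genotypes` object
#' @export
subset_genotypes <- function(g, ids, recompute_freqs = FALSE) {
  i <- match(ids, g$ids)
  if (anyNA(i)) stop("ids not genotyped: ", paste(ids[is.na(i)], collapse = ", "))
  d <- g$dosages[i, , drop = FALSE]
  genotypes(d, ids = ids, snp_ids = g$snp_ids,
            freqs = if (recompute_freqs) NULL else g$freqs)
}
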