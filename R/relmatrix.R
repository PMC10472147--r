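#' Relationship matrix container
#'
#' Tags a symmetric matrix with its kind (`A`, `A_inverse`, `A22`, `G`,
#' `H_inverse`), the animal id ordering its rows/columns follow, and any
#' construction parameters. All relationship-matrix producers in the package
#' return this class so that id-order agreement can be enforced where it
#' matters (the H-inverse genotyped block).
#'
#' @param values symmetric numeric matrix (base or `Matrix`)
#' @param kind one of `"A"`, `"A_inverse"`, `"A22"`, `"G"`, `"H_inverse"`
#' @param ids character vector of animal labels, length `nrow(values)`
#' @param meta named list of construction parameters
#' @return object of class `rel_matrix`
#' @export
rel_matrix <- function(values, kind, ids, meta = list()) {
  kind <- match.arg(kind, c("A", "A_inverse", "A22", "G", "H_inverse"))
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  asym <- max(abs(values - Matrix::t(values))) /
    max(1, max(abs(values)))
  if (asym > 1e-10) stop("relationship matrix is not symmetric (rel err ",
                         format(asym), ")")
  structure(list(values = values, kind = kind, ids = as.character(ids),
                 meta = meta),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat("<rel_matrix kind=", x$kind, "> ", length(x$ids), " x ",
      length(x$ids), "\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.rel_matrix <- function(x, ...) as.matrix(x$values)

#' @export
dim.rel_matrix <- function(x) dim(x$values)

#' Write a relationship matrix as sparse triplet text
#'
#' Lower triangle (including the diagonal) as whitespace-separated
#' `row_id col_id value`, rows ordered by (row index, col index) of the
#' matrix's own id ordering, so output is bit-stable for a given matrix.
#'
#' @param m a `rel_matrix`
#' @param path output path
#' @param zero_tol entries with absolute value at or below this are omitted
#' @return `path`, invisibly
#' @export
write_rel_matrix <- function(m, path, zero_tol = 0) {
  v <- as.matrix(m$values)
  n <- nrow(v)
  lt <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  val <- v[lt]
  keep <- abs(val) > zero_tol | lt[, 1] == lt[, 2]
  out <- data.frame(row_id = m$ids[lt[keep, 1]], col_id = m$ids[lt[keep, 2]],
                    value = format(val[keep], digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
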