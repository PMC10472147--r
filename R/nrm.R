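#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A recursively in
#' pedigree order: for animal `i` with parents `s`, `d`,
#' `a_ii = 1 + 0.5 a_sd` and `a_ij = 0.5 (a_js + a_jd)` for `j < i`; unknown
#' parents contribute zero. Diagonals are `1 + F_i` with `F_i >= 0`.
#'
#' @param ped a `pedigree` from [read_pedigree()]
#' @return a `rel_matrix` of kind `"A"` (dense), ids in pedigree order
#' @export
build_A <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_i
  d <- ped$dam_i
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (si > 0L) v <- v + 0.5 * A[j, si]
      if (di > 0L) v <- v + 0.5 * A[j, di]
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  rel_matrix(A, "A", ped$animal, meta = list(method = "tabular"))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: the contribution of animal `i` is
#' `alpha_i = 1 / m_i` where `m_i` is the Mendelian-sampling variance
#' coefficient (`0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, `1` with none), added at the usual
#' animal/sire/dam positions. Inbreeding coefficients come from
#' [inbreeding()] (Meuwissen-Luo); no dense inversion is performed.
#'
#' @param ped a `pedigree`
#' @return a `rel_matrix` of kind `"A_inverse"` holding a sparse symmetric
#'   `Matrix`, ids in pedigree order
#' @export
build_A_inverse <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_i
  d <- ped$dam_i
  F <- inbreeding(ped)
  m <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (F[pmax(s, 1L)] + F[pmax(d, 1L)]),
       ifelse(s > 0L, 0.75 - 0.25 * F[pmax(s, 1L)],
       ifelse(d > 0L, 0.75 - 0.25 * F[pmax(d, 1L)], 1)))
  alpha <- 1 / m

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  # vectorized triplet assembly
  idx <- seq_len(n)
  add(idx, idx, alpha)
  ks <- which(s > 0L)
  add(ks, s[ks], -0.5 * alpha[ks]); add(s[ks], ks, -0.5 * alpha[ks])
  add(s[ks], s[ks], 0.25 * alpha[ks])
  kd <- which(d > 0L)
  add(kd, d[kd], -0.5 * alpha[kd]); add(d[kd], kd, -0.5 * alpha[kd])
  add(d[kd], d[kd], 0.25 * alpha[kd])
  kb <- which(s > 0L & d > 0L)
  add(s[kb], d[kb], 0.25 * alpha[kb]); add(d[kb], s[kb], 0.25 * alpha[kb])

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  rel_matrix(Ainv, "A_inverse", ped$animal,
             meta = list(method = "henderson_meuwissen_luo"))
}

#' Extract the genotyped block A22
#'
#' Principal submatrix of A over the genotyped animals, in exactly the order
#' given (which must match the G ordering for single-step assembly).
#'
#' @param A a `rel_matrix` of kind `"A"`
#' @param genotyped_ids ordered character vector, subset of `A$ids`
#' @return a `rel_matrix` of kind `"A22"`
#' @export
extract_A22 <- function(A, genotyped_ids) {
  stopifnot(inherits(A, "rel_matrix"), A$kind == "A")
  i <- match(genotyped_ids, A$ids)
  if (anyNA(i)) {
    stop("genotyped ids not in A: ",
         paste(genotyped_ids[is.na(i)], collapse = ", "))
  }
  v <- as.matrix(A$values)[i, i, drop = FALSE]
  rel_matrix(v, "A22", genotyped_ids, meta = list(parent_kind = "A"))
}
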