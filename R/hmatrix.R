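#' Assemble the single-step H-inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 (G*)^-1 - A22^-1]`, with the correction block
#' aligned to the genotyped animals. `G* = w G + (1 - w) A22` blends the
#' genomic matrix toward its pedigree expectation to guarantee invertibility
#' (`w = blend_weight`; `w = 1` is allowed). The genotyped-block correction
#' carries a minus on `A22^-1`: with `G = A22` the correction vanishes and
#' `H^-1 = A^-1` exactly.
#'
#' @param Ainv a `rel_matrix` of kind `"A_inverse"` over the full pedigree
#' @param A22 a `rel_matrix` of kind `"A22"`; ids must equal `G$ids` in the
#'   same order
#' @param G a `rel_matrix` of kind `"G"`
#' @param blend_weight weight on G in the blend (default 0.95)
#' @return a `rel_matrix` of kind `"H_inverse"` (dense), ids in the `Ainv`
#'   (pedigree) order
#' @export
build_H_inverse <- function(Ainv, A22, G, blend_weight = 0.95) {
  stopifnot(inherits(Ainv, "rel_matrix"), Ainv$kind == "A_inverse",
            inherits(A22, "rel_matrix"), A22$kind == "A22",
            inherits(G, "rel_matrix"), G$kind == "G")
  if (!identical(A22$ids, G$ids)) {
    stop("id-order mismatch: A22 and G must carry the same animals in the ",
         "same order")
  }
  if (blend_weight <= 0 || blend_weight > 1) {
    stop("blend_weight must be in (0, 1]")
  }
  gi <- match(G$ids, Ainv$ids)
  if (anyNA(gi)) {
    stop("genotyped ids missing from A-inverse: ",
         paste(G$ids[is.na(gi)], collapse = ", "))
  }
  Gs <- blend_weight * as.matrix(G$values) +
    (1 - blend_weight) * as.matrix(A22$values)
  Gs_inv <- tryCatch(solve(Gs), error = function(e) {
    stop("blended G* is singular (", conditionMessage(e),
         "); try a lower blend_weight")
  })
  A22_inv <- solve(as.matrix(A22$values))
  Hinv <- as.matrix(Ainv$values)
  Hinv[gi, gi] <- Hinv[gi, gi] + (Gs_inv - A22_inv)
  Hinv <- (Hinv + t(Hinv)) / 2
  rel_matrix(Hinv, "H_inverse", Ainv$ids,
             meta = list(blend_weight = blend_weight,
                         genotyped_ids = G$ids))
}
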