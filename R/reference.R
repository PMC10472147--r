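#' Published Hanwoo carcass-trait genetic parameters
#'
#' Reference variance components, heritabilities and accuracies reported for
#' a Hanwoo carcass-trait evaluation under pedigree BLUP and single-step
#' GBLUP (traits CWT = carcass weight, EMA = eye muscle area, BFT = back-fat
#' thickness, MS = marbling score). Shipped as plain CSV and used as the
#' input side of arithmetic worked examples: heritability and phenotypic
#' variance are recomputed from the `sigma_a2` / `sigma_e2` columns and
#' checked against the printed `h2` / `sigma_p2`. Note one internal rounding
#' quirk of the source: PBLUP BFT prints `sigma_p2 = 17.82` while its
#' components sum to 17.81.
#'
#' @return data frame with columns `method`, `trait`, `sigma_a2`,
#'   `sigma_e2`, `sigma_p2`, `h2`, `h2_se`, `accuracy`, `accuracy_sd`
#' @export
reference_parameters <- function() {
  utils::read.csv(system.file("extdata", "hanwoo_reference_parameters.csv",
                              package = "ssgblup"),
                  stringsAsFactors = FALSE)
}
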