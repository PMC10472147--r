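Package: ssgblup
Title: Pedigree and Single-Step Genomic BLUP for Full-Sib Family Evaluation
Version: 0.1.0
Authors@R:
    person("GAST", "Breeding Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Animal-model genetic evaluation at desk scale: numerator
    relationship matrices (tabular method with inbreeding, Henderson's sparse
    inverse with Meuwissen-Luo coefficients), VanRaden genomic relationship
    matrices with marker quality control, single-step H-inverse assembly,
    mixed-model equations solved under pedigree BLUP (PBLUP) or single-step
    genomic BLUP (ssGBLUP), EM-REML variance components, prediction error
    variance and accuracy, plus a reproducible simulator of embryo-transfer
    full-sib family populations with a half-sib reference tier. Includes a
    one-command comparison pipeline contrasting EBV and GEBV within
    phenotype-less full-sib families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
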