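#' Simulation configuration
#'
#' Describes the synthetic population the package generates to stand in for
#' an undeposited embryo-transfer study population: a set of full-sib test
#' families (same sire and same dam throughout a family, with sires and donor
#' dams re-used across families so half-sib ties exist), on top of a larger
#' half-sib reference tier that carries the phenotypes, with biallelic SNPs
#' segregating by Mendelian gene dropping and a single additive trait.
#'
#' Defaults are the desk-scale stated world: 16 families of 10 genotyped,
#' phenotype-less full sibs; 2,000 genotyped and phenotyped reference
#' animals; 2,000 SNPs; heritability 0.4 on a carcass-weight-like scale
#' (`sigma_p2 = 2000`, mean 440).
#'
#' @param n_families number of full-sib test families
#' @param family_size full sibs per family; scalar or `c(lo, hi)` sampled
#'   uniformly per family
#' @param n_reference reference-tier animals (phenotyped, genotyped)
#' @param n_ref_sires founder sires of the reference tier (half-sib groups)
#' @param offspring_per_ref_dam reference littermates per dam (dams are
#'   re-used this many times, adding maternal half-sib ties)
#' @param n_generations reference-tier depth: 1 = founders x founders only,
#'   2 = a second generation bred from the first
#' @param n_snp number of biallelic SNPs
#' @param maf_range founder second-allele frequency range, uniform draw
#' @param n_qtl number of causal SNPs in genic mode (`NULL` = all)
#' @param target_h2 narrow-sense heritability of the trait
#' @param sigma_p2 phenotypic variance (trait units squared)
#' @param mean trait mean
#' @param trait trait column name
#' @param tbv_mode `"genic"` (TBV from SNP effects; default) or `"pedigree"`
#'   (parent-average recursion with explicit Mendelian-sampling draws)
#' @param zero_mendelian pedigree mode only: suppress the Mendelian term
#'   (degenerate control; full sibs get identical TBV)
#' @param test_phenotyped give test-family animals phenotypes (default
#'   `FALSE`, mimicking pre-slaughter evaluation)
#' @param shared_sire,shared_dam allow sires / donor dams to be re-used
#'   across families (default `TRUE`; gives cross-family half-sib pairs)
#' @param geno_missing_rate fraction of genotype calls masked to missing
#' @param fixed_effects list of class-effect settings: for each of
#'   `birth_year`, `birth_month`, `slaughter_place` a `list(levels=, sd=)`,
#'   plus `age_slope` (trait units per month of slaughter age)
#' @param seed integer seed; all randomness flows from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_families = 16, family_size = 10,
                       n_reference = 2000, n_ref_sires = 100,
                       offspring_per_ref_dam = 2, n_generations = 1,
                       n_snp = 2000, maf_range = c(0.05, 0.5), n_qtl = NULL,
                       target_h2 = 0.4, sigma_p2 = 2000, mean = 440,
                       trait = "cwt",
                       tbv_mode = c("genic", "pedigree"),
                       zero_mendelian = FALSE,
                       test_phenotyped = FALSE,
                       shared_sire = TRUE, shared_dam = TRUE,
                       geno_missing_rate = 0,
                       fixed_effects = NULL, seed = 1) {
  tbv_mode <- match.arg(tbv_mode)
  stopifnot(n_families >= 0, n_reference >= 0, n_snp >= 1,
            target_h2 > 0, target_h2 < 1, sigma_p2 > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5, !is.null(seed))
  sdp <- sqrt(sigma_p2)
  if (is.null(fixed_effects)) {
    fixed_effects <- list(
      birth_year = list(levels = 2016:2020, sd = 0.15 * sdp),
      birth_month = list(levels = 1:12, sd = 0.10 * sdp),
      slaughter_place = list(levels = paste0("P", 1:3), sd = 0.10 * sdp),
      age_slope = 0.10 * sdp
    )
  }
  structure(list(n_families = n_families, family_size = family_size,
                 n_reference = n_reference, n_ref_sires = n_ref_sires,
                 offspring_per_ref_dam = offspring_per_ref_dam,
                 n_generations = n_generations, n_snp = n_snp,
                 maf_range = maf_range, n_qtl = n_qtl,
                 target_h2 = target_h2, sigma_p2 = sigma_p2, mean = mean,
                 trait = trait, tbv_mode = tbv_mode,
                 zero_mendelian = zero_mendelian,
                 test_phenotyped = test_phenotyped,
                 shared_sire = shared_sire, shared_dam = shared_dam,
                 geno_missing_rate = geno_missing_rate,
                 fixed_effects = fixed_effects, seed = as.integer(seed)),
            class = "sim_config")
}

set_sim_seed <- function(seed, offset = 0L) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

# default embryo-transfer mating design: 16 sire x donor-dam combinations
# re-using 5 sires and 14 dams, so several families are paternal or maternal
# half sibs of each other
et_mating_design <- function(n_families, shared_sire, shared_dam) {
  sire <- c(1, 2, 1, 3, 3, 4, 2, 4, 3, 5, 3, 3, 5, 3, 3, 4)
  dam <- c(1, 2, 3, 4, 5, 6, 7, 1, 8, 9, 10, 11, 12, 9, 13, 14)
  if (!shared_sire) sire <- seq_len(16)
  if (!shared_dam) dam <- seq_len(16)
  if (n_families <= 16) {
    data.frame(sire = sire[seq_len(n_families)],
               dam = dam[seq_len(n_families)])
  } else {
    extra <- seq_len(n_families - 16)
    data.frame(sire = c(sire, max(sire) + extra),
               dam = c(dam, max(dam) + extra))
  }
}

#' Generate an embryo-transfer style pedigree
#'
#' Builds the reference tier (each reference animal out of one of
#' `n_ref_sires` founder sires and a dam re-used `offspring_per_ref_dam`
#' times; optionally a second generation bred from the first) and the
#' full-sib test families. Test-family sires are drawn from the first
#' reference sires, so test animals are paternal half sibs of part of the
#' reference tier; donor dams are dedicated founders re-used across families
#' per the mating design.
#'
#' @param cfg a `sim_config`
#' @return list with `ped` (a `pedigree`) and `families` (data frame:
#'   `animal`, `tier` in reference/test, `family` id or `NA`, `sire`, `dam`)
#' @export
generate_pedigree <- function(cfg) {
  set_sim_seed(cfg$seed, 0L)
  an <- si <- da <- tier <- character(0)
  fam <- integer(0)

  n_sires <- max(cfg$n_ref_sires, if (cfg$n_families > 0) 5L else 0L)
  ref_sires <- if (n_sires > 0) paste0("RS", seq_len(n_sires)) else character(0)

  if (cfg$n_reference > 0) {
    n_gen <- max(1L, cfg$n_generations)
    per_gen <- diff(round(seq(0, cfg$n_reference, length.out = n_gen + 1)))
    prev_ids <- character(0)
    counter <- 0L
    for (g in seq_len(n_gen)) {
      ng <- per_gen[g]
      if (ng == 0) next
      ids <- paste0("R", counter + seq_len(ng))
      counter <- counter + ng
      if (g == 1) {
        sires <- ref_sires[1 + (seq_len(ng) - 1) %% cfg$n_ref_sires]
        n_dams <- ceiling(ng / cfg$offspring_per_ref_dam)
        dams <- paste0("RD", g, "_",
                       1 + (seq_len(ng) - 1) %/% cfg$offspring_per_ref_dam)
      } else {
        # second+ generation: parents from the previous one (odd ranks act
        # as sires, even ranks as dams)
        males <- prev_ids[seq(1, length(prev_ids), by = 2)]
        females <- prev_ids[seq(2, length(prev_ids), by = 2)]
        sires <- sample(males, ng, replace = TRUE)
        dams <- sample(females, ng, replace = TRUE)
      }
      an <- c(an, ids); si <- c(si, sires); da <- c(da, dams)
      tier <- c(tier, rep("reference", ng)); fam <- c(fam, rep(NA_integer_, ng))
      prev_ids <- ids
    }
  }

  if (cfg$n_families > 0) {
    design <- et_mating_design(cfg$n_families, cfg$shared_sire,
                               cfg$shared_dam)
    fam_sire <- if (length(ref_sires) >= max(design$sire)) {
      ref_sires[design$sire]
    } else {
      paste0("TS", design$sire)
    }
    fam_dam <- paste0("ED", design$dam)
    sizes <- if (length(cfg$family_size) == 2) {
      sample(cfg$family_size[1]:cfg$family_size[2], cfg$n_families,
             replace = TRUE)
    } else {
      rep(cfg$family_size, cfg$n_families)
    }
    for (f in seq_len(cfg$n_families)) {
      ids <- paste0("F", f, "_", seq_len(sizes[f]))
      an <- c(an, ids)
      si <- c(si, rep(fam_sire[f], sizes[f]))
      da <- c(da, rep(fam_dam[f], sizes[f]))
      tier <- c(tier, rep("test", sizes[f]))
      fam <- c(fam, rep(f, sizes[f]))
    }
  }

  ped <- read_pedigree(data.frame(animal = an, sire = si, dam = da))
  info <- data.frame(animal = an, tier = tier, family = fam, sire = si,
                     dam = da, stringsAsFactors = FALSE)
  founders <- setdiff(ped$animal, an)
  if (length(founders)) {
    info <- rbind(info, data.frame(animal = founders, tier = "founder",
                                   family = NA_integer_, sire = "0",
                                   dam = "0"))
  }
  info <- info[match(ped$animal, info$animal), ]
  rownames(info) <- NULL
  list(ped = ped, families = info)
}

#' Drop genes through a pedigree
#'
#' Founder haplotypes are sampled in Hardy-Weinberg proportions at
#' per-SNP founder frequencies drawn uniformly from `cfg$maf_range`; each
#' offspring allele is drawn uniformly from the parent's two alleles,
#' independently per locus (no linkage). An unknown parent side contributes a
#' base-population gamete at the founder frequencies. Dosage = allele sum.
#'
#' @param ped a `pedigree`
#' @param cfg a `sim_config`
#' @param genotyped_tiers tiers of animals exposed in the returned genotype
#'   matrix (needs `families` info); default reference + test
#' @param families the `families` table from [generate_pedigree()] (or `NULL`
#'   to genotype every animal)
#' @return list with `genotypes` (a `genotypes` object over the genotyped
#'   animals, frequencies computed from them), `all_dosages` (full n x m
#'   integer matrix over the pedigree, no missingness — the simulation
#'   truth), and `founder_freqs`
#' @export
drop_genes <- function(ped, cfg, families = NULL,
                       genotyped_tiers = c("reference", "test")) {
  set_sim_seed(cfg$seed, 1L)
  n <- nrow(ped)
  m <- cfg$n_snp
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  gamete <- function(parent_i) {
    if (parent_i == 0L) {
      as.integer(stats::rbinom(m, 1L, p))
    } else {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, H1[parent_i, ], H2[parent_i, ])
    }
  }
  for (i in seq_len(n)) {
    H1[i, ] <- gamete(ped$sire_i[i])
    H2[i, ] <- gamete(ped$dam_i[i])
  }
  D <- H1 + H2
  rownames(D) <- ped$animal

  gids <- if (is.null(families)) ped$animal else {
    families$animal[families$tier %in% genotyped_tiers]
  }
  gids <- ped$animal[ped$animal %in% gids] # pedigree (topological) order
  Dg <- D[gids, , drop = FALSE]
  storage.mode(Dg) <- "double"
  if (cfg$geno_missing_rate > 0) {
    mask <- stats::runif(length(Dg)) < cfg$geno_missing_rate
    Dg[mask] <- NA_real_
  }
  g <- genotypes(Dg, ids = gids, snp_ids = paste0("SNP", seq_len(m)))
  list(genotypes = g, all_dosages = D, founder_freqs = p)
}

#' Simulate phenotypes and retain the truth
#'
#' True breeding values come either from SNP effects (`genic` mode:
#' `TBV_i = sum_j b_j (dosage_ij - 2 p_j)`, effects drawn normal and scaled
#' so the realized TBV variance equals `sigma_a2 = h2 sigma_p2`) or from the
#' parent-average recursion (`pedigree` mode:
#' `TBV = 1/2 TBV_sire + 1/2 TBV_dam + m`, with the Mendelian-sampling draw
#' `m ~ N(0, sigma_a2 (0.5 - 0.25 (F_s + F_d)))` for known parents and the
#' missing-parent share added for unknown ones). Phenotype = mean + class
#' effects + age slope + TBV + residual; residual variance is set from
#' `target_h2`. Test-tier animals get `NA` phenotypes unless
#' `cfg$test_phenotyped`.
#'
#' @param ped a `pedigree`
#' @param cfg a `sim_config`
#' @param families the `families` table from [generate_pedigree()]
#' @param dropped result of [drop_genes()] (required in genic mode)
#' @return list with `phenotypes` (one row per reference/test animal;
#'   trait value `NA` where unobserved) and `truth` (class `sim_truth`:
#'   `tbv`, `snp_effects`, `mendelian`, `sigma_a2`, `sigma_e2`,
#'   `realized_h2`, `founder_freqs`, `seed`)
#' @export
simulate_phenotypes <- function(ped, cfg, families, dropped = NULL) {
  set_sim_seed(cfg$seed, 2L)
  n <- nrow(ped)
  sa2 <- cfg$target_h2 * cfg$sigma_p2
  se2 <- (1 - cfg$target_h2) * cfg$sigma_p2

  snp_effects <- NULL
  mendelian <- NULL
  if (cfg$tbv_mode == "genic") {
    if (is.null(dropped)) stop("genic TBV mode needs the drop_genes() result")
    m <- cfg$n_snp
    b <- stats::rnorm(m)
    if (!is.null(cfg$n_qtl) && cfg$n_qtl < m) {
      off <- sample(m, m - cfg$n_qtl)
      b[off] <- 0
    }
    p <- dropped$founder_freqs
    raw <- as.numeric(dropped$all_dosages %*% b) - 2 * sum(p * b)
    s <- sqrt(sa2) / stats::sd(raw)
    tbv <- raw * s
    snp_effects <- b * s
  } else {
    F <- inbreeding(ped)
    tbv <- numeric(n)
    mendelian <- numeric(n)
    for (i in seq_len(n)) {
      s_i <- ped$sire_i[i]; d_i <- ped$dam_i[i]
      pa <- 0
      msvar <- 1
      if (s_i > 0L && d_i > 0L) {
        pa <- 0.5 * (tbv[s_i] + tbv[d_i])
        msvar <- 0.5 - 0.25 * (F[s_i] + F[d_i])
      } else if (s_i > 0L) {
        pa <- 0.5 * tbv[s_i]
        msvar <- 0.75 - 0.25 * F[s_i]
      } else if (d_i > 0L) {
        pa <- 0.5 * tbv[d_i]
        msvar <- 0.75 - 0.25 * F[d_i]
      }
      known_both <- s_i > 0L && d_i > 0L
      ms <- if (cfg$zero_mendelian && known_both) 0 else {
        stats::rnorm(1, 0, sqrt(sa2 * msvar))
      }
      mendelian[i] <- ms
      tbv[i] <- pa + ms
    }
    names(mendelian) <- ped$animal
  }
  names(tbv) <- ped$animal

  # fixed-effect structure
  fe <- cfg$fixed_effects
  lv_year <- fe$birth_year$levels
  lv_month <- fe$birth_month$levels
  lv_place <- fe$slaughter_place$levels
  eff_year <- stats::setNames(stats::rnorm(length(lv_year), 0,
                                           fe$birth_year$sd), lv_year)
  eff_month <- stats::setNames(stats::rnorm(length(lv_month), 0,
                                            fe$birth_month$sd), lv_month)
  eff_place <- stats::setNames(stats::rnorm(length(lv_place), 0,
                                            fe$slaughter_place$sd), lv_place)

  obs <- families$animal[families$tier %in% c("reference", "test")]
  k <- length(obs)
  yr <- sample(as.character(lv_year), k, replace = TRUE)
  mo <- sample(as.character(lv_month), k, replace = TRUE)
  pl <- sample(as.character(lv_place), k, replace = TRUE)
  age <- sample(26:36, k, replace = TRUE)
  e <- stats::rnorm(k, 0, sqrt(se2))
  yv <- cfg$mean + eff_year[yr] + eff_month[mo] + eff_place[pl] +
    fe$age_slope * (age - 31) + tbv[obs] + e

  tierk <- families$tier[match(obs, families$animal)]
  observed <- tierk == "reference" | cfg$test_phenotyped
  yv[!observed] <- NA_real_

  phen <- data.frame(animal = obs, trait = unname(yv),
                     birth_year = yr, birth_month = mo,
                     slaughter_age_months = age, slaughter_place = pl,
                     family = families$family[match(obs, families$animal)],
                     tier = tierk, stringsAsFactors = FALSE)
  names(phen)[2] <- cfg$trait

  truth <- structure(list(
    tbv = tbv, snp_effects = snp_effects, mendelian = mendelian,
    sigma_a2 = sa2, sigma_e2 = se2, target_h2 = cfg$target_h2,
    realized_h2 = stats::var(tbv) / (stats::var(tbv) + se2),
    founder_freqs = if (is.null(dropped)) NULL else dropped$founder_freqs,
    fixed_effects = list(birth_year = eff_year, birth_month = eff_month,
                         slaughter_place = eff_place,
                         age_slope = fe$age_slope),
    seed = cfg$seed
  ), class = "sim_truth")
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete dataset
#'
#' Pedigree, gene-dropped genotypes and phenotypes in one call; everything is
#' reproducible from `cfg$seed`.
#'
#' @param cfg a `sim_config`
#' @return list of class `sim_data`: `cfg`, `ped`, `families`, `genotypes`,
#'   `phenotypes`, `truth`
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  gp <- generate_pedigree(cfg)
  dropped <- if (cfg$tbv_mode == "genic" || cfg$n_snp > 0) {
    drop_genes(gp$ped, cfg, families = gp$families)
  } else NULL
  sp <- simulate_phenotypes(gp$ped, cfg, gp$families, dropped)
  structure(list(cfg = cfg, ped = gp$ped, families = gp$families,
                 genotypes = if (is.null(dropped)) NULL else dropped$genotypes,
                 phenotypes = sp$phenotypes, truth = sp$truth),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("<sim_data> ", nrow(x$ped), " animals (",
      sum(x$families$tier == "test"), " test in ",
      x$cfg$n_families, " families, ",
      sum(x$families$tier == "reference"), " reference); ",
      if (is.null(x$genotypes)) 0 else length(x$genotypes$snp_ids),
      " SNPs; trait '", x$cfg$trait, "' h2=", x$cfg$target_h2,
      ", seed=", x$cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the analysis side reads: `pedigree.csv`,
#' `phenotypes.csv`, `genotypes.tsv`, `families.csv` and `truth.json`
#' (true breeding values, variance components, seed).
#'
#' @param sim a `sim_data`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(animal = sim$ped$animal, sire = sim$ped$sire,
                              dam = sim$ped$dam),
                   file.path(dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(sim$genotypes)) {
    write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  }
  utils::write.csv(sim$families, file.path(dir, "families.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(tbv = as.list(sim$truth$tbv),
         sigma_a2 = sim$truth$sigma_a2, sigma_e2 = sim$truth$sigma_e2,
         target_h2 = sim$truth$target_h2,
         realized_h2 = sim$truth$realized_h2, seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
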