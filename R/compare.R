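#' Default comparison configuration
#'
#' @param ... overrides of the default fields (see Details)
#' @details Fields: `simulate` (logical), `sim` (list of [sim_config()]
#'   overrides), `inputs` (paths `pedigree`, `phenotypes`, `genotypes`,
#'   optionally `families` when `simulate = FALSE`), `trait`, `fixed_class`,
#'   `fixed_covariate`, `age_filter`, `age_range`, `trait_bounds`, `qc`
#'   (list `maf_min`, `miss_max`, `hwe_p_min`), `blend_weight`,
#'   `accuracy_mode`, `alpha_from` (`"fixed"` uses `components` — or the
#'   simulation truth — `"reml"` estimates per method), `components`,
#'   `seed`, `outdir`.
#' @return named list
#' @export
compare_config <- function(...) {
  cfg <- list(
    simulate = TRUE, sim = list(), inputs = list(),
    trait = NULL,
    fixed_class = c("birth_year", "birth_month", "slaughter_place"),
    fixed_covariate = "slaughter_age_months",
    age_filter = TRUE, age_range = c(26, 36), trait_bounds = NULL,
    qc = list(maf_min = 0.01, miss_max = 0.10, hwe_p_min = 1e-6),
    blend_weight = 0.95, accuracy_mode = "reliability",
    alpha_from = "fixed", components = NULL,
    seed = 1, outdir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_compare_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(compare_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# derive full-sib family ids (shared sire and dam) for phenotype-less
# genotyped animals when no families table is supplied
derive_families <- function(ped, phenotypes, genotyped_ids, trait) {
  obs <- phenotypes$animal[!is.na(phenotypes[[trait]])]
  tier <- ifelse(ped$animal %in% obs, "reference",
                 ifelse(ped$animal %in% genotyped_ids, "test", "founder"))
  key <- ifelse(tier == "test" & ped$sire != "0" & ped$dam != "0",
                paste(ped$sire, ped$dam, sep = "x"), NA_character_)
  fam <- as.integer(factor(key, levels = unique(stats::na.omit(key))))
  data.frame(animal = ped$animal, tier = tier, family = fam,
             sire = ped$sire, dam = ped$dam, stringsAsFactors = FALSE)
}

#' Run the PBLUP vs ssGBLUP comparison pipeline
#'
#' One command from inputs (or simulation) to the three report surfaces:
#' variance components / heritability / accuracy per method, per-family EBV
#' vs GEBV means and SDs, and RT1/RT2/RT3 relationship-distribution
#' summaries for the pedigree (A22) and genomic (G) matrices over the test
#' animals. Stages: phenotype filters, A and its sparse inverse, genotype
#' QC, G, H-inverse, variance components (REML or fixed), both MME solves,
#' PEV and accuracy. Any stage failure aborts with the stage name.
#'
#' @param config a list from [compare_config()], or a path to a YAML/JSON
#'   file of the same shape
#' @return object of class `comparison_report`
#' @export
run_comparison <- function(config = compare_config()) {
  if (is.character(config)) config <- read_compare_config(config)
  cfg <- do.call(compare_config, config[!vapply(config, is.null, TRUE)])

  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    simcfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    sim <- stage("simulate", simulate_dataset(simcfg))
    ped <- sim$ped
    phen <- sim$phenotypes
    geno <- sim$genotypes
    families <- sim$families
    if (is.null(cfg$trait)) cfg$trait <- simcfg$trait
    if (is.null(cfg$components) && cfg$alpha_from == "fixed") {
      cfg$components <- list(sigma_a2 = sim$truth$sigma_a2,
                             sigma_e2 = sim$truth$sigma_e2)
    }
  } else {
    ped <- stage("read_pedigree", read_pedigree(cfg$inputs$pedigree))
    phen <- stage("read_phenotypes",
                  utils::read.csv(cfg$inputs$phenotypes,
                                  stringsAsFactors = FALSE))
    geno <- stage("read_genotypes", read_genotypes(cfg$inputs$genotypes))
    families <- if (!is.null(cfg$inputs$families)) {
      utils::read.csv(cfg$inputs$families, stringsAsFactors = FALSE)
    } else NULL
    if (is.null(cfg$trait)) stop("config must name the trait")
    if (cfg$alpha_from == "fixed" && is.null(cfg$components)) {
      stop("alpha_from='fixed' needs components (or use alpha_from='reml')")
    }
  }

  filter_report <- NULL
  if (isTRUE(cfg$age_filter) && "slaughter_age_months" %in% names(phen)) {
    # the filter governs which records enter the model; animals keep their
    # equations either way
    fr <- stage("phenotype_filters",
                apply_phenotype_filters(phen, cfg$age_range,
                                        cfg$trait_bounds))
    phen <- fr$phenotypes
    filter_report <- fr$report
  }

  A <- stage("build_A", build_A(ped))
  Ainv <- stage("build_A_inverse", build_A_inverse(ped))

  geno <- stage("align_genotypes",
                subset_genotypes(geno,
                                 ped$animal[ped$animal %in% geno$ids]))
  qc <- stage("qc_filter",
              qc_filter(geno, cfg$qc$maf_min, cfg$qc$miss_max,
                        cfg$qc$hwe_p_min))
  G <- stage("build_G", build_G(qc$genotypes))
  A22 <- stage("extract_A22", extract_A22(A, G$ids))
  Hinv <- stage("build_H_inverse",
                build_H_inverse(Ainv, A22, G, cfg$blend_weight))

  if (is.null(families)) {
    families <- derive_families(ped, phen, G$ids, cfg$trait)
  }

  comp <- cfg$components
  run_arm <- function(K) {
    spec <- model_spec(cfg$trait, cfg$fixed_class, cfg$fixed_covariate,
                       components = if (cfg$alpha_from == "fixed") comp,
                       relationship = K)
    evaluate_blup(spec, phen, accuracy_mode = cfg$accuracy_mode)
  }
  pblup <- stage("pblup_solve", run_arm(Ainv))
  ssgblup <- stage("ssgblup_solve", run_arm(Hinv))

  report <- stage("report",
                  build_comparison_report(pblup, ssgblup, ped, families,
                                          phen, A22, G, cfg, filter_report,
                                          qc$report))
  if (!is.null(cfg$outdir)) {
    stage("write_artifacts",
          write_comparison(report, pblup, ssgblup, qc$report, sim,
                           cfg$outdir))
  }
  report
}

method_summary <- function(ev, test_ids) {
  a <- ev$animals
  at <- a[a$animal %in% test_ids, ]
  list(sigma_a2 = ev$components$sigma_a2, sigma_e2 = ev$components$sigma_e2,
       sigma_p2 = ev$components$sigma_p2, h2 = ev$components$h2,
       accuracy_mean = mean(at$accuracy),
       accuracy_sd = if (nrow(at) > 1) stats::sd(at$accuracy) else NA_real_)
}

family_table <- function(pblup, ssgblup, families, phen, trait) {
  test <- families[families$tier == "test" & !is.na(families$family), ]
  ebv <- stats::setNames(pblup$animals$bv, pblup$animals$animal)
  gebv <- stats::setNames(ssgblup$animals$bv, ssgblup$animals$animal)
  acc_e <- stats::setNames(pblup$animals$accuracy, pblup$animals$animal)
  acc_g <- stats::setNames(ssgblup$animals$accuracy, ssgblup$animals$animal)
  ph <- stats::setNames(phen[[trait]], phen$animal)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  rows <- lapply(split(test$animal, test$family), function(ids) {
    e <- msd(ebv[ids]); g <- msd(gebv[ids]); p <- msd(ph[ids])
    data.frame(n = length(ids),
               ebv_mean = e["mean"], ebv_sd = e["sd"],
               acc_ebv_mean = msd(acc_e[ids])["mean"],
               gebv_mean = g["mean"], gebv_sd = g["sd"],
               acc_gebv_mean = msd(acc_g[ids])["mean"],
               phen_mean = p["mean"], phen_sd = p["sd"])
  })
  out <- do.call(rbind, rows)
  fam_ids <- as.integer(names(rows))
  sire <- test$sire[match(fam_ids, test$family)]
  dam <- test$dam[match(fam_ids, test$family)]
  out <- cbind(data.frame(family = fam_ids, sire = sire, dam = dam), out)
  rownames(out) <- NULL
  out[order(out$family), ]
}

build_comparison_report <- function(pblup, ssgblup, ped, families, phen,
                                    A22, G, cfg, filter_report, qc_report) {
  test_ids <- families$animal[families$tier == "test"]
  if (!length(test_ids)) test_ids <- pblup$animals$animal
  fam <- family_table(pblup, ssgblup, families, phen, cfg$trait)

  strata_ids <- intersect(G$ids, test_ids)
  strata <- if (length(strata_ids) >= 2) {
    subA <- extract_A22(structure(list(values = A22$values, kind = "A",
                                       ids = A22$ids, meta = list()),
                                  class = "rel_matrix"), strata_ids)
    subG_i <- match(strata_ids, G$ids)
    subG <- rel_matrix(as.matrix(G$values)[subG_i, subG_i], "G", strata_ids)
    list(pedigree = summarize_strata(subA, ped)$summary,
         genomic = summarize_strata(subG, ped)$summary)
  } else NULL

  n_tot <- sum(fam$n)
  headline <- list(
    accuracy_gap = mean(ssgblup$animals$accuracy[
      ssgblup$animals$animal %in% test_ids]) -
      mean(pblup$animals$accuracy[pblup$animals$animal %in% test_ids]),
    max_within_family_ebv_sd = suppressWarnings(max(fam$ebv_sd, na.rm = TRUE)),
    min_within_family_gebv_sd = suppressWarnings(min(fam$gebv_sd,
                                                     na.rm = TRUE)),
    ebv_mean_animal_weighted = sum(fam$ebv_mean * fam$n) / n_tot,
    ebv_mean_family_weighted = mean(fam$ebv_mean),
    gebv_mean_animal_weighted = sum(fam$gebv_mean * fam$n) / n_tot,
    gebv_mean_family_weighted = mean(fam$gebv_mean)
  )
  structure(list(
    trait = cfg$trait,
    methods = list(PBLUP = method_summary(pblup, test_ids),
                   ssGBLUP = method_summary(ssgblup, test_ids)),
    families = fam,
    strata = strata,
    headline = headline,
    manifest = list(seed = cfg$seed, qc = cfg$qc,
                    blend_weight = cfg$blend_weight,
                    accuracy_mode = cfg$accuracy_mode,
                    alpha_from = cfg$alpha_from,
                    age_range = if (isTRUE(cfg$age_filter)) cfg$age_range,
                    filter_report = filter_report,
                    n_snp_post_qc = if (!is.null(qc_report))
                      qc_report$n_snp_out,
                    package_version =
                      as.character(utils::packageVersion("ssgblup")))
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== PBLUP vs ssGBLUP comparison: trait '", x$trait, "' ==\n", sep = "")
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    cat(sprintf(
      "%-8s sigma_a2=%.4g sigma_e2=%.4g h2=%.3f accuracy=%.3f+/-%.3f\n",
      m, s$sigma_a2, s$sigma_e2, s$h2, s$accuracy_mean, s$accuracy_sd))
  }
  cat(sprintf("accuracy gap (ssGBLUP - PBLUP, test animals): %.3f\n",
              x$headline$accuracy_gap))
  cat(sprintf("within-family SD: EBV max %.3g, GEBV min %.3g\n",
              x$headline$max_within_family_ebv_sd,
              x$headline$min_within_family_gebv_sd))
  cat("\nPer-family breeding values (mean +/- SD):\n")
  f <- x$families
  for (i in seq_len(nrow(f))) {
    cat(sprintf(
      "  family %2d (%s x %s, n=%d): EBV %7.2f+/-%-6.3g GEBV %7.2f+/-%-6.3g\n",
      f$family[i], f$sire[i], f$dam[i], f$n[i], f$ebv_mean[i],
      ifelse(is.na(f$ebv_sd[i]), 0, f$ebv_sd[i]), f$gebv_mean[i],
      ifelse(is.na(f$gebv_sd[i]), 0, f$gebv_sd[i])))
  }
  if (!is.null(x$strata)) {
    cat("\nRelationship strata over test animals (off-diagonals):\n")
    cat("  pedigree (A22):\n")
    print(x$strata$pedigree, row.names = FALSE)
    cat("  genomic (G):\n")
    print(x$strata$genomic, row.names = FALSE)
  }
  invisible(x)
}

write_comparison <- function(report, pblup, ssgblup, qc_report, sim,
                             outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fam_of <- function(ids, families) {
    families$family[match(ids, families$animal)]
  }
  tier_of <- function(ids, families) {
    families$tier[match(ids, families$animal)]
  }
  families <- if (!is.null(sim)) sim$families else NULL
  for (arm in list(list(ev = pblup, file = "pblup_results.tsv"),
                   list(ev = ssgblup, file = "ssgblup_results.tsv"))) {
    a <- arm$ev$animals
    out <- data.frame(animal = a$animal, ebv_or_gebv = a$bv, pev = a$pev,
                      accuracy = a$accuracy)
    if (!is.null(families)) {
      out$tier <- tier_of(a$animal, families)
      out$family <- fam_of(a$animal, families)
    }
    utils::write.table(out, file.path(outdir, arm$file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$families, file.path(outdir, "family_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(qc_report)) {
    write_qc_report(qc_report, file.path(outdir, "qc_report.tsv"))
  }
  jsonlite::write_json(
    list(trait = report$trait, methods = report$methods,
         headline = report$headline, manifest = report$manifest),
    file.path(outdir, "comparison.json"), auto_unbox = TRUE, digits = 10,
    force = TRUE)
  if (!is.null(sim)) write_dataset(sim, file.path(outdir, "data"))
  invisible(outdir)
}
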