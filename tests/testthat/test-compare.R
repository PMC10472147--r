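small_compare_cfg <- function(seed = 19, ...) {
  compare_config(sim = list(n_families = 4, family_size = 4,
                            n_reference = 100, n_ref_sires = 8,
                            n_snp = 400),
                 seed = seed, ...)
}

test_that("the pipeline reproduces the full-sib EBV/GEBV contrast", {
  rep <- run_comparison(small_compare_cfg())
  f <- rep$families
  expect_true(all(f$ebv_sd < 1e-8))          # PBLUP: one EBV per family
  expect_true(all(f$gebv_sd > 0))            # ssGBLUP: individual GEBVs
  expect_gt(rep$headline$accuracy_gap, 0)
  # report totals are internally consistent
  expect_equal(rep$headline$ebv_mean_animal_weighted,
               sum(f$ebv_mean * f$n) / sum(f$n))
  # equal family sizes: the two weightings coincide
  expect_equal(rep$headline$gebv_mean_animal_weighted,
               rep$headline$gebv_mean_family_weighted)
  # both strata summaries cover the same pairs
  expect_equal(sum(rep$strata$pedigree$count),
               sum(rep$strata$genomic$count))
})

test_that("reruns with the same seed are identical, artifacts included", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  suppressWarnings({
    r1 <- run_comparison(small_compare_cfg(outdir = dir1))
    r2 <- run_comparison(small_compare_cfg(outdir = dir2))
  })
  r1$manifest$package_version <- r2$manifest$package_version <- NULL
  expect_equal(r1, r2)
  for (f in c("pblup_results.tsv", "ssgblup_results.tsv",
              "family_table.tsv", "comparison.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = f)
  }
})

test_that("file-based runs agree with in-memory simulation", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(do.call(sim_config,
                                  c(small_compare_cfg()$sim,
                                    list(seed = 19))))
  write_dataset(sim, dir)
  cfg <- small_compare_cfg()
  file_cfg <- compare_config(
    simulate = FALSE,
    inputs = list(pedigree = file.path(dir, "pedigree.csv"),
                  phenotypes = file.path(dir, "phenotypes.csv"),
                  genotypes = file.path(dir, "genotypes.tsv"),
                  families = file.path(dir, "families.csv")),
    trait = "cwt",
    components = list(sigma_a2 = sim$truth$sigma_a2,
                      sigma_e2 = sim$truth$sigma_e2),
    seed = 19)
  r_file <- run_comparison(file_cfg)
  r_mem <- run_comparison(cfg)
  expect_equal(r_file$families$gebv_mean, r_mem$families$gebv_mean,
               tolerance = 1e-10)
  expect_equal(r_file$methods, r_mem$methods, tolerance = 1e-10)
})

test_that("YAML and JSON configs load and families can be derived", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(do.call(sim_config,
                                  c(small_compare_cfg()$sim,
                                    list(seed = 19))))
  write_dataset(sim, dir)
  cfg <- list(simulate = FALSE,
              inputs = list(pedigree = file.path(dir, "pedigree.csv"),
                            phenotypes = file.path(dir, "phenotypes.csv"),
                            genotypes = file.path(dir, "genotypes.tsv")),
              trait = "cwt",
              components = list(sigma_a2 = sim$truth$sigma_a2,
                                sigma_e2 = sim$truth$sigma_e2))
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, yml)
  r <- run_comparison(yml)
  expect_equal(nrow(r$families), 4) # families recovered from the pedigree
  expect_true(all(r$families$gebv_sd > 0))
  jsn <- file.path(dir, "run.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  r2 <- run_comparison(jsn)
  expect_equal(r2$families$gebv_mean, r$families$gebv_mean)
})

test_that("stage failures name the stage", {
  bad <- compare_config(simulate = FALSE,
                        inputs = list(pedigree = "does_not_exist.csv",
                                      phenotypes = "x", genotypes = "y"),
                        trait = "cwt",
                        components = list(sigma_a2 = 1, sigma_e2 = 1))
  expect_error(run_comparison(bad), "read_pedigree")
})

test_that("REML-driven comparison runs end to end at small scale", {
  rep <- run_comparison(small_compare_cfg(alpha_from = "reml"))
  for (m in rep$methods) {
    expect_gt(m$sigma_a2, 0)
    expect_gt(m$sigma_e2, 0)
  }
  expect_true(all(rep$families$ebv_sd < 1e-8))
})
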