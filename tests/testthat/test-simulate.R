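test_that("generated pedigrees carry the ET family structure", {
  cfg <- small_sim_cfg(seed = 2)
  gp <- generate_pedigree(cfg)
  fam <- gp$families
  test <- fam[fam$tier == "test", ]
  # every within-family pair is RT3
  for (f in unique(test$family)) {
    ids <- test$animal[test$family == f]
    expect_equal(classify_pair(gp$ped, ids[1], ids[2]), "RT3")
  }
  # the default mating design re-uses sires: cross-family RT2 pairs exist
  sire_of <- tapply(test$sire, test$family, unique)
  shared <- which(table(unlist(sire_of)) > 1)
  expect_gt(length(shared), 0)
  fams <- names(sire_of)[sire_of == names(shared)[1]]
  a <- test$animal[test$family == as.integer(fams[1])][1]
  b <- test$animal[test$family == as.integer(fams[2])][1]
  expect_equal(classify_pair(gp$ped, a, b), "RT2")
  # without sharing, families are parentally disjoint
  gp2 <- generate_pedigree(small_sim_cfg(seed = 2, shared_sire = FALSE,
                                         shared_dam = FALSE))
  t2 <- gp2$families[gp2$families$tier == "test", ]
  expect_true(all(table(tapply(t2$sire, t2$family, unique)) == 1))
})

test_that("simulation is reproducible from the seed alone", {
  s1 <- simulate_dataset(small_sim_cfg(seed = 33))
  s2 <- simulate_dataset(small_sim_cfg(seed = 33))
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
  s3 <- simulate_dataset(small_sim_cfg(seed = 34))
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("gene dropping obeys Mendelian transmission", {
  cfg <- small_sim_cfg(seed = 12)
  gp <- generate_pedigree(cfg)
  dr <- drop_genes(gp$ped, cfg, families = NULL)
  D <- dr$all_dosages
  ped <- gp$ped
  # fixed parents transmit with certainty
  both_known <- which(ped$sire_i > 0 & ped$dam_i > 0)
  for (i in both_known[1:5]) {
    s <- D[ped$sire_i[i], ]
    d <- D[ped$dam_i[i], ]
    fixed <- s == 2 & d == 2
    expect_true(all(D[i, fixed] == 2))
    expect_true(all(D[i, s == 0 & d == 0] == 0))
  }
  # founder genotypes are in HWE proportions within binomial error
  founders <- which(ped$sire_i == 0 & ped$dam_i == 0)
  j <- which.min(abs(dr$founder_freqs - 0.5))
  x <- D[founders, j]
  n <- length(founders)
  p_hat <- mean(x) / 2
  ci <- stats::binom.test(sum(x), 2 * n, dr$founder_freqs[j])$conf.int
  expect_true(dr$founder_freqs[j] >= ci[1] & dr$founder_freqs[j] <= ci[2] ||
                abs(p_hat - dr$founder_freqs[j]) < 0.1)
  het <- mean(x == 1)
  expect_lt(abs(het - 2 * p_hat * (1 - p_hat)), 3 * sqrt(0.5 * 0.5 / n) + .05)
})

test_that("full sibs share half their genome on average, with spread", {
  cfg <- sim_config(n_families = 2, family_size = 15, n_reference = 0,
                    n_ref_sires = 0, n_snp = 5000, seed = 13)
  gp <- generate_pedigree(cfg)
  dr <- drop_genes(gp$ped, cfg, families = gp$families)
  G <- build_G(dr$genotypes, freq_source = "supplied",
               freqs = dr$founder_freqs)
  v <- as.matrix(G$values)
  sm <- ssgblup:::strata_matrix(gp$ped,
                                match(G$ids, gp$ped$animal))
  rt3 <- v[lower.tri(v)][sm[lower.tri(sm)] == 3]
  expect_lt(abs(mean(rt3) - 0.5), 0.03)
  expect_gt(sd(rt3), 0)
  # genomic full-sib relationships are strictly wider than pedigree ones
  A22 <- extract_A22(build_A(gp$ped), G$ids)
  a3 <- as.matrix(A22$values)[lower.tri(v)][sm[lower.tri(sm)] == 3]
  expect_gt(sd(rt3), sd(a3) + 0.01)
})

test_that("phenotypes realize the target heritability", {
  cfg <- sim_config(n_families = 0, n_reference = 5000, n_ref_sires = 100,
                    n_snp = 300, target_h2 = 0.4, seed = 14)
  sim <- simulate_dataset(cfg)
  phen <- sim$phenotypes
  tbv <- sim$truth$tbv[phen$animal]
  fe <- sim$truth$fixed_effects
  fixed_part <- cfg$mean + fe$birth_year[phen$birth_year] +
    fe$birth_month[phen$birth_month] +
    fe$slaughter_place[phen$slaughter_place] +
    fe$age_slope * (phen$slaughter_age_months - 31)
  genetic_plus_resid <- phen$cwt - fixed_part # = TBV + e by construction
  h2_real <- var(tbv) / var(genetic_plus_resid)
  expect_lt(abs(h2_real - 0.4), 0.03)
})

test_that("pedigree-mode TBV honors the parent-average recursion", {
  cfg <- small_sim_cfg(seed = 16, tbv_mode = "pedigree")
  sim <- simulate_dataset(cfg)
  ped <- sim$ped
  tbv <- sim$truth$tbv
  ms <- sim$truth$mendelian
  for (i in which(ped$sire_i > 0 & ped$dam_i > 0)) {
    pa <- 0.5 * (tbv[ped$sire_i[i]] + tbv[ped$dam_i[i]])
    expect_equal(unname(tbv[i] - pa), unname(ms[i]), tolerance = 1e-12)
  }
  # degenerate control: no Mendelian sampling means identical full sibs
  cfg0 <- small_sim_cfg(seed = 16, tbv_mode = "pedigree",
                        zero_mendelian = TRUE)
  sim0 <- simulate_dataset(cfg0)
  fam <- sim0$families
  for (f in unique(fam$family[fam$tier == "test"])) {
    ids <- fam$animal[fam$tier == "test" & fam$family %in% f]
    expect_equal(sd(sim0$truth$tbv[ids]), 0)
  }
})

test_that("datasets round-trip through the writers", {
  sim <- simulate_dataset(small_sim_cfg(seed = 17))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_identical(ped2$animal, sim$ped$animal)
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(g2$dosages, sim$genotypes$dosages)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sigma_a2, sim$truth$sigma_a2)
  expect_equal(truth$seed, sim$cfg$seed)
})
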