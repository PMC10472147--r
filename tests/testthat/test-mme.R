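test_that("single-animal mean-only system expands as expected", {
  ped <- read_pedigree(data.frame(animal = "A", sire = "0", dam = "0"))
  Ainv <- build_A_inverse(ped)
  spec <- model_spec("y", fixed_class = character(0),
                     fixed_covariate = character(0),
                     components = list(sigma_a2 = 1, sigma_e2 = 2),
                     relationship = Ainv)
  mme <- build_mme(spec, data.frame(animal = "A", y = 5))
  expect_equal(mme$LHS, matrix(c(1, 1, 1, 1 + 2), 2), ignore_attr = TRUE)
  expect_equal(mme$RHS, c(5, 5))
})

test_that("phenotype-less animals keep equations and zero data rows", {
  herd <- toy_herd(seed = 3)
  Ainv <- build_A_inverse(herd$ped)
  spec <- model_spec("y", fixed_class = "grp", fixed_covariate = "age",
                     components = list(sigma_a2 = 40, sigma_e2 = 60),
                     relationship = Ainv)
  mme <- build_mme(spec, herd$phen)
  q <- nrow(herd$ped)
  expect_equal(nrow(mme$LHS), mme$n_fixed + q)
  unobs <- setdiff(herd$ped$animal, herd$phen$animal)
  sol <- solve_mme(mme)
  expect_true(all(unobs %in% names(sol$u)))
  # y = 0 gives the zero solution
  phen0 <- herd$phen
  phen0$y <- 0
  sol0 <- solve_mme(build_mme(spec, phen0))
  expect_equal(max(abs(c(sol0$beta, sol0$u))), 0)
})

test_that("MME solutions and PEV match the dense GLS/BLUP oracle", {
  for (seed in c(3, 8)) {
    herd <- toy_herd(seed = seed)
    ped <- herd$ped
    expect_lte(nrow(ped), 50)
    Ainv <- build_A_inverse(ped)
    sa2 <- 40; se2 <- 60
    spec <- model_spec("y", fixed_class = "grp", fixed_covariate = "age",
                       components = list(sigma_a2 = sa2, sigma_e2 = se2),
                       relationship = Ainv)
    mme <- build_mme(spec, herd$phen)
    sol <- solve_mme(mme)
    pev <- compute_pev(mme_inverse_animal_diag(mme), se2)

    A <- as.matrix(build_A(ped))
    ai <- match(herd$phen$animal, ped$animal)
    X <- cbind(1, herd$phen$grp == "g2", herd$phen$age)
    orc <- oracle_dense_blup(herd$phen$y, X, ai, A, sa2, se2)
    expect_equal(unname(sol$beta), orc$beta, tolerance = 1e-8)
    expect_equal(unname(sol$u), orc$u, tolerance = 1e-8)
    expect_equal(unname(pev), orc$pev, tolerance = 1e-8)
  }
})

test_that("PEV brackets reflect information content", {
  # founder unconnected to any record: PEV equals the prior variance;
  # two records are needed so the mean does not absorb all information
  ped <- read_pedigree(data.frame(animal = c("A", "B", "C"), sire = "0",
                                  dam = "0"))
  Ainv <- build_A_inverse(ped)
  spec <- model_spec("y", fixed_class = character(0),
                     fixed_covariate = character(0),
                     components = list(sigma_a2 = 4, sigma_e2 = 6),
                     relationship = Ainv)
  mme <- build_mme(spec, data.frame(animal = c("A", "C"), y = c(3, 5)))
  pev <- compute_pev(mme_inverse_animal_diag(mme), 6)
  expect_equal(unname(pev["B"]), 4)      # no information: sigma_a2
  expect_lt(pev[["A"]], 4)               # own record reduces PEV
})

test_that("accuracy follows the printed formula and its square root", {
  expect_equal(compute_accuracy(0, 10), 1)
  expect_equal(compute_accuracy(10, 10), 0)
  expect_equal(compute_accuracy(5, 10, mode = "sqrt"), sqrt(0.5),
               tolerance = 1e-12)
  expect_warning(acc <- compute_accuracy(12, 10), "clamped")
  expect_equal(acc, 0)
})

test_that("heritability arithmetic holds at the edges", {
  expect_equal(compute_heritability(2, 0)$h2, 1)
  expect_equal(compute_heritability(0, 2)$h2, 0)
  h <- compute_heritability(3, 7)
  expect_equal(h$sigma_p2, 10)
  expect_equal(h$h2, 0.3)
  expect_error(compute_heritability(0, 0), "zero")
})

test_that("confounded fixed effects warn and fall back to ginv", {
  herd <- toy_herd(seed = 5)
  phen <- herd$phen
  phen$dup <- phen$age # aliased covariate
  Ainv <- build_A_inverse(herd$ped)
  spec <- model_spec("y", fixed_class = "grp",
                     fixed_covariate = c("age", "dup"),
                     components = list(sigma_a2 = 40, sigma_e2 = 60),
                     relationship = Ainv)
  expect_warning(mme <- build_mme(spec, phen), "confounded")
  sol <- solve_mme(mme)
  expect_true(sol$used_ginv)
  expect_true(all(is.finite(sol$u)))
})
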