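make_reml_data <- function(seed = 11, n_founder = 6, n_off = 34, h2 = 0.4,
                           sigma_p2 = 100) {
  set.seed(seed)
  ped <- ped_random(n_founder, n_off, seed = seed, p_unknown = 0)
  cfg <- sim_config(n_families = 0, n_reference = 0, n_snp = 1,
                    target_h2 = h2, sigma_p2 = sigma_p2, seed = seed,
                    tbv_mode = "pedigree")
  F <- inbreeding(ped)
  sa2 <- h2 * sigma_p2
  tbv <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire_i[i]; d <- ped$dam_i[i]
    pa <- 0; msv <- 1
    if (s > 0 && d > 0) {
      pa <- 0.5 * (tbv[s] + tbv[d]); msv <- 0.5 - 0.25 * (F[s] + F[d])
    }
    tbv[i] <- pa + rnorm(1, 0, sqrt(sa2 * msv))
  }
  y <- 50 + tbv + rnorm(nrow(ped), 0, sqrt(sigma_p2 - sa2))
  data.frame(animal = ped$animal, y = y,
             x = runif(nrow(ped), 0, 1))[sample(nrow(ped)), ] -> phen
  list(ped = ped, phen = phen)
}

test_that("spectral EM-REML reproduces the naive dense-EM trajectory", {
  d <- make_reml_data(seed = 11)
  Ainv <- build_A_inverse(d$ped)
  fit <- em_reml(d$phen, Ainv, "y", fixed_class = character(0),
                 fixed_covariate = "x", tol = 0, max_iter = 25)
  X <- cbind(1, d$phen$x)
  ai <- match(d$phen$animal, d$ped$animal)
  naive <- oracle_naive_em(d$phen$y, X, ai, as.matrix(Ainv$values),
                           n_iter = 25)
  expect_equal(fit$sigma_a2, naive$sigma_a2, tolerance = 1e-8)
  expect_equal(fit$sigma_e2, naive$sigma_e2, tolerance = 1e-8)
})

test_that("restricted log-likelihood is non-decreasing along EM", {
  for (seed in c(11, 23)) {
    d <- make_reml_data(seed = seed)
    Ainv <- build_A_inverse(d$ped)
    fit <- em_reml(d$phen, Ainv, "y", fixed_class = character(0),
                   fixed_covariate = "x", max_iter = 200)
    expect_gte(min(diff(fit$loglik_path)), -1e-8)
  }
})

test_that("EM-REML agrees with a restricted-likelihood grid on a toy herd", {
  # five animals: two founder parents and three full sibs, all phenotyped
  ped <- read_pedigree(data.frame(animal = c("O1", "O2", "O3"),
                                  sire = "S", dam = "D"))
  set.seed(7)
  phen <- data.frame(animal = ped$animal,
                     y = c(11.5, 8.2, 10.9, 12.7, 9.9))
  Ainv <- build_A_inverse(ped)
  fit <- em_reml(phen, Ainv, "y", fixed_class = character(0),
                 fixed_covariate = character(0), tol = 1e-12,
                 max_iter = 5000)
  A <- as.matrix(build_A(ped))
  h2_grid <- oracle_reml_grid(phen$y, matrix(1, 5, 1),
                              match(phen$animal, ped$animal), A)
  expect_false(h2_grid %in% range(seq(0.0001, 0.9999, by = 1e-4)))
  expect_equal(fit$h2, h2_grid, tolerance = 1e-3)
})

test_that("estimates are invariant to animal reordering", {
  d <- make_reml_data(seed = 31)
  Ainv <- build_A_inverse(d$ped)
  fit1 <- em_reml(d$phen, Ainv, "y", fixed_class = character(0),
                  fixed_covariate = "x")
  perm <- d$phen[rev(seq_len(nrow(d$phen))), ]
  fit2 <- em_reml(perm, Ainv, "y", fixed_class = character(0),
                  fixed_covariate = "x")
  expect_equal(fit1$sigma_a2, fit2$sigma_a2, tolerance = 1e-9)
  expect_equal(fit1$sigma_e2, fit2$sigma_e2, tolerance = 1e-9)
})

test_that("degenerate inputs fail loudly", {
  ped <- ped_full_sibs()
  Ainv <- build_A_inverse(ped)
  expect_error(em_reml(data.frame(animal = "O1", y = 1), Ainv, "y",
                       fixed_class = character(0),
                       fixed_covariate = character(0)),
               "at least 2")
})
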