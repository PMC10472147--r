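# Small fixtures built in code.

# sire S, dam D (founders), two joint offspring
ped_full_sibs <- function() {
  read_pedigree(data.frame(animal = c("O1", "O2"), sire = "S", dam = "D"))
}

# three generations ending in an offspring of a full-sib mating (F = 0.25)
ped_inbred <- function() {
  read_pedigree(data.frame(animal = c("O1", "O2", "X"),
                           sire = c("S", "S", "O1"),
                           dam = c("D", "D", "O2")))
}

# random valid pedigree: founders plus `n_off` offspring whose parents are
# drawn from earlier animals (always topologically valid)
ped_random <- function(n_founder = 4, n_off = 8, seed = 1,
                       p_unknown = 0.15) {
  set.seed(seed)
  an <- paste0("A", seq_len(n_founder + n_off))
  si <- da <- rep("0", n_founder + n_off)
  for (i in (n_founder + 1):(n_founder + n_off)) {
    pool <- an[seq_len(i - 1)]
    pair <- sample(pool, 2)
    si[i] <- if (stats::runif(1) < p_unknown) "0" else pair[1]
    da[i] <- if (stats::runif(1) < p_unknown) "0" else pair[2]
  }
  read_pedigree(data.frame(animal = an, sire = si, dam = da))
}

# genotypes drawn in HWE at given frequencies
geno_hwe <- function(n, freqs, seed = 1, prefix = "A") {
  set.seed(seed)
  m <- length(freqs)
  d <- vapply(freqs, function(p) stats::rbinom(n, 2, p), numeric(n))
  genotypes(matrix(d, n, m,
                   dimnames = list(paste0(prefix, seq_len(n)),
                                   paste0("S", seq_len(m)))))
}

# tiny phenotyped herd for MME tests: q animals (some phenotype-less),
# simple mean + covariate model
toy_herd <- function(seed = 3, n_founder = 3, n_off = 7, h2 = 0.4) {
  set.seed(seed)
  ped <- ped_random(n_founder, n_off, seed = seed, p_unknown = 0)
  q <- nrow(ped)
  obs <- ped$animal[seq(2, q, by = 2)] # every other animal phenotyped
  phen <- data.frame(
    animal = obs,
    y = stats::rnorm(length(obs), 100, 10),
    grp = sample(c("g1", "g2"), length(obs), replace = TRUE),
    age = stats::runif(length(obs), 26, 36)
  )
  list(ped = ped, phen = phen)
}

small_sim_cfg <- function(seed = 5, ...) {
  sim_config(n_families = 4, family_size = 4, n_reference = 80,
             n_ref_sires = 8, n_snp = 300, seed = seed, ...)
}
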