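# Independent oracles used to check the analytical code paths. These stay
# deliberately naive: Monte-Carlo gene dropping for A, dense variance-matrix
# algebra for BLUP/PEV, direct enumeration for the HWE exact test, and a
# profiled restricted-likelihood grid for REML.

# Monte-Carlo identity-by-descent estimate of the numerator relationship
# matrix: founders carry unique allele labels, alleles drop independently
# per replicate; a_ij = 2 * kinship(i, j), a_ii = 1 + P(two alleles of i IBD).
oracle_gene_drop_A <- function(ped, n_rep = 1e6, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  M1 <- matrix(0L, n_rep, n)
  M2 <- matrix(0L, n_rep, n)
  for (i in seq_len(n)) {
    s <- ped$sire_i[i]
    d <- ped$dam_i[i]
    M1[, i] <- if (s == 0L) 2L * i - 1L else {
      pick <- stats::runif(n_rep) < 0.5
      ifelse(pick, M1[, s], M2[, s])
    }
    M2[, i] <- if (d == 0L) 2L * i else {
      pick <- stats::runif(n_rep) < 0.5
      ifelse(pick, M1[, d], M2[, d])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(M1[, i] == M2[, i])
    for (j in seq_len(i - 1L)) {
      f <- (mean(M1[, i] == M1[, j]) + mean(M1[, i] == M2[, j]) +
              mean(M2[, i] == M1[, j]) + mean(M2[, i] == M2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  A
}

# Dense GLS/BLUP oracle from V = Z G Z' + R with G = Arel * sigma_a2,
# R = I * sigma_e2. `ai` maps each record to its animal column in Arel.
oracle_dense_blup <- function(y, X, ai, Arel, sigma_a2, sigma_e2) {
  N <- length(y)
  q <- nrow(Arel)
  Z <- matrix(0, N, q)
  Z[cbind(seq_len(N), ai)] <- 1
  Gu <- Arel * sigma_a2
  V <- Z %*% Gu %*% t(Z) + diag(sigma_e2, N)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  B <- solve(XtVi %*% X)
  beta <- B %*% XtVi %*% y
  resid <- y - X %*% beta
  GZtVi <- Gu %*% t(Z) %*% Vi
  u <- GZtVi %*% resid
  # Var(u - u_hat) including fixed-effect estimation error
  P <- Vi - t(XtVi) %*% B %*% XtVi
  pev <- unname(diag(Gu - Gu %*% t(Z) %*% P %*% Z %*% Gu))
  list(beta = as.numeric(beta), u = as.numeric(u), pev = pev)
}

# HWE exact test by direct enumeration with a recurrence on heterozygote
# probabilities (independent of the lgamma evaluation in the package).
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  n_minor <- min(na, 2 * n - na)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      hom_min <- (n_minor - h) / 2
      hom_maj <- n - h - hom_min
      # P(h+2) / P(h)
      probs[k + 1] <- probs[k] * 4 * hom_min * hom_maj /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_ab)
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

# Profiled restricted-likelihood grid over heritability; Arel restricted to
# phenotyped animals via `ai`. Returns the h2 grid value with maximal lR.
oracle_reml_grid <- function(y, X, ai, Arel, h2_grid = seq(0.0001, 0.9999,
                                                          by = 1e-4)) {
  N <- length(y)
  Z <- matrix(0, N, nrow(Arel))
  Z[cbind(seq_len(N), ai)] <- 1
  App <- Z %*% Arel %*% t(Z)
  p <- qr(X)$rank
  m2ll <- vapply(h2_grid, function(h2) {
    alpha <- (1 - h2) / h2
    V0 <- App / alpha + diag(N)
    V0i <- solve(V0)
    XtV0i <- t(X) %*% V0i
    B <- solve(XtV0i %*% X)
    P0 <- V0i - t(XtV0i) %*% B %*% XtV0i
    s <- as.numeric(t(y) %*% P0 %*% y) / (N - p)
    as.numeric(determinant(V0)$modulus) +
      as.numeric(determinant(XtV0i %*% X)$modulus) +
      (N - p) * log(s)
  }, numeric(1))
  h2_grid[which.min(m2ll)]
}

# Naive EM-REML: the textbook updates with an explicit dense inverse of the
# mixed-model equations every iteration. Same start as em_reml().
oracle_naive_em <- function(y, X, ai, K, n_iter, start = NULL) {
  N <- length(y)
  q <- nrow(K)
  p <- ncol(X)
  Z <- matrix(0, N, q)
  Z[cbind(seq_len(N), ai)] <- 1
  vp <- stats::var(y)
  sa2 <- if (is.null(start)) vp / 2 else start$sigma_a2
  se2 <- if (is.null(start)) vp / 2 else start$sigma_e2
  for (it in seq_len(n_iter)) {
    alpha <- se2 / sa2
    LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                 cbind(crossprod(Z, X), crossprod(Z) + alpha * K))
    RHS <- c(crossprod(X, y), crossprod(Z, y))
    C <- solve(LHS)
    sol <- C %*% RHS
    beta <- sol[1:p]
    u <- sol[-(1:p)]
    Cuu <- C[-(1:p), -(1:p)]
    sa2 <- (as.numeric(t(u) %*% K %*% u) + se2 * sum(diag(K %*% Cuu))) / q
    se2 <- as.numeric(sum(y^2) - t(beta) %*% crossprod(X, y) -
                        t(u) %*% crossprod(Z, y)) / (N - p)
  }
  list(sigma_a2 = sa2, sigma_e2 = se2)
}

# Dense single-step H built blockwise from A and G*, then inverted.
oracle_H_inverse <- function(A, Gstar, gidx) {
  n <- nrow(A)
  nidx <- setdiff(seq_len(n), gidx)
  A11 <- A[nidx, nidx, drop = FALSE]
  A12 <- A[nidx, gidx, drop = FALSE]
  A22 <- A[gidx, gidx, drop = FALSE]
  A22i <- solve(A22)
  H <- matrix(0, n, n)
  H[nidx, nidx] <- A11 + A12 %*% A22i %*% (Gstar - A22) %*% A22i %*% t(A12)
  H[nidx, gidx] <- A12 %*% A22i %*% Gstar
  H[gidx, nidx] <- t(H[nidx, gidx])
  H[gidx, gidx] <- Gstar
  solve(H)
}
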