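#' Animal-model specification
#'
#' Describes a single-trait animal model `y = X b + Z u + e` with
#' `Var(u) = K^-1 sigma_a^2` for a supplied relationship inverse `K`
#' (`A^-1` for PBLUP, `H^-1` for ssGBLUP) and `Var(e) = I sigma_e^2`.
#' Class effects are expanded to dummy columns with the first level
#' constrained to zero (corner-point parameterization); covariates enter
#' linearly.
#'
#' @param trait name of the trait column in the phenotype table
#' @param fixed_class character vector of class-effect columns
#' @param fixed_covariate character vector of covariate columns
#' @param components `list(sigma_a2 =, sigma_e2 =)` or `NULL` to estimate by
#'   [em_reml()]
#' @param relationship a `rel_matrix` of kind `"A_inverse"` or `"H_inverse"`
#' @return object of class `model_spec`
#' @export
model_spec <- function(trait,
                       fixed_class = c("birth_year", "birth_month",
                                       "slaughter_place"),
                       fixed_covariate = "slaughter_age_months",
                       components = NULL,
                       relationship = NULL) {
  if (!is.null(components)) {
    stopifnot(components$sigma_a2 > 0, components$sigma_e2 > 0)
  }
  if (!is.null(relationship)) {
    stopifnot(inherits(relationship, "rel_matrix"),
              relationship$kind %in% c("A_inverse", "H_inverse"))
  }
  structure(list(trait = trait, fixed_class = fixed_class,
                 fixed_covariate = fixed_covariate, components = components,
                 relationship = relationship),
            class = "model_spec")
}

# fixed-effect design matrix with intercept, corner-constrained class dummies
# and covariates; deterministic level order (sorted unique values)
build_X <- function(phenotypes, fixed_class, fixed_covariate) {
  n <- nrow(phenotypes)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (fc in fixed_class) {
    if (!fc %in% names(phenotypes)) stop("missing fixed effect column: ", fc)
    f <- factor(phenotypes[[fc]])
    if (nlevels(f) > 1) {
      D <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(D) <- paste0(fc, ":", levels(f)[-1])
      X <- cbind(X, D)
    }
  }
  for (cv in fixed_covariate) {
    if (!cv %in% names(phenotypes)) stop("missing covariate column: ", cv)
    X <- cbind(X, as.numeric(phenotypes[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  storage.mode(X) <- "double"
  X
}

#' Assemble Henderson's mixed-model equations
#'
#' `LHS = [[X'X, X'Z], [Z'X, Z'Z + alpha K]]`, `RHS = [X'y, Z'y]` with
#' `alpha = sigma_e^2 / sigma_a^2` and `K` the relationship inverse
#' (residuals absorbed as `R = I sigma_e^2`). Every animal carried by `K`
#' receives an equation whether phenotyped or not. If the fixed-effect block
#' is rank-deficient beyond the corner constraint a warning is issued and
#' downstream solves use a generalized inverse.
#'
#' @param spec a `model_spec` with `components` and `relationship` set
#' @param phenotypes data frame; column `animal` plus the model columns;
#'   rows with a missing trait value are dropped
#' @param ped_ids ordered animal labels of the equations; must equal the
#'   relationship matrix ids
#' @return object of class `mme`: LHS, RHS, X, y, animal row bookkeeping
#' @export
build_mme <- function(spec, phenotypes, ped_ids = spec$relationship$ids) {
  stopifnot(inherits(spec, "model_spec"), !is.null(spec$relationship),
            !is.null(spec$components))
  K <- spec$relationship
  if (!identical(as.character(ped_ids), K$ids)) {
    stop("ped_ids must match the relationship matrix ids in order")
  }
  phenotypes <- phenotypes[!is.na(phenotypes[[spec$trait]]), , drop = FALSE]
  ai <- match(as.character(phenotypes$animal), K$ids)
  if (anyNA(ai)) {
    stop("phenotyped animals missing from relationship matrix: ",
         paste(phenotypes$animal[is.na(ai)], collapse = ", "))
  }
  y <- as.numeric(phenotypes[[spec$trait]])
  X <- build_X(phenotypes, spec$fixed_class, spec$fixed_covariate)
  N <- length(y)
  q <- length(K$ids)
  p <- ncol(X)
  alpha <- spec$components$sigma_e2 / spec$components$sigma_a2

  Z <- Matrix::sparseMatrix(i = seq_len(N), j = ai, x = 1, dims = c(N, q))
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(Matrix::Matrix(X, sparse = TRUE), Z))
  ZtZ <- Matrix::Diagonal(x = tabulate(ai, nbins = q))
  LHS <- matrix(0, p + q, p + q)
  LHS[1:p, 1:p] <- XtX
  LHS[1:p, p + 1:q] <- XtZ
  LHS[p + 1:q, 1:p] <- t(XtZ)
  LHS[p + 1:q, p + 1:q] <- as.matrix(ZtZ + alpha * K$values)
  RHS <- c(crossprod(X, y), as.numeric(Matrix::crossprod(Z, y)))

  rank_x <- qr(X)$rank
  if (rank_x < p) {
    warning("fixed effects confounded beyond the corner constraint (rank ",
            rank_x, " < ", p, "); generalized inverse will be used")
  }
  structure(list(LHS = LHS, RHS = RHS, X = X, y = y, n_fixed = p,
                 ids = K$ids, record_animal = ai, alpha = alpha,
                 components = spec$components, trait = spec$trait,
                 rank_x = rank_x, kind = K$kind),
            class = "mme")
}

#' Solve the mixed-model equations
#'
#' Direct solve (Cholesky when the system is positive definite, generalized
#' inverse otherwise); deterministic given its inputs.
#'
#' @param mme an `mme` from [build_mme()]
#' @return list with `beta` (fixed-effect solutions, named), `u` (breeding
#'   values, named by animal), and `used_ginv`
#' @export
solve_mme <- function(mme) {
  sol <- NULL
  used_ginv <- FALSE
  if (mme$rank_x == mme$n_fixed) {
    sol <- tryCatch(solve(mme$LHS, mme$RHS), error = function(e) NULL)
  }
  if (is.null(sol)) {
    used_ginv <- TRUE
    sol <- MASS::ginv(mme$LHS) %*% mme$RHS
    if (mme$rank_x == mme$n_fixed) {
      stop("mixed-model equations singular after constraints")
    }
  }
  sol <- as.numeric(sol)
  p <- mme$n_fixed
  beta <- stats::setNames(sol[1:p], colnames(mme$X))
  u <- stats::setNames(sol[-(1:p)], mme$ids)
  list(beta = beta, u = u, used_ginv = used_ginv)
}

#' Animal-block diagonal of the inverted coefficient matrix
#'
#' Explicit dense inverse of the LHS (desk scale); returns the diagonal
#' entries `C^uu_ii` corresponding to the animal equations.
#'
#' @param mme an `mme`
#' @return numeric vector named by animal
#' @export
mme_inverse_animal_diag <- function(mme) {
  Cmat <- if (mme$rank_x == mme$n_fixed) {
    tryCatch(chol2inv(chol(mme$LHS)), error = function(e) solve(mme$LHS))
  } else {
    MASS::ginv(mme$LHS)
  }
  stats::setNames(diag(Cmat)[-(1:mme$n_fixed)], mme$ids)
}

#' Prediction error variance from the inverted coefficient matrix
#'
#' `PEV_i = C^uu_ii * sigma_e^2`, the standard scaling when the equations are
#' assembled with the variance ratio `alpha`.
#'
#' @param lhs_inverse_diag animal-block diagonal of the inverse LHS
#'   ([mme_inverse_animal_diag()])
#' @param sigma_e2 residual variance
#' @return per-animal PEV (named as the input)
#' @export
compute_pev <- function(lhs_inverse_diag, sigma_e2) {
  lhs_inverse_diag * sigma_e2
}

#' Accuracy (reliability) of estimated breeding values
#'
#' Default mode `"reliability"` applies the printed evaluation formula
#' `Acc = 1 - PEV / sigma_a^2` (which in standard usage is the reliability);
#' mode `"sqrt"` returns its square root, the conventional accuracy. PEV
#' exceeding `sigma_a^2` (numerical overshoot) is clamped to accuracy 0 with
#' a warning.
#'
#' @param pev per-animal prediction error variance
#' @param sigma_a2 additive genetic variance (> 0)
#' @param mode `"reliability"` (default) or `"sqrt"`
#' @return per-animal accuracy in `[0, 1]`
#' @export
compute_accuracy <- function(pev, sigma_a2, mode = c("reliability", "sqrt")) {
  mode <- match.arg(mode)
  stopifnot(sigma_a2 > 0)
  rel <- 1 - pev / sigma_a2
  if (any(rel < 0)) {
    warning(sum(rel < 0), " animals with PEV > sigma_a2; accuracy clamped ",
            "to 0")
    rel[rel < 0] <- 0
  }
  if (mode == "sqrt") sqrt(rel) else rel
}

#' Heritability from variance components
#'
#' `sigma_p^2 = sigma_a^2 + sigma_e^2`; `h^2 = sigma_a^2 / sigma_p^2`.
#'
#' @param sigma_a2 additive genetic variance (>= 0)
#' @param sigma_e2 residual variance (>= 0)
#' @return list with `h2` and `sigma_p2`
#' @export
compute_heritability <- function(sigma_a2, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0)
  sigma_p2 <- sigma_a2 + sigma_e2
  if (sigma_p2 == 0) stop("phenotypic variance is zero")
  list(h2 = sigma_a2 / sigma_p2, sigma_p2 = sigma_p2)
}

#' Run a full single-trait evaluation
#'
#' Convenience wrapper: optional EM-REML for the variance components, MME
#' assembly and solve, PEV and accuracy. This is the engine behind both the
#' PBLUP and the ssGBLUP arms of [run_comparison()] — the only difference
#' between the two is the relationship inverse passed in.
#'
#' @param spec a `model_spec` (components may be `NULL` to trigger REML)
#' @param phenotypes phenotype data frame (column `animal` + model columns)
#' @param accuracy_mode passed to [compute_accuracy()]
#' @param reml_control list of arguments forwarded to [em_reml()]
#' @return object of class `evaluation`: data frame `animals` with columns
#'   `animal`, `bv`, `pev`, `accuracy`; `fixed_solutions`; `components`
#'   (including `h2`, `sigma_p2`); `variance_estimate` when REML ran
#' @export
evaluate_blup <- function(spec, phenotypes,
                          accuracy_mode = c("reliability", "sqrt"),
                          reml_control = list()) {
  accuracy_mode <- match.arg(accuracy_mode)
  ve <- NULL
  if (is.null(spec$components)) {
    ve <- do.call(em_reml, c(list(phenotypes = phenotypes,
                                  relationship = spec$relationship,
                                  trait = spec$trait,
                                  fixed_class = spec$fixed_class,
                                  fixed_covariate = spec$fixed_covariate),
                             reml_control))
    spec$components <- list(sigma_a2 = ve$sigma_a2, sigma_e2 = ve$sigma_e2)
  }
  mme <- build_mme(spec, phenotypes)
  sol <- solve_mme(mme)
  cuu <- mme_inverse_animal_diag(mme)
  pev <- compute_pev(cuu, spec$components$sigma_e2)
  acc <- compute_accuracy(pev, spec$components$sigma_a2, accuracy_mode)
  h <- compute_heritability(spec$components$sigma_a2,
                            spec$components$sigma_e2)
  structure(list(
    animals = data.frame(animal = mme$ids, bv = unname(sol$u),
                         pev = unname(pev), accuracy = unname(acc),
                         stringsAsFactors = FALSE),
    fixed_solutions = sol$beta,
    components = c(spec$components, h),
    accuracy_mode = accuracy_mode,
    kind = mme$kind,
    variance_estimate = ve
  ), class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat("<evaluation ", if (x$kind == "A_inverse") "PBLUP" else "ssGBLUP",
      "> ", nrow(x$animals), " animals; sigma_a2=",
      format(x$components$sigma_a2, digits = 5), ", sigma_e2=",
      format(x$components$sigma_e2, digits = 5), ", h2=",
      format(x$components$h2, digits = 3), "; mean accuracy=",
      format(mean(x$animals$accuracy), digits = 3), "\n", sep = "")
  invisible(x)
}
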