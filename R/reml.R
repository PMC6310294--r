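#' Model specification for the animal model
#'
#' The fitted model is `y = Xb + Pl + Za + e` with a random common-litter
#' (permanent environmental) effect `l ~ N(0, I sigma2_pe)`, additive
#' genetic effect `a ~ N(0, A sigma2_a)` over the full pedigree, and
#' residual `e ~ N(0, I sigma2_e)`. Fixed factors default to the study
#' preset for known trait names ([study_fixed()]); the first level of each
#' factor is constrained to zero (treatment contrasts).
#'
#' @param trait name of the trait column in the phenotype table.
#' @param fixed character vector of fixed-factor column names (subset of
#'   `sex`, `breed`, `rearing`, `finishing`, `familiar`); `NULL` uses the
#'   study preset.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(trait, fixed = NULL) {
  if (is.null(fixed)) fixed <- study_fixed(trait)
  stopifnot(is.character(trait), length(trait) == 1L)
  out <- list(trait = trait, fixed = fixed)
  class(out) <- "model_spec"
  out
}

#' Study-preset fixed factors per trait
#'
#' Preweaning traits (BT1, BT2, INJ, PSS, PDG): sex + breed. Rearing-stage
#' traits (RLS, RSS, LS1, RDG): + rearing housing. Post-mixing lesion traits
#' (LS2, LSD): + rearing + unfamiliar-pig class. Finishing traits (FLS,
#' FSS, FDG): sex + breed + finishing housing. Lifetime gain (ADG): sex +
#' breed + rearing + finishing.
#'
#' @param trait trait name.
#' @return Character vector of factor names.
#' @export
study_fixed <- function(trait) {
  switch(trait,
    BT1 = , BT2 = , INJ = , PSS = , PDG = c("sex", "breed"),
    RLS = , RSS = , LS1 = , RDG = c("sex", "breed", "rearing"),
    LS2 = , LSD = c("sex", "breed", "rearing", "familiar"),
    FLS = , FSS = , FDG = c("sex", "breed", "finishing"),
    ADG = c("sex", "breed", "rearing", "finishing"),
    c("sex", "breed")
  )
}

#' Prepare the design for REML evaluation
#'
#' Assembles response, fixed-effect design (rank-checked), litter and
#' animal incidence matrices and the sparse inverse relationship matrix for
#' one trait, dropping records with missing phenotype (animals stay in the
#' pedigree). Fixed factors with fewer than two observed levels are dropped
#' with a message.
#'
#' @param phenotypes phenotype data.frame (see [read_phenotypes()]).
#' @param ped validated pedigree containing every phenotyped animal.
#' @param spec a [model_spec()].
#' @return List of class `reml_design` (used by [reml_loglik()],
#'   [fit_univariate()] and [solve_mme()]).
#' @export
reml_design <- function(phenotypes, ped, spec) {
  assert_pedigree(ped)
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(phenotypes[[spec$trait]])) {
    stop("trait column '", spec$trait, "' not found in phenotype table")
  }
  missing_fac <- setdiff(spec$fixed, names(phenotypes))
  if (length(missing_fac)) {
    stop("fixed-effect column(s) not found: ", paste(missing_fac, collapse = ", "))
  }
  y <- phenotypes[[spec$trait]]
  keep <- !is.na(y) & !is.na(phenotypes$litter)
  for (f in spec$fixed) keep <- keep & !is.na(phenotypes[[f]])
  if (sum(keep) < 2L) stop("fewer than 2 usable records for trait ", spec$trait)
  dat <- phenotypes[keep, , drop = FALSE]
  y <- as.numeric(dat[[spec$trait]])
  if (stats::var(y) == 0) {
    stop("trait ", spec$trait, " is constant; variance components undefined")
  }
  unknown <- setdiff(dat$animal, ped$animal)
  if (length(unknown)) {
    stop("phenotyped animals absent from pedigree: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  }
  fixed <- spec$fixed
  for (f in fixed) {
    if (length(unique(dat[[f]])) < 2L) {
      message("dropping constant fixed factor '", f, "' for trait ", spec$trait)
      fixed <- setdiff(fixed, f)
    }
  }
  X <- if (length(fixed)) {
    fdat <- as.data.frame(lapply(dat[fixed], factor))
    stats::model.matrix(~., data = fdat)
  } else {
    matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confounded fixed effects (aliased columns): ",
         paste(aliased, collapse = ", "))
  }
  litters <- sort(unique(dat$litter))
  if (length(litters) < 2L) stop("need at least 2 litters for trait ", spec$trait)
  W <- Matrix::sparseMatrix(i = seq_len(nrow(dat)),
                            j = match(dat$litter, litters),
                            x = 1, dims = c(nrow(dat), length(litters)))
  aidx <- match(dat$animal, ped$animal)
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(dat)), j = aidx, x = 1,
                            dims = c(nrow(dat), nrow(ped)))
  Ainv <- relationship_inverse(ped)
  Tm <- cbind2(methods::as(X, "CsparseMatrix"), cbind2(W, Z))
  p <- ncol(X)
  ql <- ncol(W)
  qa <- nrow(ped)
  Dpe <- Matrix::Diagonal(x = c(rep(0, p), rep(1, ql), rep(0, qa)))
  Da <- Matrix::bdiag(Matrix::Diagonal(p + ql, 0), Ainv)
  env <- new.env(parent = emptyenv()) # cached symbolic Cholesky
  structure(list(
    y = y, X = X, Tm = Tm, TtT = Matrix::forceSymmetric(Matrix::crossprod(Tm)),
    Tty = Matrix::crossprod(Tm, y), yty = sum(y^2),
    n = length(y), p = p, ql = ql, qa = qa,
    Dpe = Matrix::forceSymmetric(methods::as(Dpe, "CsparseMatrix")),
    Da = Matrix::forceSymmetric(methods::as(Da, "CsparseMatrix")),
    logdetA = attr(Ainv, "logdet"),
    animal = dat$animal, ped_animal = ped$animal,
    litters = litters, fixed = fixed, xnames = colnames(X),
    trait = spec$trait, cache = env
  ), class = "reml_design")
}

## One evaluation of the restricted log-likelihood through the sparse MME
## (Graser et al. formulation): -2 lR = (n-p) log 2pi + log|R| + log|G| +
## log|C| + y'Py. Optionally returns the MME solutions.
reml_eval <- function(dsg, s2a, s2pe, s2e, solutions = FALSE) {
  C <- dsg$TtT * (1 / s2e) + dsg$Dpe * (1 / s2pe) + dsg$Da * (1 / s2a)
  ch <- dsg$cache$chol
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(C, LDL = FALSE)
    dsg$cache$chol <- ch
  } else {
    ch <- Matrix::update(ch, C)
  }
  rhs <- dsg$Tty * (1 / s2e)
  sol <- Matrix::solve(ch, rhs, system = "A")
  yPy <- dsg$yty / s2e - sum(sol * rhs)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  ll <- -0.5 * ((dsg$n - dsg$p) * log(2 * pi) +
                  dsg$n * log(s2e) +
                  dsg$ql * log(s2pe) + dsg$qa * log(s2a) + dsg$logdetA +
                  logdetC + yPy)
  if (!solutions) return(ll)
  sol <- as.numeric(sol)
  list(loglik = ll, fixef = stats::setNames(sol[seq_len(dsg$p)], dsg$xnames),
       litter = stats::setNames(sol[dsg$p + seq_len(dsg$ql)], dsg$litters),
       ebv = stats::setNames(sol[dsg$p + dsg$ql + seq_len(dsg$qa)],
                             dsg$ped_animal),
       C = C, rhs = rhs)
}

#' Restricted log-likelihood at given variance components
#'
#' Exact evaluation (not an approximation) via the mixed-model-equation
#' identity `log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|`; used both
#' by the fitting routine and for likelihood-surface diagnostics such as
#' grid checks around a converged fit.
#'
#' @param design a [reml_design()].
#' @param sigma2_a,sigma2_pe,sigma2_e variance components (> 0).
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(design, sigma2_a, sigma2_pe, sigma2_e) {
  stopifnot(inherits(design, "reml_design"),
            sigma2_a > 0, sigma2_pe > 0, sigma2_e > 0)
  reml_eval(design, sigma2_a, sigma2_pe, sigma2_e)
}

#' Fit the univariate Gaussian animal model by REML
#'
#' Maximises the restricted likelihood over `(sigma2_a, sigma2_pe,
#' sigma2_e)` by quasi-Newton search on log-variances, with the likelihood
#' evaluated through sparse mixed-model equations. Standard errors come
#' from the inverse of a central-finite-difference information matrix on
#' the variance scale; BLUP solutions are returned at the converged
#' components. Variances are bounded below by `1e-8` times the phenotypic
#' variance; an estimate within 10% of that floor is flagged as boundary.
#'
#' @param phenotypes,ped,spec data, pedigree and [model_spec()].
#' @param se compute standard errors (default `TRUE`).
#' @param start optional starting components `c(sigma2_a, sigma2_pe,
#'   sigma2_e)`.
#' @param control list: `maxit` (default 200) and `factr` passed to
#'   [stats::optim()]'s L-BFGS-B.
#' @return Object of class `herd_vc` with elements `components`, `se`,
#'   `vcov`, `h2`, `se_h2`, `loglik`, `converged`, `n_iter`, `boundary`,
#'   `fixef`, `ebv` (data.frame `animal`, `ebv`, `with_own_record`) and the
#'   `design` used.
#' @export
fit_univariate <- function(phenotypes, ped, spec, se = TRUE, start = NULL,
                           control = list()) {
  dsg <- reml_design(phenotypes, ped, spec)
  maxit <- control$maxit %||% 200L
  factr <- control$factr %||% 1e7
  vary <- stats::var(dsg$y)
  if (is.null(start)) start <- vary * c(0.3, 0.1, 0.6)
  lower <- log(1e-8 * vary)
  upper <- log(1e3 * vary)
  nll <- function(lpar) {
    -reml_eval(dsg, exp(lpar[1]), exp(lpar[2]), exp(lpar[3]))
  }
  opt <- stats::optim(log(pmax(start, 2e-8 * vary)), nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr))
  theta <- exp(opt$par)
  names(theta) <- c("sigma2_a", "sigma2_pe", "sigma2_e")
  boundary <- theta <= 1.1e-8 * vary
  sol <- reml_eval(dsg, theta[1], theta[2], theta[3], solutions = TRUE)
  vc <- list(trait = dsg$trait, components = theta,
             loglik = sol$loglik, converged = opt$convergence == 0,
             n_iter = unname(opt$counts[1]), boundary = boundary,
             fixef = sol$fixef, litter_effects = sol$litter)
  class(vc) <- "herd_vc"
  if (se) {
    H <- fd_hessian(function(th) {
      -reml_eval(dsg, max(th[1], 1e-10 * vary), max(th[2], 1e-10 * vary),
                 max(th[3], 1e-10 * vary))
    }, theta, rel = 1e-3, abs = 1e-7 * vary)
    vcv <- try(solve(H), silent = TRUE)
    if (inherits(vcv, "try-error") || any(!is.finite(vcv))) {
      vcv <- matrix(NA_real_, 3, 3)
    }
    dimnames(vcv) <- list(names(theta), names(theta))
    vc$vcov <- vcv
    vc$se <- sqrt(pmax(diag(vcv), 0))
  } else {
    vc$vcov <- matrix(NA_real_, 3, 3)
    vc$se <- rep(NA_real_, 3)
  }
  h <- heritability(vc)
  vc$h2 <- h$h2
  vc$se_h2 <- h$se
  vc$ebv <- data.frame(animal = dsg$ped_animal, ebv = unname(sol$ebv),
                       with_own_record = dsg$ped_animal %in% dsg$animal,
                       stringsAsFactors = FALSE)
  vc$design <- dsg
  vc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## central finite-difference Hessian
fd_hessian <- function(f, x, rel = 1e-3, abs = 1e-8) {
  k <- length(x)
  h <- pmax(rel * base::abs(x), abs)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        H[i, i] <- (f(x + h * (seq_len(k) == i)) - 2 * f(x) +
                      f(x - h * (seq_len(k) == i))) / h[i]^2
      } else {
        ei <- h * (seq_len(k) == i)
        ej <- h * (seq_len(k) == j)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.herd_vc <- function(x, ...) {
  cat("Animal-model REML fit, trait", x$trait, "\n")
  cmp <- rbind(estimate = x$components, se = x$se)
  print(round(cmp, 4))
  cat(sprintf("h2 = %.3f (SE %.3f); logLik = %.3f; %s in %d evaluations\n",
              x$h2, x$se_h2, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (any(x$boundary)) {
    cat("boundary estimate:", paste(names(x$components)[x$boundary],
                                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`. For a fitted
#' `herd_vc` object the standard error is propagated from the component
#' covariance matrix by the first-order delta method.
#'
#' @param x a `herd_vc` fit, or the additive variance if raw components are
#'   given.
#' @param sigma2_pe,sigma2_e litter and residual variances when `x` is
#'   numeric (vectorised).
#' @return For a fit: list with `h2` and `se`. For numeric input: numeric
#'   vector of heritabilities.
#' @examples
#' heritability(0.52, 0.08, 0.87)
#' @export
heritability <- function(x, sigma2_pe = NULL, sigma2_e = NULL) {
  if (is.numeric(x)) {
    tot <- x + sigma2_pe + sigma2_e
    if (any(tot <= 0)) stop("total variance must be positive")
    return(x / tot)
  }
  stopifnot(inherits(x, "herd_vc"))
  th <- x$components
  tot <- sum(th)
  if (tot <= 0) stop("total variance must be positive")
  h2 <- th[["sigma2_a"]] / tot
  se <- NA_real_
  if (!anyNA(x$vcov)) {
    g <- c((tot - th[[1]]) / tot^2, -th[[1]] / tot^2, -th[[1]] / tot^2)
    se <- sqrt(max(0, drop(t(g) %*% x$vcov %*% g)))
  }
  list(h2 = unname(h2), se = se)
}

#' Solve the mixed-model equations at fixed components
#'
#' Henderson's equations with `A^-1 sigma2_e / sigma2_a` on the animal
#' block; no variance re-estimation. The relative residual of the linear
#' system is checked against `1e-8`.
#'
#' @inheritParams fit_univariate
#' @param components numeric `c(sigma2_a, sigma2_pe, sigma2_e)` or a
#'   `herd_vc` fit.
#' @return List with `fixef`, `litter_effects`, `ebv` (data.frame over all
#'   pedigree animals), `residual_rel` and `loglik`.
#' @export
solve_mme <- function(phenotypes, ped, spec, components) {
  if (inherits(components, "herd_vc")) components <- components$components
  stopifnot(length(components) == 3, all(components > 0))
  dsg <- if (inherits(phenotypes, "reml_design")) phenotypes else
    reml_design(phenotypes, ped, spec)
  sol <- reml_eval(dsg, components[1], components[2], components[3],
                   solutions = TRUE)
  full <- c(sol$fixef, sol$litter, sol$ebv)
  resid <- sol$C %*% full - sol$rhs
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(sol$rhs^2)), 1e-300)
  if (rel > 1e-8) {
    stop("mixed-model equations solved to relative residual ", format(rel),
         " > 1e-8 (internal error)")
  }
  list(fixef = sol$fixef, litter_effects = sol$litter,
       ebv = data.frame(animal = dsg$ped_animal, ebv = unname(sol$ebv),
                        with_own_record = dsg$ped_animal %in% dsg$animal,
                        stringsAsFactors = FALSE),
       residual_rel = rel, loglik = sol$loglik)
}

## ---------- bivariate ----------

bivariate_design <- function(phenotypes, ped, spec1, spec2) {
  d1 <- reml_design(phenotypes, ped, spec1)
  d2 <- reml_design(phenotypes, ped, spec2)
  litters <- sort(unique(c(d1$litters, d2$litters)))
  ql <- length(litters)
  qa <- nrow(ped)
  ## rebuild litter incidence on the union level set
  lit1 <- phenotypes$litter[match(d1$animal, phenotypes$animal)]
  lit2 <- phenotypes$litter[match(d2$animal, phenotypes$animal)]
  W1 <- Matrix::sparseMatrix(i = seq_len(d1$n), j = match(lit1, litters),
                             x = 1, dims = c(d1$n, ql))
  W2 <- Matrix::sparseMatrix(i = seq_len(d2$n), j = match(lit2, litters),
                             x = 1, dims = c(d2$n, ql))
  Z1 <- Matrix::sparseMatrix(i = seq_len(d1$n),
                             j = match(d1$animal, ped$animal), x = 1,
                             dims = c(d1$n, qa))
  Z2 <- Matrix::sparseMatrix(i = seq_len(d2$n),
                             j = match(d2$animal, ped$animal), x = 1,
                             dims = c(d2$n, qa))
  X <- Matrix::bdiag(methods::as(d1$X, "CsparseMatrix"),
                     methods::as(d2$X, "CsparseMatrix"))
  Wb <- Matrix::bdiag(W1, W2)
  Zb <- Matrix::bdiag(Z1, Z2)
  Tm <- cbind2(X, cbind2(Wb, Zb))
  y <- c(d1$y, d2$y)
  n1 <- d1$n
  n2 <- d2$n
  both <- intersect(d1$animal, d2$animal)
  i1 <- match(both, d1$animal)
  i2 <- n1 + match(both, d2$animal)
  Ainv <- relationship_inverse(ped)
  structure(list(
    y = y, Tm = Tm, n1 = n1, n2 = n2, n = n1 + n2, p = ncol(X),
    p1 = d1$p, p2 = d2$p, ql = ql, qa = qa,
    i_both1 = i1, i_both2 = i2, n_both = length(both),
    Ainv = Ainv, logdetA = attr(Ainv, "logdet"),
    Iql = Matrix::Diagonal(ql),
    animal1 = d1$animal, animal2 = d2$animal, ped_animal = ped$animal,
    xnames = c(paste0(spec1$trait, ":", d1$xnames),
               paste0(spec2$trait, ":", d2$xnames)),
    traits = c(spec1$trait, spec2$trait),
    d1 = d1, d2 = d2, cache = new.env(parent = emptyenv())
  ), class = "bireml_design")
}

## theta = list(Ga, Gpe, Re) of 2x2 covariance matrices
bireml_eval <- function(dsg, Ga, Gpe, Re, solutions = FALSE) {
  n <- dsg$n
  s2e <- diag(Re)
  ce <- Re[1, 2]
  detR0 <- s2e[1] * s2e[2] - ce^2
  if (detR0 <= 0 || any(s2e <= 0)) return(-Inf)
  xdiag <- c(rep(1 / s2e[1], dsg$n1), rep(1 / s2e[2], dsg$n2))
  xboth <- rep(-ce / detR0, dsg$n_both)
  if (dsg$n_both) {
    ## jointly-recorded animals get the 2x2 inverse residual block
    xdiag[dsg$i_both1] <- s2e[2] / detR0
    xdiag[dsg$i_both2] <- s2e[1] / detR0
  }
  Rinv <- Matrix::sparseMatrix(
    i = c(seq_len(n), dsg$i_both1, dsg$i_both2),
    j = c(seq_len(n), dsg$i_both2, dsg$i_both1),
    x = c(xdiag, xboth, xboth), dims = c(n, n))
  logdetR <- dsg$n_both * log(detR0) +
    (dsg$n1 - dsg$n_both) * log(s2e[1]) + (dsg$n2 - dsg$n_both) * log(s2e[2])
  Gai <- solve(Ga)
  Gpei <- solve(Gpe)
  Ginv <- Matrix::bdiag(
    Matrix::Diagonal(dsg$p, 0),
    Matrix::kronecker(Gpei, dsg$Iql),
    Matrix::kronecker(Gai, dsg$Ainv)
  )
  RT <- Rinv %*% dsg$Tm
  C <- Matrix::forceSymmetric(Matrix::crossprod(dsg$Tm, RT) + Ginv)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  rhs <- Matrix::crossprod(RT, dsg$y)
  sol <- Matrix::solve(ch, rhs, system = "A")
  yRy <- sum(dsg$y * (Rinv %*% dsg$y))
  yPy <- yRy - sum(sol * rhs)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  logdetG <- dsg$qa * determinant(Ga, logarithm = TRUE)$modulus +
    2 * dsg$logdetA + dsg$ql * determinant(Gpe, logarithm = TRUE)$modulus
  ll <- -0.5 * ((n - dsg$p) * log(2 * pi) + logdetR + as.numeric(logdetG) +
                  logdetC + yPy)
  if (!solutions) return(ll)
  sol <- as.numeric(sol)
  a <- sol[dsg$p + 2 * dsg$ql + seq_len(2 * dsg$qa)]
  list(loglik = ll,
       fixef = stats::setNames(sol[seq_len(dsg$p)], dsg$xnames),
       ebv1 = stats::setNames(a[seq_len(dsg$qa)], dsg$ped_animal),
       ebv2 = stats::setNames(a[dsg$qa + seq_len(dsg$qa)], dsg$ped_animal))
}

## parameter packing: log variances + atanh correlations
bi_unpack <- function(par, est_re) {
  v <- exp(par[1:6])
  ra <- tanh(par[7])
  rpe <- tanh(par[8])
  re <- if (est_re) tanh(par[9]) else 0
  list(Ga = matrix(c(v[1], ra * sqrt(v[1] * v[2]),
                     ra * sqrt(v[1] * v[2]), v[2]), 2),
       Gpe = matrix(c(v[3], rpe * sqrt(v[3] * v[4]),
                      rpe * sqrt(v[3] * v[4]), v[4]), 2),
       Re = matrix(c(v[5], re * sqrt(v[5] * v[6]),
                     re * sqrt(v[5] * v[6]), v[6]), 2))
}

#' Fit the bivariate Gaussian animal model by REML
#'
#' Two-trait extension of [fit_univariate()]: additive, litter and residual
#' effects carry 2x2 covariance matrices; the residual covariance is
#' estimated only when some animals have records for both traits, and fixed
#' at zero otherwise. Returns genetic, litter, residual and phenotypic
#' correlations with delta-method standard errors. A trait whose additive
#' variance sits at the boundary flags the genetic correlation as
#' unreliable (it is still reported).
#'
#' @param phenotypes,ped data and pedigree.
#' @param spec1,spec2 [model_spec()] for the two traits.
#' @param se compute standard errors (slower; default `TRUE`).
#' @param control list with `maxit` (default 400).
#' @return Object of class `herd_vc2` with `Ga`, `Gpe`, `Re`, `r_g`,
#'   `r_pe`, `r_e`, `r_p`, their SEs, per-trait heritabilities, `loglik`,
#'   `converged`, `unreliable`, and EBV data.frames `ebv1`, `ebv2`.
#' @export
fit_bivariate <- function(phenotypes, ped, spec1, spec2, se = TRUE,
                          control = list()) {
  dsg <- bivariate_design(phenotypes, ped, spec1, spec2)
  est_re <- dsg$n_both > 1L
  u1 <- fit_univariate(phenotypes, ped, spec1, se = FALSE)
  u2 <- fit_univariate(phenotypes, ped, spec2, se = FALSE)
  v0 <- c(u1$components[1], u2$components[1],
          u1$components[2], u2$components[2],
          u1$components[3], u2$components[3])
  vary <- stats::var(dsg$y)
  par0 <- c(log(pmax(v0, 1e-6 * vary)), 0, 0)
  if (est_re) par0 <- c(par0, 0)
  lower <- c(rep(log(1e-8 * vary), 6), rep(-5, length(par0) - 6))
  upper <- c(rep(log(1e4 * vary), 6), rep(5, length(par0) - 6))
  nll <- function(par) {
    th <- bi_unpack(par, est_re)
    ll <- bireml_eval(dsg, th$Ga, th$Gpe, th$Re)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = control$maxit %||% 400L))
  th <- bi_unpack(opt$par, est_re)
  sol <- bireml_eval(dsg, th$Ga, th$Gpe, th$Re, solutions = TRUE)
  stats_of <- function(par) {
    t2 <- bi_unpack(par, est_re)
    P <- t2$Ga + t2$Gpe + t2$Re
    c(r_g = t2$Ga[1, 2] / sqrt(t2$Ga[1, 1] * t2$Ga[2, 2]),
      r_pe = t2$Gpe[1, 2] / sqrt(t2$Gpe[1, 1] * t2$Gpe[2, 2]),
      r_e = if (est_re) t2$Re[1, 2] / sqrt(t2$Re[1, 1] * t2$Re[2, 2]) else 0,
      r_p = P[1, 2] / sqrt(P[1, 1] * P[2, 2]),
      h2_1 = t2$Ga[1, 1] / P[1, 1], h2_2 = t2$Ga[2, 2] / P[2, 2])
  }
  est <- stats_of(opt$par)
  ses <- rep(NA_real_, length(est))
  names(ses) <- names(est)
  if (se) {
    H <- fd_hessian(nll, opt$par, rel = 1e-3, abs = 1e-4)
    vcv <- try(solve(H), silent = TRUE)
    if (!inherits(vcv, "try-error") && all(is.finite(vcv))) {
      k <- length(opt$par)
      J <- matrix(0, length(est), k)
      for (j in seq_len(k)) {
        hstep <- max(1e-4 * abs(opt$par[j]), 1e-5)
        pp <- opt$par; pp[j] <- pp[j] + hstep
        pm <- opt$par; pm[j] <- pm[j] - hstep
        J[, j] <- (stats_of(pp) - stats_of(pm)) / (2 * hstep)
      }
      ses <- sqrt(pmax(diag(J %*% vcv %*% t(J)), 0))
      names(ses) <- names(est)
    }
  }
  bnd <- c(th$Ga[1, 1], th$Ga[2, 2]) <= 1.1e-8 * vary
  out <- list(
    traits = dsg$traits, Ga = th$Ga, Gpe = th$Gpe, Re = th$Re,
    r_g = unname(est["r_g"]), r_pe = unname(est["r_pe"]),
    r_e = unname(est["r_e"]), r_p = unname(est["r_p"]),
    h2 = unname(est[c("h2_1", "h2_2")]), se = ses,
    loglik = sol$loglik, converged = opt$convergence == 0,
    n_iter = unname(opt$counts[1]),
    unreliable = any(bnd), boundary_additive = bnd,
    residual_cov_estimated = est_re,
    fixef = sol$fixef,
    ebv1 = data.frame(animal = dsg$ped_animal, ebv = unname(sol$ebv1),
                      stringsAsFactors = FALSE),
    ebv2 = data.frame(animal = dsg$ped_animal, ebv = unname(sol$ebv2),
                      stringsAsFactors = FALSE)
  )
  class(out) <- "herd_vc2"
  out
}

#' @export
print.herd_vc2 <- function(x, ...) {
  cat("Bivariate animal-model REML fit:", paste(x$traits, collapse = " x "), "\n")
  cat(sprintf("r_g = %.3f (SE %.3f), r_p = %.3f (SE %.3f)\n",
              x$r_g, x$se["r_g"], x$r_p, x$se["r_p"]))
  cat(sprintf("h2: %.3f, %.3f; logLik %.2f; %s\n", x$h2[1], x$h2[2],
              x$loglik, if (x$converged) "converged" else "NOT converged"))
  if (x$unreliable) cat("NOTE: additive variance at boundary; correlations unreliable\n")
  invisible(x)
}
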