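#' Residual variance of the logistic liability
#'
#' The logit threshold model fixes the residual liability variance at the
#' variance of the standard logistic distribution, `pi^2/3`; it is never
#' estimated. Reports print it rounded to 3.29.
#'
#' @export
LOGIT_RESIDUAL_VARIANCE <- pi^2 / 3

#' Binary recoding schemes for behaviour scores
#'
#' A recoding scheme maps every value of a trait's support to 0 or 1 and
#' must be order-preserving (all 0s below the cut, all 1s above).
#' `study_recoding()` returns the preset cut-points used for the emulated
#' study traits: load and weighing scores 1 vs 2-3; injection and lesion
#' scores 1-2 vs 3-4; backtest counts 0-2 vs 3+.
#'
#' @param support integer support of the observed scores.
#' @param cut first value coded as 1 (everything below maps to 0).
#' @return Named integer vector of class `recoding_scheme` mapping
#'   `as.character(support)` to 0/1.
#' @examples
#' recoding_scheme(1:4, cut = 3) # injection/lesion style
#' @export
recoding_scheme <- function(support, cut) {
  support <- as.integer(support)
  map <- as.integer(support >= cut)
  if (all(map == 0L) || all(map == 1L)) {
    stop("cut leaves a single category; choose a cut inside the support")
  }
  structure(stats::setNames(map, as.character(support)),
            class = "recoding_scheme")
}

#' @rdname recoding_scheme
#' @param trait trait name (BT1, BT2, INJ, PSS, RLS, RSS, FLS, FSS, LS1,
#'   LS2).
#' @export
study_recoding <- function(trait) {
  switch(trait,
    BT1 = , BT2 = recoding_scheme(0:9, cut = 3L),
    INJ = recoding_scheme(1:4, cut = 3L),
    LS1 = , LS2 = recoding_scheme(1:4, cut = 3L),
    PSS = , RSS = , FSS = , RLS = , FLS = recoding_scheme(1:3, cut = 2L),
    stop("no preset recoding scheme for trait ", trait)
  )
}

#' @rdname recoding_scheme
#' @param scheme a `recoding_scheme` to serialise.
#' @param path file path for the YAML (key-value) serialisation.
#' @export
write_recoding <- function(scheme, path) {
  stopifnot(inherits(scheme, "recoding_scheme"))
  yaml::write_yaml(as.list(stats::setNames(as.integer(scheme),
                                           names(scheme))), path)
  invisible(path)
}

#' @rdname recoding_scheme
#' @export
read_recoding <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- as.integer(unlist(raw))
  if (!all(map %in% c(0L, 1L))) stop("recoding values must be 0 or 1")
  if (is.unsorted(map)) {
    stop("recoding scheme is not order-preserving over its support")
  }
  if (length(unique(map)) < 2L) stop("recoding scheme has a single category")
  structure(stats::setNames(map, names(raw)), class = "recoding_scheme")
}

#' Median-split cut-point
#'
#' Chooses the cut that brings the proportions of the two binary classes
#' closest to one half, for arbitrary score distributions.
#'
#' @param scores observed scores (missing values ignored).
#' @return A `recoding_scheme` over the observed support.
#' @export
median_split <- function(scores) {
  scores <- scores[!is.na(scores)]
  support <- sort(unique(as.integer(scores)))
  cuts <- support[-1]
  bal <- vapply(cuts, function(ct) abs(mean(scores >= ct) - 0.5), 0)
  recoding_scheme(support, cuts[which.min(bal)])
}

#' Recode scores to a binary trait
#'
#' Deterministic mapping through a [recoding_scheme()]; missing stays
#' missing; values outside the scheme's support are an error.
#'
#' @param scores per-animal trait values.
#' @param scheme a `recoding_scheme`.
#' @param trait trait name used in error messages.
#' @return Integer vector of 0/1 (with `NA` preserved).
#' @export
recode_binary <- function(scores, scheme, trait = "trait") {
  stopifnot(inherits(scheme, "recoding_scheme"))
  out <- rep(NA_integer_, length(scores))
  ok <- !is.na(scores)
  idx <- match(as.character(as.integer(scores[ok])), names(scheme))
  if (anyNA(idx)) {
    bad <- scores[ok][which(is.na(idx))[1L]]
    stop("score ", bad, " outside the declared support of ", trait)
  }
  out[ok] <- unname(scheme[idx])
  out
}

## ---------- Laplace-approximate logit animal model ----------
##
## Reduced animal model: the Mendelian-sampling deviation of every
## phenotyped NON-parent animal enters exactly one Bernoulli record and is
## integrated out exactly by Gauss-Hermite quadrature (the marginal
## likelihood is unchanged). The Laplace expansion is then applied only to
## parental breeding values and litter effects, each informed by many
## records, where it is accurate.

## Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix)
gauss_hermite <- function(k = 20L) {
  if (k == 1L) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(k - 1L) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  J[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

#' Prepare the reduced-animal-model design for the binary model
#'
#' Extends [reml_design()] with the bookkeeping of the reduced animal
#' model: parental breeding values are retained as explicit random effects
#' (with the inverse relationship matrix of the parent sub-pedigree), while
#' the Mendelian-sampling deviation of each phenotyped non-parent animal is
#' integrated out of its single Bernoulli record by Gauss-Hermite
#' quadrature.
#'
#' @inheritParams reml_design
#' @return A `reml_design` with an extra `bin` element.
#' @export
binary_design <- function(phenotypes, ped, spec) {
  dsg <- reml_design(phenotypes, ped, spec)
  n <- dsg$n
  is_parent <- ped$animal %in% c(ped$sire, ped$dam)
  retained <- which(is_parent)
  ## retained sub-pedigree (parents are closed under parenthood)
  if (length(retained)) {
    sub <- ped[retained, , drop = FALSE]
    class(sub) <- c("pedigree", "data.frame")
    sub$sire_idx <- match(ped$sire[retained], sub$animal)
    sub$dam_idx <- match(ped$dam[retained], sub$animal)
    sub$sire_idx[is.na(sub$sire_idx)] <- 0L
    sub$dam_idx[is.na(sub$dam_idx)] <- 0L
    ArInv <- relationship_inverse(sub)
    logdetAr <- attr(ArInv, "logdet")
  } else {
    ArInv <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, 0L))
    logdetAr <- 0
  }
  qr_ <- length(retained)
  dv <- mendelian_variance(ped)
  aidx <- match(dsg$animal, ped$animal)
  rmap <- match(seq_len(nrow(ped)), retained) # full ped index -> retained col
  ii <- jj <- integer(0)
  xx <- numeric(0)
  vcoef <- numeric(n) # multiplier of sigma2_a in the per-record integral
  for (r in seq_len(n)) {
    a <- aidx[r]
    if (!is.na(rmap[a])) { # record on a parent: its BV stays in the Laplace block
      ii <- c(ii, r); jj <- c(jj, rmap[a]); xx <- c(xx, 1)
    } else {
      s <- ped$sire_idx[a]
      d <- ped$dam_idx[a]
      if (s > 0L) { ii <- c(ii, r); jj <- c(jj, rmap[s]); xx <- c(xx, 0.5) }
      if (d > 0L) { ii <- c(ii, r); jj <- c(jj, rmap[d]); xx <- c(xx, 0.5) }
      vcoef[r] <- dv[a]
    }
  }
  Zr <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, qr_))
  Tr <- cbind2(methods::as(dsg$X, "CsparseMatrix"),
               cbind2(dsg$Tm[, dsg$p + seq_len(dsg$ql), drop = FALSE], Zr))
  gh <- gauss_hermite(20L)
  dsg$bin <- list(Tr = Tr, qr = qr_, retained = retained, ArInv = ArInv,
                  logdetAr = logdetAr, vcoef = vcoef, aidx = aidx,
                  rmap = rmap, gh = gh,
                  GinvPe = Matrix::Diagonal(x = c(rep(0, dsg$p),
                                                  rep(1, dsg$ql),
                                                  rep(0, qr_))),
                  GinvA = Matrix::bdiag(Matrix::Diagonal(dsg$p + dsg$ql, 0),
                                        ArInv))
  dsg
}

## per-record marginal Bernoulli-logit log-likelihood and derivatives in c,
## after integrating a N(0, v) deviation; v = 0 reduces to the plain term
loglik_terms <- function(c_, y, v, gh) {
  n <- length(c_)
  l0 <- l1 <- l2 <- numeric(n)
  z <- v <= 0
  if (any(z)) {
    mu <- stats::plogis(c_[z])
    l0[z] <- ifelse(y[z] == 1, log(pmax(mu, 1e-300)),
                    log(pmax(1 - mu, 1e-300)))
    l1[z] <- y[z] - mu
    l2[z] <- -mu * (1 - mu)
  }
  if (any(!z)) {
    idx <- which(!z)
    M <- outer(sqrt(2 * v[idx]), gh$x) + c_[idx] # n x k nodes
    G <- stats::plogis(M)
    sgn <- 2 * y[idx] - 1 # row vector, recycled down columns
    B <- G
    y0 <- y[idx] == 0
    if (any(y0)) B[y0, ] <- 1 - G[y0, , drop = FALSE]
    Bp <- sgn * G * (1 - G)
    Bpp <- sgn * G * (1 - G) * (1 - 2 * G)
    w <- gh$w
    S0 <- pmax(as.numeric(B %*% w), 1e-300)
    S1 <- as.numeric(Bp %*% w)
    S2 <- as.numeric(Bpp %*% w)
    l0[idx] <- log(S0) - 0.5 * log(pi)
    l1[idx] <- S1 / S0
    l2[idx] <- S2 / S0 - (S1 / S0)^2
  }
  list(l0 = l0, l1 = l1, l2 = l2)
}

## penalised-likelihood mode over (b, l, a_parents) at fixed variances
logit_inner <- function(dsg, s2a, s2pe, beta0 = NULL, maxit = 50L) {
  bn <- dsg$bin
  Tm <- bn$Tr
  y <- dsg$y
  m <- ncol(Tm)
  v <- bn$vcoef * s2a
  Ginv <- bn$GinvPe * (1 / s2pe) +
    (if (bn$qr > 0) bn$GinvA * (1 / s2a) else bn$GinvPe * 0)
  beta <- beta0 %||% numeric(m)
  pen <- function(beta, eta) {
    sum(loglik_terms(eta, y, v, bn$gh)$l0) -
      0.5 * sum(beta * (Ginv %*% beta))
  }
  eta <- as.numeric(Tm %*% beta)
  f <- pen(beta, eta)
  for (it in seq_len(maxit)) {
    lt <- loglik_terms(eta, y, v, bn$gh)
    wt <- pmax(-lt$l2, 1e-10)
    grad <- as.numeric(Matrix::crossprod(Tm, lt$l1)) -
      as.numeric(Ginv %*% beta)
    H <- Matrix::forceSymmetric(Matrix::crossprod(Tm, Tm * wt) + Ginv)
    step <- as.numeric(Matrix::solve(H, grad))
    alpha <- 1
    repeat {
      bnew <- beta + alpha * step
      enew <- as.numeric(Tm %*% bnew)
      fnew <- pen(bnew, enew)
      if (fnew >= f - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    conv <- max(abs(grad)) < 1e-6 || abs(fnew - f) < 1e-10
    beta <- bnew
    eta <- enew
    f <- fnew
    if (conv) break
  }
  lt <- loglik_terms(eta, y, v, bn$gh)
  list(beta = beta, eta = eta, f = f, wt = pmax(-lt$l2, 1e-10),
       l1 = lt$l1, Ginv = Ginv, v = v)
}

## Laplace log marginal likelihood at fixed variances:
## l = penalised loglik at the (b, l, a_parents) mode - 0.5 log|G|
##     - 0.5 log|H_uu|
bin_laplace_ll <- function(dsg, s2a, s2pe, cacheb = NULL) {
  inner <- logit_inner(dsg, s2a, s2pe,
                       beta0 = if (!is.null(cacheb)) cacheb$beta)
  if (!is.null(cacheb)) cacheb$beta <- inner$beta
  Tu <- dsg$bin$Tr[, -seq_len(dsg$p), drop = FALSE]
  Huu <- Matrix::forceSymmetric(
    Matrix::crossprod(Tu, Tu * inner$wt) +
      inner$Ginv[-seq_len(dsg$p), -seq_len(dsg$p)])
  ch <- Matrix::Cholesky(Huu, LDL = FALSE)
  logdetH <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  logdetG <- dsg$ql * log(s2pe) + dsg$bin$qr * log(s2a) + dsg$bin$logdetAr
  inner$f - 0.5 * logdetG - 0.5 * logdetH
}

#' Laplace marginal log-likelihood of the binary animal model
#'
#' Evaluates the approximate marginal log-likelihood of the logit threshold
#' model at given liability variances, for likelihood-surface diagnostics
#' and posterior quadrature checks against [gibbs_threshold()].
#'
#' @param design a design prepared by [binary_design()].
#' @param sigma2_a,sigma2_pe liability-scale variances (> 0).
#' @return Scalar approximate log marginal likelihood.
#' @export
binary_loglik <- function(design, sigma2_a, sigma2_pe) {
  stopifnot(!is.null(design$bin), sigma2_a > 0, sigma2_pe > 0)
  bin_laplace_ll(design, sigma2_a, sigma2_pe)
}

#' Fit the binary (logit liability) animal model
#'
#' Generalised animal model `Pr(y = 1) = logistic(Xb + Pl + Za)` with
#' litter and additive variances on the logistic liability scale and
#' residual liability variance fixed at `pi^2/3`. The marginal likelihood
#' is approximated by a Laplace expansion around the joint penalised-
#' likelihood mode and maximised over `(sigma2_a, sigma2_pe)` by
#' quasi-Newton search on log-variances. [gibbs_threshold()] provides a
#' slower, simulation-based reference for the same liability model.
#'
#' @param phenotypes phenotype table whose `spec$trait` column is binary
#'   0/1 (use [recode_binary()] first for scores).
#' @param ped,spec pedigree and [model_spec()].
#' @param se compute SEs from a finite-difference information matrix.
#' @param control list: `maxit` for the outer optimiser (default 100).
#' @return Object of class `herd_vc_bin` with `components`
#'   (`sigma2_a`, `sigma2_pe`), `residual = pi^2/3`, `se`, `h2` (liability
#'   scale), `se_h2`, `loglik` (Laplace), `converged`, `separation`,
#'   `boundary`, `fixef` and liability-scale `ebv`.
#' @export
fit_binary <- function(phenotypes, ped, spec, se = TRUE, control = list()) {
  vals <- phenotypes[[spec$trait]]
  if (is.null(vals)) stop("trait column '", spec$trait, "' not found")
  obs <- vals[!is.na(vals)]
  if (!all(obs %in% c(0, 1))) {
    stop("trait ", spec$trait, " is not binary 0/1; recode it first")
  }
  if (length(unique(obs)) < 2L) {
    stop("trait ", spec$trait, " has a single response category")
  }
  dsg <- binary_design(phenotypes, ped, spec)
  cacheb <- new.env(parent = emptyenv())
  nll <- function(lpar) {
    -bin_laplace_ll(dsg, exp(lpar[1]), exp(lpar[2]), cacheb)
  }
  maxit <- control$maxit %||% 100L
  lower <- log(1e-8)
  upper <- log(1e3)
  opt <- stats::optim(log(c(0.5, 0.2)), nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit))
  theta <- exp(opt$par)
  names(theta) <- c("sigma2_a", "sigma2_pe")
  inner <- logit_inner(dsg, theta[1], theta[2], beta0 = cacheb$beta)
  boundary <- theta <= 1.1e-8
  out <- list(trait = dsg$trait, components = theta,
              residual = LOGIT_RESIDUAL_VARIANCE,
              loglik = -opt$value, converged = opt$convergence == 0,
              n_iter = unname(opt$counts[1]), boundary = boundary,
              separation = any(abs(inner$eta) > 15))
  class(out) <- "herd_vc_bin"
  if (se) {
    H <- fd_hessian(function(th) nll(log(pmax(th, 1e-10))), theta,
                    rel = 1e-3, abs = 1e-6)
    vcv <- try(solve(H), silent = TRUE)
    if (inherits(vcv, "try-error") || any(!is.finite(vcv))) {
      vcv <- matrix(NA_real_, 2, 2)
    }
    dimnames(vcv) <- list(names(theta), names(theta))
    out$vcov <- vcv
    out$se <- sqrt(pmax(diag(vcv), 0))
  } else {
    out$vcov <- matrix(NA_real_, 2, 2)
    out$se <- rep(NA_real_, 2)
  }
  tot <- sum(theta) + LOGIT_RESIDUAL_VARIANCE
  out$h2 <- unname(theta[1] / tot)
  out$se_h2 <- NA_real_
  if (!anyNA(out$vcov)) {
    g <- c((tot - theta[[1]]) / tot^2, -theta[[1]] / tot^2)
    out$se_h2 <- sqrt(max(0, drop(t(g) %*% out$vcov %*% g)))
  }
  beta <- inner$beta
  out$fixef <- stats::setNames(beta[seq_len(dsg$p)], dsg$xnames)
  out$litter_effects <- stats::setNames(beta[dsg$p + seq_len(dsg$ql)],
                                        dsg$litters)
  out$ebv <- assemble_binary_ebv(dsg, ped, inner)
  out$design <- dsg
  out
}

## breeding values for every pedigree animal: parents from the Laplace mode,
## phenotyped terminals as parent average + posterior-mean Mendelian
## deviation (E[m | y] = v * dl/dc at the mode), others as parent average
assemble_binary_ebv <- function(dsg, ped, inner) {
  bn <- dsg$bin
  n_ped <- nrow(ped)
  a <- numeric(n_ped)
  if (bn$qr > 0) {
    a[bn$retained] <- inner$beta[dsg$p + dsg$ql + seq_len(bn$qr)]
  }
  rec_of <- match(seq_len(n_ped), bn$aidx) # pedigree index -> record index
  for (i in seq_len(n_ped)) {
    if (!is.na(bn$rmap[i])) next # parent, already set
    pa <- 0
    if (ped$sire_idx[i] > 0L) pa <- pa + 0.5 * a[ped$sire_idx[i]]
    if (ped$dam_idx[i] > 0L) pa <- pa + 0.5 * a[ped$dam_idx[i]]
    r <- rec_of[i]
    a[i] <- pa + if (!is.na(r)) inner$v[r] * inner$l1[r] else 0
  }
  data.frame(animal = ped$animal, ebv = a,
             with_own_record = ped$animal %in% dsg$animal,
             stringsAsFactors = FALSE)
}

#' @export
print.herd_vc_bin <- function(x, ...) {
  cat("Threshold (logit liability) animal-model fit, trait", x$trait, "\n")
  cmp <- rbind(estimate = x$components, se = x$se)
  print(round(cmp, 4))
  cat(sprintf("residual fixed at pi^2/3 = %.2f; liability h2 = %.3f (SE %.3f)\n",
              x$residual, x$h2, x$se_h2))
  cat(sprintf("Laplace logLik = %.3f; %s\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (x$separation) cat("WARNING: possible separation (|eta| > 15)\n")
  invisible(x)
}

#' Liability-scale EBVs at fixed components
#'
#' Penalised-likelihood mode of the logit animal model at supplied
#' variance components (no re-estimation) — the binary-model counterpart of
#' [solve_mme()], used by the cross-validation machinery.
#'
#' @inheritParams fit_binary
#' @param components `c(sigma2_a, sigma2_pe)` or a `herd_vc_bin` fit.
#' @return List with `fixef`, `litter_effects` and `ebv` data.frame.
#' @export
solve_binary_mme <- function(phenotypes, ped, spec, components) {
  if (inherits(components, "herd_vc_bin")) components <- components$components
  stopifnot(length(components) == 2, all(components > 0))
  dsg <- binary_design(phenotypes, ped, spec)
  inner <- logit_inner(dsg, components[1], components[2])
  beta <- inner$beta
  list(fixef = stats::setNames(beta[seq_len(dsg$p)], dsg$xnames),
       litter_effects = stats::setNames(beta[dsg$p + seq_len(dsg$ql)],
                                        dsg$litters),
       ebv = assemble_binary_ebv(dsg, ped, inner))
}

#' Liability-scale heritability of the threshold model
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + pi^2/3)`; the residual is the
#' fixed logistic liability variance, never an estimate.
#'
#' @param sigma2_a,sigma2_pe liability-scale variances (vectorised), or a
#'   `herd_vc_bin` fit as first argument.
#' @return Numeric heritability on the liability scale.
#' @examples
#' liability_heritability(0.47, 0.11)
#' @export
liability_heritability <- function(sigma2_a, sigma2_pe = NULL) {
  if (inherits(sigma2_a, "herd_vc_bin")) {
    th <- sigma2_a$components
    return(unname(th[1] / (sum(th) + LOGIT_RESIDUAL_VARIANCE)))
  }
  stopifnot(all(sigma2_a >= 0), all(sigma2_pe >= 0))
  sigma2_a / (sigma2_a + sigma2_pe + LOGIT_RESIDUAL_VARIANCE)
}

#' Gibbs sampler for the threshold animal model (reference implementation)
#'
#' Data-augmentation sampler on a normal liability with residual variance
#' fixed at `pi^2/3`: truncated-normal liabilities given the record,
#' a joint normal block update of all location effects, and scaled
#' inverse-chi-squared updates of the two variance components under a
#' weakly-informative scaled-inverse-chi-squared prior. This is an exact MCMC for the probit-form threshold model
#' rescaled to the logistic residual variance; it serves as an independent,
#' auditable check on the Laplace logit path, from which it differs only
#' through the shape of the link (see the methods vignette).
#'
#' @inheritParams fit_binary
#' @param n_iter total sweeps (default 3000).
#' @param burnin discarded sweeps (default 1000).
#' @param seed RNG seed.
#' @param prior_df,prior_scale scaled-inverse-chi-squared prior for both
#'   variance components (default df 4, scale 1; weakly informative).
#' @return List with posterior draws (`sigma2_a`, `sigma2_pe`, `h2`), their
#'   posterior means `estimate`, `h2_se` (posterior SD of h2) and `h2_mcse`
#'   (batch-means Monte-Carlo standard error of the h2 posterior mean).
#' @export
gibbs_threshold <- function(phenotypes, ped, spec, n_iter = 3000L,
                            burnin = 1000L, seed = 1L, prior_df = 4,
                            prior_scale = 1) {
  dsg <- reml_design(phenotypes, ped, spec)
  y <- dsg$y
  if (!all(y %in% c(0, 1))) stop("trait must be binary 0/1")
  set.seed(seed)
  Td <- as.matrix(dsg$Tm)
  m <- ncol(Td)
  n <- nrow(Td)
  s2e <- LOGIT_RESIDUAL_VARIANCE
  sde <- sqrt(s2e)
  TtT <- crossprod(Td)
  Ainv_d <- as.matrix(dsg$Da[dsg$p + dsg$ql + seq_len(dsg$qa),
                             dsg$p + dsg$ql + seq_len(dsg$qa)])
  idx_pe <- dsg$p + seq_len(dsg$ql)
  idx_a <- dsg$p + dsg$ql + seq_len(dsg$qa)
  beta <- numeric(m)
  s2a <- 0.5
  s2pe <- 0.2
  keep <- n_iter - burnin
  draws <- matrix(NA_real_, keep, 2, dimnames = list(NULL, c("sigma2_a", "sigma2_pe")))
  eta <- as.numeric(Td %*% beta)
  for (it in seq_len(n_iter)) {
    ## liabilities: truncated normal via inverse CDF
    plo <- stats::pnorm(0, eta, sde)
    u <- stats::runif(n)
    pz <- ifelse(y == 1, plo + u * (1 - plo), u * plo)
    pz <- pmin(pmax(pz, 1e-12), 1 - 1e-12)
    z <- stats::qnorm(pz, eta, sde)
    ## joint location update
    Cmat <- TtT / s2e
    diag(Cmat)[idx_pe] <- diag(Cmat)[idx_pe] + 1 / s2pe
    Cmat[idx_a, idx_a] <- Cmat[idx_a, idx_a] + Ainv_d / s2a
    R <- chol(Cmat)
    mu <- backsolve(R, backsolve(R, crossprod(Td, z) / s2e,
                                 transpose = TRUE))
    beta <- drop(mu + backsolve(R, stats::rnorm(m)))
    eta <- as.numeric(Td %*% beta)
    ## variances: scaled inverse chi-square (flat scale prior)
    a <- beta[idx_a]
    l <- beta[idx_pe]
    s2a <- max((drop(crossprod(a, Ainv_d %*% a)) + prior_df * prior_scale) /
                 stats::rchisq(1, df = dsg$qa + prior_df), 1e-8)
    s2pe <- max((sum(l^2) + prior_df * prior_scale) /
                  stats::rchisq(1, df = dsg$ql + prior_df), 1e-8)
    if (it > burnin) draws[it - burnin, ] <- c(s2a, s2pe)
  }
  h2 <- draws[, 1] / (rowSums(draws) + s2e)
  nb <- 20L
  bsz <- ceiling(length(h2) / nb)
  bm <- tapply(h2, rep(seq_len(nb), each = bsz)[seq_along(h2)], mean)
  list(sigma2_a = draws[, 1], sigma2_pe = draws[, 2], h2 = h2,
       estimate = c(sigma2_a = mean(draws[, 1]),
                    sigma2_pe = mean(draws[, 2]), h2 = mean(h2)),
       h2_se = stats::sd(h2),
       h2_mcse = stats::sd(bm) / sqrt(nb))
}
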