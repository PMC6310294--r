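#' Simulation configuration for a synthetic fattening-pig herd
#'
#' The defaults emulate the structure of a commercial herd of roughly one
#' thousand fattening pigs descended from 31 boars and 135 sows, with one
#' grandparental layer above the parents. Litter sizes are Poisson around
#' `litter_size_mean` (the sampled-litter-size distribution is an
#' assumption; see the methods vignette).
#'
#' @param n_sires,n_dams numbers of founder sires and dams (parents of the
#'   phenotyped generation).
#' @param litters_per_dam litters per dam (each litter gets a fresh random
#'   sire).
#' @param litter_size_mean mean Poisson litter size; the default
#'   `1004/135` targets about 1004 offspring.
#' @param generation_depth number of ancestral layers above the parents
#'   (0 = parents are founders; 1 adds a grandparental layer).
#' @param n_gsires,n_gdams size of the grandparental pool when
#'   `generation_depth >= 1`.
#' @param seed integer seed; the whole generation chain is reproducible.
#' @param traits named list of [trait_sim_spec()] blocks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 31L, n_dams = 135L, litters_per_dam = 1L,
                       litter_size_mean = 1004 / 135, generation_depth = 1L,
                       n_gsires = 2L * n_sires, n_gdams = 2L * n_dams,
                       seed = 1L, traits = list()) {
  stopifnot(n_sires >= 1, n_dams >= 1, litters_per_dam >= 1,
            litter_size_mean > 0, generation_depth >= 0)
  if (n_dams * litters_per_dam < 1) stop("no matings configured")
  cfg <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              litters_per_dam = as.integer(litters_per_dam),
              litter_size_mean = litter_size_mean,
              generation_depth = as.integer(generation_depth),
              n_gsires = as.integer(n_gsires), n_gdams = as.integer(n_gdams),
              seed = as.integer(seed), traits = traits)
  class(cfg) <- "sim_config"
  cfg
}

#' Per-trait simulation specification
#'
#' A trait is generated on a Gaussian liability
#' `y* = mu + fixed effects + litter + a + e` with additive genetic values
#' propagated down the pedigree (founders `N(0, sigma2_a)`, non-founders
#' parent average plus Mendelian sampling with variance
#' `d_i * sigma2_a`, `d_i` accounting for parental inbreeding), a litter
#' effect shared by littermates, and i.i.d. residuals. Ordinal scores and
#' escape-attempt counts are obtained by thresholding the liability;
#' Gaussian traits report the liability itself.
#'
#' @param mu trait mean (trait units).
#' @param sigma2_a,sigma2_le,sigma2_e additive-genetic, common-litter and
#'   residual variances (trait units squared).
#' @param score_type `"gaussian"`, `"ordinal"` or `"count"`.
#' @param support integer vector of admissible values for ordinal/count
#'   traits (e.g. `1:3` for a scale score, `0:9` for backtest counts).
#' @param target_mean,target_sd observed-scale mean/SD the discretised
#'   scores should match; thresholds are placed with
#'   [thresholds_for_moments()]. Ignored for Gaussian traits.
#' @param thresholds optional explicit strictly increasing latent
#'   cut-points, overriding the moment matching.
#' @param fixed_effects named list of per-level effect sizes (first level is
#'   the reference, effects are added for levels 2+) for any of `sex`,
#'   `breed`, `rearing`, `finishing`, `familiar`.
#' @param missing_rate per-trait probability that a phenotype is masked.
#' @param residual residual distribution of the liability: `"gaussian"`
#'   (default) or `"logistic"` (scaled to variance `sigma2_e`), the latter
#'   for studies of the logit threshold model.
#' @return A list of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(mu, sigma2_a, sigma2_le, sigma2_e,
                           score_type = c("gaussian", "ordinal", "count"),
                           support = NULL, target_mean = NULL,
                           target_sd = NULL, thresholds = NULL,
                           fixed_effects = list(), missing_rate = 0,
                           residual = c("gaussian", "logistic")) {
  score_type <- match.arg(score_type)
  residual <- match.arg(residual)
  stopifnot(sigma2_a >= 0, sigma2_le >= 0, sigma2_e >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (score_type != "gaussian") {
    if (is.null(support)) stop("ordinal/count traits need a support")
    support <- as.integer(support)
    if (is.null(thresholds)) {
      if (is.null(target_mean) || is.null(target_sd)) {
        stop("either thresholds or target moments must be given")
      }
    } else if (is.unsorted(thresholds, strictly = TRUE)) {
      stop("thresholds must be strictly increasing")
    }
  }
  spec <- list(mu = mu, sigma2_a = sigma2_a, sigma2_le = sigma2_le,
               sigma2_e = sigma2_e, score_type = score_type,
               support = support, target_mean = target_mean,
               target_sd = target_sd, thresholds = thresholds,
               fixed_effects = fixed_effects, missing_rate = missing_rate,
               residual = residual)
  class(spec) <- "trait_sim_spec"
  spec
}

#' Simulate a pedigree
#'
#' Founder sires and dams (optionally with a grandparental layer), random
#' sire-dam matings, Poisson litter sizes. Offspring litters are labelled
#' `L<dam>.<parity>`; the litter map is attached as attribute
#' `"litter"` (NA for non-offspring).
#'
#' @param config a [sim_config()].
#' @return A validated [validate_pedigree()] pedigree with attributes
#'   `litter` (character) and `is_offspring` (logical), both in pedigree
#'   order.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_pedigree_impl(config)
}

sim_pedigree_impl <- function(config) {
  gs <- gd <- character(0)
  if (config$generation_depth >= 1L) {
    gs <- sprintf("GS%03d", seq_len(config$n_gsires))
    gd <- sprintf("GD%03d", seq_len(config$n_gdams))
  }
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%03d", seq_len(config$n_dams))
  par_sire <- par_dam <- rep(NA_character_, length(sires) + length(dams))
  if (config$generation_depth >= 1L) {
    np <- length(par_sire)
    par_sire <- sample(gs, np, replace = TRUE)
    par_dam <- sample(gd, np, replace = TRUE)
  }
  animal <- c(gs, gd, sires, dams)
  sire <- c(rep(NA_character_, length(gs) + length(gd)), par_sire)
  dam <- c(rep(NA_character_, length(gs) + length(gd)), par_dam)
  litter <- rep(NA_character_, length(animal))
  kid <- 0L
  for (p in seq_len(config$litters_per_dam)) {
    mate <- sample(sires, config$n_dams, replace = TRUE)
    sizes <- stats::rpois(config$n_dams, config$litter_size_mean)
    for (j in seq_len(config$n_dams)) {
      if (sizes[j] == 0L) next
      ids <- sprintf("P%05d", kid + seq_len(sizes[j]))
      kid <- kid + sizes[j]
      animal <- c(animal, ids)
      sire <- c(sire, rep(mate[j], sizes[j]))
      dam <- c(dam, rep(dams[j], sizes[j]))
      litter <- c(litter, rep(sprintf("L%s.%d", dams[j], p), sizes[j]))
    }
  }
  if (kid == 0L) stop("no offspring generated; increase litter_size_mean")
  ped <- validate_pedigree(animal, sire, dam)
  ord <- match(ped$animal, animal)
  attr(ped, "litter") <- litter[ord]
  attr(ped, "is_offspring") <- !is.na(litter[ord])
  ped
}

## Multi-trait additive genetic values down a sorted pedigree.
## Ga is a k x k additive (co)variance matrix; returns n x k matrix.
simulate_genetic_values <- function(ped, Ga) {
  assert_pedigree(ped)
  Ga <- as.matrix(Ga)
  k <- ncol(Ga)
  n <- nrow(ped)
  L <- chol_psd(Ga)
  dvar <- mendelian_variance(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  a <- matrix(0, n, k)
  z <- matrix(stats::rnorm(n * k), n, k) %*% L
  for (i in seq_len(n)) {
    pa <- 0
    if (s[i] > 0L) pa <- pa + 0.5 * a[s[i], ]
    if (d[i] > 0L) pa <- pa + 0.5 * a[d[i], ]
    a[i, ] <- pa + sqrt(dvar[i]) * z[i, ]
  }
  rownames(a) <- ped$animal
  a
}

## upper-triangular factor tolerating semidefinite (zero-variance) matrices
chol_psd <- function(M) {
  M <- as.matrix(M)
  e <- eigen(M, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Simulate latent liabilities for one trait
#'
#' @param ped sorted pedigree (with `litter` attribute or an explicit
#'   `litter` vector).
#' @param spec a [trait_sim_spec()].
#' @param factors data.frame of fixed-effect class assignments in pedigree
#'   order (see [assign_factors()]); may be `NULL` when the spec has no
#'   fixed effects.
#' @param litter litter identifier per animal (NA = no litter effect).
#' @param seed optional seed (omit to continue the current RNG stream).
#' @return Numeric vector of liabilities in pedigree order.
#' @export
simulate_liabilities <- function(ped, spec, factors = NULL,
                                 litter = attr(ped, "litter"), seed = NULL) {
  assert_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  a <- drop(simulate_genetic_values(ped, matrix(spec$sigma2_a, 1, 1)))
  le <- numeric(n)
  if (!is.null(litter) && spec$sigma2_le > 0) {
    lev <- unique(litter[!is.na(litter)])
    eff <- stats::rnorm(length(lev), 0, sqrt(spec$sigma2_le))
    idx <- match(litter, lev)
    le <- ifelse(is.na(idx), 0, eff[idx])
  }
  fx <- fixed_effect_values(spec$fixed_effects, factors, n)
  spec$mu + fx + le + a + residual_draw(spec, n)
}

residual_draw <- function(spec, n) {
  if (identical(spec$residual, "logistic")) {
    stats::rlogis(n, 0, sqrt(3 * spec$sigma2_e) / pi)
  } else {
    stats::rnorm(n, 0, sqrt(spec$sigma2_e))
  }
}

fixed_effect_values <- function(fixed_effects, factors, n) {
  fx <- numeric(n)
  for (nm in names(fixed_effects)) {
    if (is.null(factors) || is.null(factors[[nm]])) {
      stop("fixed effect '", nm, "' has no factor assignment")
    }
    lev <- sort(unique(as.character(factors[[nm]])))
    eff <- fixed_effects[[nm]]
    if (length(eff) != length(lev)) {
      stop("fixed effect '", nm, "' needs ", length(lev), " level effects")
    }
    fx <- fx + eff[match(as.character(factors[[nm]]), lev)]
  }
  fx
}

#' Assign fixed-effect classes
#'
#' Sex is assigned per animal (1:1); breed, rearing housing (3 classes),
#' finishing housing (2 classes) and unfamiliar-pig class (4 classes) are
#' assigned at the litter level, mirroring a design in which housing is a
#' group-level treatment. Non-offspring animals get NA classes.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param seed optional seed.
#' @param p_crossbred probability that a litter belongs to the crossbred
#'   line (default 814/1004).
#' @return data.frame with columns `sex`, `breed`, `rearing`, `finishing`,
#'   `familiar` in pedigree order.
#' @export
assign_factors <- function(ped, seed = NULL, p_crossbred = 814 / 1004) {
  assert_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  litter <- attr(ped, "litter")
  n <- nrow(ped)
  off <- !is.na(litter)
  lev <- unique(litter[off])
  nl <- length(lev)
  litter_pick <- function(values, probs = NULL) {
    by_litter <- sample(values, nl, replace = TRUE, prob = probs)
    out <- rep(NA_character_, n)
    out[off] <- by_litter[match(litter[off], lev)]
    out
  }
  sex <- rep(NA_character_, n)
  sex[off] <- sample(c("barrow", "gilt"), sum(off), replace = TRUE)
  data.frame(
    sex = sex,
    breed = litter_pick(c("cross", "pure"), c(p_crossbred, 1 - p_crossbred)),
    rearing = litter_pick(c("R1", "R2", "R3")),
    finishing = litter_pick(c("F1", "F2")),
    familiar = litter_pick(c("U0", "U1", "U2", "U3")),
    stringsAsFactors = FALSE
  )
}

#' Latent thresholds matching observed-scale moments
#'
#' Places cut-points on a `N(mu, sigma2)` liability so that the discretised
#' trait has (approximately) a target mean and SD on its integer support.
#' Category probabilities come from a discretised-normal family whose two
#' parameters are fitted to the target moments, then mapped to liability
#' quantiles.
#'
#' @param support integer support (ordered).
#' @param target_mean,target_sd target observed-scale moments.
#' @param mu,sigma2 liability mean and total variance.
#' @return Strictly increasing numeric vector of `length(support) - 1`
#'   thresholds.
#' @export
thresholds_for_moments <- function(support, target_mean, target_sd, mu, sigma2) {
  support <- as.integer(support)
  k <- length(support)
  if (k < 2L) return(numeric(0))
  probs_of <- function(m, s) {
    cuts <- c(-Inf, support[-k] + 0.5, Inf)
    p <- diff(stats::pnorm(cuts, m, s))
    p / sum(p)
  }
  obj <- function(par) {
    p <- probs_of(par[1], exp(par[2]))
    mean_ <- sum(p * support)
    sd_ <- sqrt(sum(p * (support - mean_)^2))
    (mean_ - target_mean)^2 + (sd_ - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(max(target_sd, 1e-3))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- probs_of(fit$par[1], exp(fit$par[2]))
  cum <- cumsum(p)[-k]
  cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
  thr <- stats::qnorm(cum, mean = mu, sd = sqrt(sigma2))
  ## enforce strict monotonicity against degenerate tails
  for (i in seq_along(thr)[-1]) {
    if (thr[i] <= thr[i - 1]) thr[i] <- thr[i - 1] + 1e-9
  }
  thr
}

#' Discretise liabilities into ordinal scores or counts
#'
#' Monotone step function: a liability below the first threshold maps to
#' `support[1]`, and so on. With `thresholds = numeric(0)` all values fall
#' in the single category `support[1]`.
#'
#' @param latent numeric liabilities.
#' @param thresholds strictly increasing cut-points.
#' @param support category values, `length(thresholds) + 1`.
#' @return Vector of `support` values, same length as `latent`.
#' @export
discretize <- function(latent, thresholds, support = seq_len(length(thresholds) + 1L)) {
  if (length(thresholds) &&
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  if (length(support) != length(thresholds) + 1L) {
    stop("support must have length(thresholds) + 1 values")
  }
  idx <- findInterval(latent, thresholds) + 1L
  out <- support[idx]
  out[is.na(latent)] <- NA
  out
}

#' Mask phenotypes at random
#'
#' Independent per-trait Bernoulli masking; masked cells become `NA`.
#'
#' @param phenotypes data.frame with trait columns.
#' @param rates named vector/list of per-trait missing rates in `[0, 1)`.
#' @param seed optional seed.
#' @return The phenotype table with masked cells set to `NA`.
#' @export
apply_missingness <- function(phenotypes, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    stopifnot(r >= 0, r < 1)
    if (r == 0 || is.null(phenotypes[[nm]])) next
    mask <- stats::runif(nrow(phenotypes)) < r
    phenotypes[[nm]][mask] <- NA
  }
  phenotypes
}

#' Simulate a complete herd
#'
#' Runs the whole chain — pedigree, factor assignment, per-trait
#' liabilities, discretisation, missingness — under a single seed, so a
#' given configuration is byte-reproducible.
#'
#' @param config a [sim_config()] with at least one trait.
#' @return A list of class `sim_herd` with elements `pedigree`,
#'   `phenotypes` (one row per offspring: `animal`, `litter`, the five
#'   factor columns, then one column per trait) and `truth` (per-trait list
#'   with the simulated breeding values and liabilities, for validation
#'   studies).
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$traits)) stop("config contains no traits")
  set.seed(config$seed)
  ped <- sim_pedigree_impl(config)
  factors <- assign_factors(ped)
  litter <- attr(ped, "litter")
  off <- which(attr(ped, "is_offspring"))
  phen <- data.frame(animal = ped$animal[off], litter = litter[off],
                     factors[off, , drop = FALSE], stringsAsFactors = FALSE)
  rownames(phen) <- NULL
  truth <- list()
  for (nm in names(config$traits)) {
    spec <- config$traits[[nm]]
    a <- drop(simulate_genetic_values(ped, matrix(spec$sigma2_a, 1, 1)))
    le <- numeric(nrow(ped))
    if (spec$sigma2_le > 0) {
      lev <- unique(litter[!is.na(litter)])
      eff <- stats::rnorm(length(lev), 0, sqrt(spec$sigma2_le))
      idx <- match(litter, lev)
      le <- ifelse(is.na(idx), 0, eff[idx])
    }
    fx <- fixed_effect_values(spec$fixed_effects, factors, nrow(ped))
    liab <- spec$mu + fx + le + a + residual_draw(spec, nrow(ped))
    obs <- liab[off]
    if (spec$score_type != "gaussian") {
      thr <- spec$thresholds
      if (is.null(thr)) {
        tot <- spec$sigma2_a + spec$sigma2_le + spec$sigma2_e
        thr <- thresholds_for_moments(spec$support, spec$target_mean,
                                      spec$target_sd, spec$mu, tot)
      }
      obs <- discretize(obs, thr, spec$support)
    }
    phen[[nm]] <- obs
    truth[[nm]] <- list(breeding_values = a, liability = liab)
    if (spec$missing_rate > 0) {
      mask <- stats::runif(nrow(phen)) < spec$missing_rate
      phen[[nm]][mask] <- NA
    }
  }
  out <- list(pedigree = ped, phenotypes = phen, truth = truth,
              config = config)
  class(out) <- "sim_herd"
  out
}

#' Simulate a genetically correlated trait pair
#'
#' Shares the machinery of [simulate_herd()] but draws additive, litter and
#' residual effects from 2x2 covariance matrices, for parameter-recovery
#' studies of the bivariate model.
#'
#' @param config a [sim_config()] (its `traits` entry is ignored).
#' @param spec1,spec2 [trait_sim_spec()] for the two traits.
#' @param r_g,r_le,r_e additive-genetic, litter and residual correlations.
#' @return A `sim_herd` whose phenotype table has columns `t1`, `t2`.
#' @export
simulate_trait_pair <- function(config, spec1, spec2, r_g, r_le = 0, r_e = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- sim_pedigree_impl(config)
  factors <- assign_factors(ped)
  litter <- attr(ped, "litter")
  off <- which(attr(ped, "is_offspring"))
  cov2 <- function(v1, v2, r) {
    matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
  }
  Ga <- cov2(spec1$sigma2_a, spec2$sigma2_a, r_g)
  Gle <- cov2(spec1$sigma2_le, spec2$sigma2_le, r_le)
  Re <- cov2(spec1$sigma2_e, spec2$sigma2_e, r_e)
  a <- simulate_genetic_values(ped, Ga)
  lev <- unique(litter[!is.na(litter)])
  leff <- matrix(stats::rnorm(2 * length(lev)), ncol = 2) %*% chol_psd(Gle)
  idx <- match(litter, lev)
  le <- matrix(0, nrow(ped), 2)
  le[!is.na(idx), ] <- leff[idx[!is.na(idx)], ]
  e <- matrix(stats::rnorm(2 * nrow(ped)), ncol = 2) %*% chol_psd(Re)
  mk <- function(j, spec) {
    fx <- fixed_effect_values(spec$fixed_effects, factors, nrow(ped))
    liab <- spec$mu + fx + le[, j] + a[, j] + e[, j]
    obs <- liab[off]
    if (spec$score_type != "gaussian") {
      thr <- spec$thresholds
      if (is.null(thr)) {
        tot <- spec$sigma2_a + spec$sigma2_le + spec$sigma2_e
        thr <- thresholds_for_moments(spec$support, spec$target_mean,
                                      spec$target_sd, spec$mu, tot)
      }
      obs <- discretize(obs, thr, spec$support)
    }
    obs
  }
  phen <- data.frame(animal = ped$animal[off], litter = litter[off],
                     factors[off, , drop = FALSE],
                     t1 = mk(1, spec1), t2 = mk(2, spec2),
                     stringsAsFactors = FALSE)
  rownames(phen) <- NULL
  out <- list(pedigree = ped, phenotypes = phen,
              truth = list(t1 = list(breeding_values = a[, 1]),
                           t2 = list(breeding_values = a[, 2])),
              config = config)
  class(out) <- "sim_herd"
  out
}

#' Trait presets for the emulated study herd
#'
#' Named [trait_sim_spec()] blocks for the fourteen behaviour and growth
#' traits of the emulated population: backtest escape-attempt counts (BT1,
#' BT2, support 0-9), handling/weighing scores 1-3 (PSS, RLS, RSS, FLS,
#' FSS), injection and skin-lesion scores 1-4 (INJ, LS1, LS2), and daily
#' gains in g/day (PDG, RDG, FDG, ADG). Variance components, observed
#' moments and per-trait record counts follow the linear-model summaries of
#' the emulated study; missing rates are `1 - n_trait/1004`.
#'
#' @return Named list of `trait_sim_spec` objects.
#' @export
study_traits <- function() {
  miss <- function(n) 1 - n / 1004
  fx <- list() # preset effect sizes are zero; housing contrasts can be added
  list(
    BT1 = trait_sim_spec(2.4, 0.32, 0.12, 1.04, "count", support = 0:9,
                         target_mean = 2.4, target_sd = 1.2,
                         fixed_effects = fx, missing_rate = miss(1004)),
    BT2 = trait_sim_spec(2.5, 0.52, 0.08, 0.87, "count", support = 0:9,
                         target_mean = 2.5, target_sd = 1.2,
                         fixed_effects = fx, missing_rate = miss(769)),
    INJ = trait_sim_spec(2.8, 0.03, 0.13, 0.34, "ordinal", support = 1:4,
                         target_mean = 2.8, target_sd = 0.8,
                         fixed_effects = fx, missing_rate = miss(769)),
    PSS = trait_sim_spec(2.0, 0.04, 0.13, 0.46, "ordinal", support = 1:3,
                         target_mean = 2.0, target_sd = 0.8,
                         fixed_effects = fx, missing_rate = miss(874)),
    RLS = trait_sim_spec(1.8, 0.05, 0.04, 0.55, "ordinal", support = 1:3,
                         target_mean = 1.8, target_sd = 0.8,
                         fixed_effects = fx, missing_rate = miss(987)),
    RSS = trait_sim_spec(2.0, 0.07, 0.02, 0.48, "ordinal", support = 1:3,
                         target_mean = 2.0, target_sd = 0.8,
                         fixed_effects = fx, missing_rate = miss(987)),
    FLS = trait_sim_spec(1.5, 0.02, 0.00, 0.44, "ordinal", support = 1:3,
                         target_mean = 1.5, target_sd = 0.7,
                         fixed_effects = fx, missing_rate = miss(976)),
    FSS = trait_sim_spec(1.5, 0.09, 0.00, 0.33, "ordinal", support = 1:3,
                         target_mean = 1.5, target_sd = 0.7,
                         fixed_effects = fx, missing_rate = miss(976)),
    LS1 = trait_sim_spec(2.3, 0.08, 0.05, 0.43, "ordinal", support = 1:4,
                         target_mean = 2.3, target_sd = 0.8,
                         fixed_effects = fx, missing_rate = miss(1004)),
    LS2 = trait_sim_spec(2.9, 0.07, 0.09, 0.45, "ordinal", support = 1:4,
                         target_mean = 2.9, target_sd = 0.9,
                         fixed_effects = fx, missing_rate = miss(987)),
    PDG = trait_sim_spec(224, 112.1, 1120.8, 1686.8, "gaussian",
                         fixed_effects = fx, missing_rate = miss(996)),
    RDG = trait_sim_spec(413, 79.5, 1078.8, 1717.6, "gaussian",
                         fixed_effects = fx, missing_rate = miss(777)),
    FDG = trait_sim_spec(760, 5707.2, 1234.3, 2859.2, "gaussian",
                         fixed_effects = fx, missing_rate = miss(603)),
    ADG = trait_sim_spec(600, 1228.5, 313.5, 1010.8, "gaussian",
                         fixed_effects = fx, missing_rate = miss(603))
  )
}

#' Read or write a phenotype file
#'
#' Delimited text with header `animal,litter,sex,breed,rearing,finishing,
#' familiar,<traits...>`; missing values are empty fields. Comma or tab is
#' auto-detected on read.
#'
#' @param path file path.
#' @return `read_phenotypes()` returns a data.frame;
#'   `write_phenotypes()` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  if (!all(c("animal", "litter") %in% names(out))) {
    stop("phenotype file must have columns animal and litter")
  }
  out$animal <- as.character(out$animal)
  out$litter <- as.character(out$litter)
  out
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame to write.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_phenotypes <- function(phenotypes, path, sep = ",") {
  utils::write.table(phenotypes, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
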