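#' Random k-fold partition of animals
#'
#' Balanced to within one animal, reproducible under the seed.
#'
#' @param animal_ids identifiers of phenotyped animals.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold labels `1..k` named by animal id.
#' @export
make_folds <- function(animal_ids, k, seed = 1L) {
  n <- length(animal_ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of animals (", n, ")")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  stats::setNames(fold, animal_ids)
}

#' Cross-validation plan
#'
#' @param trait trait to cross-validate.
#' @param k folds (default 4).
#' @param repeats number of whole-procedure repeats (default 5).
#' @param models subset of `c("gaussian", "logit")`.
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @param scheme optional [recoding_scheme()] for the logit model; defaults
#'   to the study preset when available, else a median split.
#' @param refit_components re-estimate variance components on every
#'   training split (`TRUE`) or estimate once on the full data and hold
#'   fixed (`FALSE`, default).
#' @return List of class `crossval_plan`.
#' @export
crossval_plan <- function(trait, k = 4L, repeats = 5L,
                          models = c("gaussian", "logit"), seed = 1L,
                          scheme = NULL, refit_components = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(trait = trait, k = as.integer(k),
                 repeats = as.integer(repeats), models = models,
                 seed = as.integer(seed), scheme = scheme,
                 refit_components = isTRUE(refit_components)),
            class = "crossval_plan")
}

#' Cross-validated predictive ability of estimated breeding values
#'
#' For each repeat, phenotyped animals are split into `k` folds. Breeding
#' values are first estimated from all records; then, fold by fold, the
#' fold's phenotypes are masked (the animals stay in the pedigree, so
#' their EBVs are predicted from relatives) and the model is re-solved.
#' The Pearson correlation between full-data and masked EBVs over the
#' fold's animals measures how much the model can recover about an
#' animal's breeding value without its own record. Results are aggregated
#' as mean +/- SD over all repeat-by-fold correlations per model. A fold
#' whose masked fit fails is recorded as `NA` with a warning and excluded
#' from the summary.
#'
#' @param phenotypes,ped data and pedigree.
#' @param plan a [crossval_plan()].
#' @param spec optional [model_spec()]; defaults to the study preset for
#'   the plan's trait.
#' @return Object of class `crossval_result`: data.frame `folds` (model,
#'   repeat, fold, r) and data.frame `summary` (model, mean_r, sd_r,
#'   n_folds), plus the fitted full-data components per model.
#' @export
run_crossval <- function(phenotypes, ped, plan, spec = NULL) {
  stopifnot(inherits(plan, "crossval_plan"))
  assert_pedigree(ped)
  spec <- spec %||% model_spec(plan$trait)
  if (is.null(phenotypes[[plan$trait]])) {
    stop("trait column '", plan$trait, "' not found in phenotype table")
  }
  rows <- list()
  components <- list()
  for (model in plan$models) {
    dat <- phenotypes
    if (model == "logit") {
      vals <- dat[[plan$trait]]
      if (!all(stats::na.omit(vals) %in% c(0, 1))) {
        scheme <- plan$scheme %||% tryCatch(study_recoding(plan$trait),
                                            error = function(e) median_split(vals))
        dat[[plan$trait]] <- recode_binary(vals, scheme, plan$trait)
      }
      full <- fit_binary(dat, ped, spec, se = FALSE)
    } else {
      full <- fit_univariate(dat, ped, spec, se = FALSE)
    }
    components[[model]] <- full$components
    ebv_full <- stats::setNames(full$ebv$ebv, full$ebv$animal)
    phen_ids <- dat$animal[!is.na(dat[[plan$trait]])]
    for (r in seq_len(plan$repeats)) {
      folds <- make_folds(phen_ids, plan$k, seed = plan$seed + r)
      for (f in seq_len(plan$k)) {
        fold_ids <- names(folds)[folds == f]
        train <- dat
        train[[plan$trait]][train$animal %in% fold_ids] <- NA
        cv <- tryCatch({
          if (plan$refit_components) {
            refit <- if (model == "logit") {
              fit_binary(train, ped, spec, se = FALSE)
            } else {
              fit_univariate(train, ped, spec, se = FALSE)
            }
            refit$ebv
          } else if (model == "logit") {
            solve_binary_mme(train, ped, spec, full$components)$ebv
          } else {
            solve_mme(train, ped, spec, full$components)$ebv
          }
        }, error = function(e) {
          warning("fold ", f, " (repeat ", r, ", ", model,
                  ") failed: ", conditionMessage(e))
          NULL
        })
        rho <- NA_real_
        if (!is.null(cv)) {
          ebv_cv <- stats::setNames(cv$ebv, cv$animal)
          ## masking never removes animals from the pedigree
          stopifnot(all(fold_ids %in% cv$animal))
          rho <- stats::cor(ebv_full[fold_ids], ebv_cv[fold_ids])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, rep = r, fold = f, r = rho,
          stringsAsFactors = FALSE)
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(folds_df, folds_df$model), function(d) {
    data.frame(model = d$model[1], mean_r = mean(d$r, na.rm = TRUE),
               sd_r = stats::sd(d$r, na.rm = TRUE),
               n_folds = sum(!is.na(d$r)), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  out <- list(folds = folds_df, summary = summ, components = components,
              plan = plan)
  class(out) <- "crossval_result"
  out
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Cross-validated EBV correlations, trait", x$plan$trait,
      sprintf("(k = %d, %d repeats)\n", x$plan$k, x$plan$repeats))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s r = %.3f +/- %.3f over %d folds\n",
                x$summary$model[i], x$summary$mean_r[i], x$summary$sd_r[i],
                x$summary$n_folds[i]))
  }
  invisible(x)
}
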