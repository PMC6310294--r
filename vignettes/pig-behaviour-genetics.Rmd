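---
title: "Animal-model genetics of pig behaviour traits: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Animal-model genetics of pig behaviour traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigherit)
```

`pigherit` estimates genetic parameters for behaviour and growth traits
recorded on commercial fattening-pig herds: escape attempts during the
backtest, handling and weighing scores, skin-lesion scores around mixing,
and daily weight gains. This vignette is the package's own account of the
models it fits, the algorithms behind them, the synthetic herd generator
used to validate everything, and the design choices that were genuinely
open.

## The model

For a phenotype vector $y$ the package fits the animal model

$$ y = Xb + Pl + Za + e $$

with fixed classification effects $b$ (any of sex, genetic line,
rearing-housing class, finishing-housing class, and the number of
unfamiliar pigs at mixing), a random common-litter (permanent
environmental) effect $l \sim N(0, I\sigma^2_{pe})$, a random additive
genetic effect with one level per pedigree animal,
$a \sim N(0, A\sigma^2_a)$, where $A$ is the numerator relationship
matrix, and residual $e \sim N(0, I\sigma^2_e)$. The common-litter effect
absorbs the non-genetic resemblance of littermates (shared uterus, sow,
creep area); omitting it would inflate $\sigma^2_a$ because full sibs are
also littermates. Heritability is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$.

Per production stage the preset fixed-effect sets are: preweaning traits,
sex + line; rearing traits, + rearing housing; post-mixing lesion traits,
+ unfamiliar-pig class; finishing traits, sex + line + finishing housing;
lifetime gain, sex + line + both housing factors (`study_fixed()`).

Bivariate fits stack two traits with 2×2 additive, litter and residual
(co)variance matrices; the residual covariance is estimated only when some
animals carry records for both traits and is fixed at zero otherwise
(identifiability). The genetic correlation is
$r_g = \mathrm{cov}_a / \sqrt{\sigma^2_{a,1}\sigma^2_{a,2}}$ and the
phenotypic correlation sums all three components. When either additive
variance converges to the boundary, correlations are flagged unreliable
but still reported.

## Pedigree algebra

`relationship_matrix()` uses the tabular method; `relationship_inverse()`
assembles $A^{-1}$ directly from Henderson's rules with full accounting
for parental inbreeding via the Mendelian-sampling variance ratios
$d_i = \tfrac12 - \tfrac14(F_s + F_d)$ (suitably modified for unknown
parents), which also yield $\log\det A = \sum_i \log d_i$ for the
likelihood. Inbreeding coefficients are computed from a tabular
relationship matrix restricted to the ancestor sub-pedigree, so the
quadratic cost is paid only in the number of parents. Unknown parents
(empty field or `0` in pedigree files) are base-population founders.
Pedigree order is a deterministic topological sort with ties broken by
input order, so matrix indexing is reproducible.

## REML

The restricted likelihood is evaluated exactly through the sparse
mixed-model equations (the identity
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$, with $C$ the
full MME coefficient matrix), which costs one sparse Cholesky
factorisation per evaluation — a few milliseconds at the default herd
size of about 1,000 records and 1,500 pedigree animals. The maximiser is
a quasi-Newton (L-BFGS-B) search on log-variances. This was a deliberate
choice over an average-information update loop: the stationary point is
identical, there are no hand-derived trace identities to get wrong, and
the evaluator is verified in the test suite against an independent
dense-$V$ implementation (agreement to ~1e-12) and against likelihood
grids around every converged fit. Convergence uses the optimiser's
default relative-improvement criterion with a 200-evaluation cap;
non-convergence is flagged on the result, not thrown.

Variances are kept positive by the log parameterisation and bounded below
at $10^{-8}$ times the phenotypic variance; an estimate within 10% of
that floor carries a `boundary` flag, so zero-variance rows remain
representable in reports. Standard errors come from the inverse of a
central finite-difference information matrix on the variance scale, and
the SE of $h^2$ (and of correlations) by the first-order delta method.
Identifiability of fixed effects uses treatment contrasts (first level
zero); any full-rank constraint gives the same REML components, and
aliased factors are reported by name as errors.

BLUP solutions at the converged (or user-supplied) components come from
the same equations (`solve_mme()`); the solver asserts a relative residual
below 1e-8. Every pedigree animal gets an EBV, with `with_own_record`
recording whether its own phenotype contributed.

## The threshold (logit liability) model

Binary scores are modelled as
$\Pr(y=1) = \mathrm{logistic}(Xb + Pl + Za)$ with the residual liability
variance fixed at the logistic variance $\pi^2/3 \approx 3.29$ — a
convention, not an estimate, and printed as 3.29 in reports. Scores are
binarised by order-preserving recoding schemes; the bundled presets cut
load/weighing scores at 2, injection and lesion scores at 3, and backtest
counts at 3, and `median_split()` picks the cut that best balances the
two classes for arbitrary distributions.

Plain joint-mode Laplace estimation (the `glmer` approach) is accurate
for effects informed by many records, but in an animal model every
terminal animal contributes a single Bernoulli record to its own
breeding value, and the quadratic expansion there underestimates
$\sigma^2_a$ severely (we measured roughly −50% at $\sigma^2_a = 1$).
`fit_binary()` therefore works on the reduced animal model: the
Mendelian-sampling deviation of each phenotyped non-parent animal is
integrated out of its record *exactly* by 20-node Gauss–Hermite
quadrature — an algebraic reduction that leaves the marginal likelihood
unchanged — and the Laplace expansion is applied only to litter effects
and parental breeding values, each informed by several records. In
simulations at the default herd scale this removes the bias (mean
$\hat\sigma^2_a \approx 1.09$ at truth 1.0 over replicates). Terminal
EBVs are recovered as parent average plus the posterior mean of the
integrated deviation, $v_i\,\partial\ell_i/\partial c$ at the mode.

The litter effect is integrated (approximately, via Laplace) rather than
conditioned on, and the returned EBVs stay on the liability scale — the
cross-validation below compares correlations, which are scale-free.

As an independent, auditable reference, `gibbs_threshold()` implements an
Albert–Chib-style data-augmentation sampler on a *normal* liability with
the residual variance fixed at $\pi^2/3$ — an exact MCMC for the
probit-form threshold model rescaled to the logistic residual variance,
differing from the logit fit only through the shape of the link
(maximum CDF discrepancy about 0.01). Because a flat scale prior makes
the small-sample posterior of $\sigma^2_a$ extremely heavy-tailed, the
sampler uses a weakly informative scaled-inverse-$\chi^2$(4, 1) prior on
both variances, and the agreement test compares the posterior mean of
$h^2$ under that same prior computed two ways: MCMC versus 2-D
quadrature over the Laplace marginal likelihood. That comparison isolates
exactly what the oracle is meant to audit — the quality of the Laplace
approximation — with a tolerance of four Monte-Carlo standard errors
plus a small link-shape allowance, fixed a priori.

## Scale transformation

`observed_to_liability()` and `liability_to_observed()` implement the
classical transformation between observed-scale and liability-scale
heritability of an all-or-none trait,
$h^2_{liab} = h^2_{obs}\, p(1-p)/z^2$, with $p$ the incidence and $z$ the
standard normal density at the threshold $\Phi^{-1}(1-p)$. The
transformation is defined on a *normal* liability; applying it to a
logit-model estimate therefore carries a small link-shape approximation,
which is stated rather than hidden. At $p = 0.5$ the multiplier is
exactly $\pi/2$; the multiplier is symmetric in $p \leftrightarrow 1-p$
and the functions are exact inverses of each other. Outputs are not
clipped mathematically; reporting code may clip to $[0,1]$ with a
warning. In the pipeline's side-by-side components table, the `h2_tr`
column transforms the threshold-model liability $h^2$ to the observed
scale at the realized incidence of the binarised trait, making it
directly comparable to the linear-model column. Published tables of this
kind sometimes print transformed values that cannot be reproduced from
the printed inputs without unprinted incidences; the package always
recomputes the column from its own realized incidence, and preset
heritabilities are likewise recomputed from component values whenever
rounding makes a printed summary internally inconsistent.

## Synthetic herd generator

No individual pig records are publicly deposited for populations of this
kind, so the package ships a generator that emulates the study design it
targets: 1,004 phenotyped fattening pigs descended from 31 boars and 135
sows (about 7.4 piglets per litter), pedigree two generations deep, sex
assigned per animal, and line, rearing housing (3 classes), finishing
housing (2 classes) and unfamiliar-pig class (4 classes) assigned at the
litter level, mirroring group-level treatments. Litter sizes are Poisson
around the configured mean — an assumption, as litter-size distributions
are rarely printed. One grandparental layer of twice the parental count
is the default depth; the exact grandparental structure of any real herd
is unknowable from published totals, so depth is a parameter rather than
a target.

Traits are generated on a Gaussian liability with additive values
propagated down the pedigree (founders $N(0, \sigma^2_a)$; non-founders
parent average plus Mendelian sampling with variance $d_i \sigma^2_a$,
consistent with the inbreeding in $A$), a shared litter effect, fixed
effects, and Gaussian or — for logit-model studies — logistic residuals.
Ordinal scores and backtest counts are produced by thresholding the
liability; cut-points are placed so that a discretised-normal family
matches each trait's target observed mean and SD
(`thresholds_for_moments()`). Backtest counts are deliberately generated
this way rather than by a count GLM: the downstream models treat counts
as Gaussian or binarised, so only the liability structure matters.
Missingness is independent per-trait Bernoulli masking at the recorded
per-trait rates. The bundled `study_traits()` presets carry
the component values, observed moments and record counts of the emulated
population; preset fixed-effect sizes are zero (the models still estimate
them), since published stage-wise effect sizes are not available in trait
units.

What passing recovery tests on these herds shows — and does not show:
they demonstrate that the estimators are consistent and approximately
unbiased *under the assumed generating model* (multivariate-normal
liabilities, litter-level treatments, random mating, missingness at
random). Real herds add selection, maternal genetic effects, pen-level
social interactions and informative missingness, none of which are
simulated; batch/parity structure is collapsed into litter identity
because the fitted models contain no batch term.

## Cross-validated predictive ability

`run_crossval()` reproduces the model-comparison device used for such
traits: phenotyped animals are split into $k = 4$ folds (251 of 1,004
animals each), breeding values are estimated with all records and again
with each fold's phenotypes masked — the animals stay in the pedigree, so
their EBVs are predicted from relatives — and the Pearson correlation
between the two EBV sets over the fold's animals is averaged over folds
and 5 whole-procedure repeats, per model (Gaussian and logit). Whether
variance components are re-estimated per training split is a switch
(`refit_components`); the default estimates them once on all data, which
is cheaper and stabler, and the report records the choice.

A caution that our simulations make explicit: this with/without-own-record
agreement is **not** a monotone measure of trait information. Both EBV
sets share the training relatives' records, so even phenotypes that are
pure noise with respect to the pedigree yield strongly positive
correlations (≈0.75 at the default herd structure — both vectors then
reduce to the same shrunken family means), and a barely-heritable trait
can show *higher* agreement than a strongly heritable one, for which the
full fit adds own-record Mendelian information that the masked fit cannot
have. The package reports the comparison between the Gaussian and logit
specifications without asserting a direction; differences between model
families on the same trait remain interpretable because the shared-
information baseline is common to both.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the emulated
study scale: 20 replicate herds of ~1,000 records for Gaussian recovery
(each fit takes ~1 s; an 11³ component grid around each optimum verifies
the maximiser), 20 replicates of ~2,000 records for binary recovery, one
~300-animal herd for the MCMC/Laplace agreement check, and 4×5-fold
cross-validation at ~1,000 records. Tie-breaks and degenerate inputs:
constant traits and single-category binary traits are errors, not
estimates; constant fixed factors are dropped with a message; folds are
balanced to ±1 animal; all random draws flow from a single user seed, and
identical configurations reproduce outputs byte for byte.

## Known limitations

* Maternal genetic effects, genetic groups, random regression and
  more-than-two-trait fits are out of scope.
* The threshold model is logit-specific (the 3.29 constant presumes
  logistic residuals); no probit option is exposed.
* The Gibbs reference sampler is exact for a probit-form liability
  rescaled to variance $\pi^2/3$, not for the logistic link itself.
* Laplace-based SEs for liability variances are asymptotic and can be
  optimistic near the boundary.
* Bivariate fits warm-start from univariate components; in very small or
  severely unbalanced data the 9-parameter search can stop at a boundary
  of the correlation parameterisation (|r| = 0.9999), which is reported
  as-is.
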