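# Posterior mean of the liability heritability by 2-D quadrature over the
# Laplace marginal likelihood, under the same scaled-inv-chi2 prior the
# Gibbs reference sampler uses. Comparing this with the Gibbs posterior
# mean isolates the quality of the Laplace approximation (plus link shape).
laplace_posterior_h2 <- function(design, prior_df = 4, prior_scale = 1,
                                 grid_n = 21, range = c(0.02, 8)) {
  lg <- seq(log(range[1]), log(range[2]), length.out = grid_n)
  grid <- expand.grid(a = lg, p = lg)
  ll <- mapply(function(a, p) binary_loglik(design, exp(a), exp(p)),
               grid$a, grid$p)
  ## scaled-inv-chi2 log density + log-scale Jacobian
  lpri <- function(ls2) {
    -(prior_df / 2 + 1) * ls2 - prior_df * prior_scale / (2 * exp(ls2)) + ls2
  }
  lw <- ll + lpri(grid$a) + lpri(grid$p)
  w <- exp(lw - max(lw))
  h2 <- exp(grid$a) / (exp(grid$a) + exp(grid$p) + pi^2 / 3)
  sum(w * h2) / sum(w)
}
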