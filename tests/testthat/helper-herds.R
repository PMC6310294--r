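# Small simulated herds shared across tests.

small_gaussian_herd <- function(seed = 3L, n_sires = 6L, n_dams = 18L,
                                litter_size_mean = 6,
                                sigma2 = c(0.52, 0.08, 0.87)) {
  cfg <- sim_config(
    n_sires = n_sires, n_dams = n_dams, litter_size_mean = litter_size_mean,
    seed = seed,
    traits = list(y = trait_sim_spec(2.5, sigma2[1], sigma2[2], sigma2[3],
                                     "gaussian",
                                     fixed_effects = list(sex = c(0, 0.3),
                                                          breed = c(0, -0.2))))
  )
  simulate_herd(cfg)
}

study_scale_herd <- function(seed, sigma2 = c(0.52, 0.08, 0.87)) {
  cfg <- sim_config(
    seed = seed,
    traits = list(y = trait_sim_spec(2.5, sigma2[1], sigma2[2], sigma2[3],
                                     "gaussian",
                                     fixed_effects = list(sex = c(0, 0.3),
                                                          breed = c(0, -0.2))))
  )
  simulate_herd(cfg)
}

# herd with a binary trait generated on the logistic liability
binary_liability_herd <- function(seed, n_sires = 31L, n_dams = 135L,
                                  litters_per_dam = 2L,
                                  litter_size_mean = 7.44,
                                  sigma2_a = 1.0, sigma2_pe = 0.3) {
  cfg <- sim_config(
    n_sires = n_sires, n_dams = n_dams, litters_per_dam = litters_per_dam,
    litter_size_mean = litter_size_mean, seed = seed,
    traits = list(yb = trait_sim_spec(0, sigma2_a, sigma2_pe,
                                      LOGIT_RESIDUAL_VARIANCE, "gaussian",
                                      residual = "logistic"))
  )
  herd <- simulate_herd(cfg)
  herd$phenotypes$yb <-
    as.integer(herd$phenotypes$yb > stats::median(herd$phenotypes$yb))
  herd
}
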