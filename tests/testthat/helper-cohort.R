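# shared fixtures, all built in code

default_atlas <- make_atlas()

# small healthy cohort with a noiseless planted FC -> WMA map
noiseless_cohort <- function(n = 60, n_nonzero = 16, seed = 3) {
  gt <- ground_truth(default_atlas, n_nonzero = n_nonzero, noise_sd = 0,
                     seed = seed)
  sim <- simulate_cohort(c(HC = n), gt, default_atlas, score_noise_sd = 0,
                         seed = seed + 100)
  sim
}

# patients with a planted WMA effect size plus matched controls
shifted_cohort <- function(diagnosis, g, n_pat, n_con, gt, seed) {
  gt$delta[[diagnosis]] <- delta_for_effect(gt, g)
  simulate_cohort(stats::setNames(c(n_con, n_pat), c("HC", diagnosis)),
                  gt, default_atlas, seed = seed)
}

# one-way F statistic on subject means, computed independently via lm/anova
oracle_main_F <- function(sub_mean, labels) {
  fit <- stats::lm(sub_mean ~ factor(labels))
  stats::anova(fit)[1, "F value"]
}
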