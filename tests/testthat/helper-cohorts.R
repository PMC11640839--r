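# Shared cohort-simulation shorthands for tests.

# Simulation block for one training cohort carrying the planted hub-gene
# signature: one unfavorable gene paired with four favorable genes (4 pairs,
# 5 genes), gene-level log-HR log(2.5) and pair-level log-HR log(2.2), with
# moderate batch effects. The hub topology makes the planted pairs the full
# UPG x FPG product over planted genes, so every additional discovery is an
# unambiguous false positive.
planted_cohort_config <- function(seed, prefix, n_per_batch = c(200, 200),
                                  n_genes = 300) {
  sim_config(n_genes = n_genes, n_samples_per_batch = n_per_batch,
             n_fpg_planted = 4, n_upg_planted = 1,
             gene_log_hr = log(2.5),
             planted_pairs = cbind(rep(1, 4), 1:4), pair_log_hr = log(2.2),
             batch_shift_sd = 1, batch_scale_sd = 0.3,
             censor_rate_target = 0.3, id_prefix = prefix, seed = seed)
}

pipeline_sim_config <- function(seed, n_per_batch = c(200, 200), n_genes = 300) {
  blk <- function(s, prefix) list(
    n_genes = n_genes, n_samples_per_batch = n_per_batch,
    n_fpg_planted = 4, n_upg_planted = 1, gene_log_hr = log(2.5),
    planted_pairs = cbind(rep(1, 4), 1:4), pair_log_hr = log(2.2),
    batch_shift_sd = 1, batch_scale_sd = 0.3, censor_rate_target = 0.3,
    id_prefix = prefix, seed = s)
  list(seed = seed, simulation = list(blk(seed * 2 + 1, "A"), blk(seed * 2 + 2, "B")))
}

# Null survival data: exponential times, ~30% uniform censoring, no group
# structure.
null_surv <- function(n, seed) {
  set.seed(seed)
  t_ev <- rexp(n, 0.15)
  t_cn <- runif(n, 0, 22)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn),
       group = factor(rbinom(n, 1, 0.5)))
}
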