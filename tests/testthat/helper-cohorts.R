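# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

# default-scale cohort (2000 CpGs, 20+20 individuals, 3 lobes)
default_sim <- function() cached("default", simulate_cohort(sim_config(seed = 7)))

# small cohort for network-level unit tests
small_net_cfg <- function(seed = 5) {
  sim_config(seed = seed, n_cpgs = 400, n_clock_cpgs = 10,
             module_sizes = c(50, 30), n_hd_modules = 1)
}
small_net_sim <- function() cached("small_net", simulate_cohort(small_net_cfg()))

# age/sex-residualized variance-filtered matrices per lobe
residualized_lobes <- function(sim) {
  keep <- variance_filter(sim$beta)$keep
  lapply(sim$beta, function(b) {
    al <- align_samples(beta_matrix(unclass(b)[keep, , drop = FALSE]),
                        sim$sheet)
    adjust_age_sex(al$beta, al$sheet)
  })
}

small_net <- function() cached("small_net_fit", {
  sim <- small_net_sim()
  consensus_network(residualized_lobes(sim))
})

hd_trait <- function(sim, resid_list) {
  lapply(resid_list, function(r) {
    as.numeric(sim$sheet$diagnosis[match(colnames(r),
                                         sim$sheet$sample_id)] == "HD")
  })
}

combined_beta <- function(sim) {
  beta_matrix(do.call(cbind, lapply(sim$beta, unclass)))
}
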