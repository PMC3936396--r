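# Build a small metapopulation by hand: one row per individual, each with a
# chosen deterministic sum and instability sum spread evenly over the alleles.
make_pop <- function(det_sums, inst_sums, demes, n_demes = max(demes),
                     n_loci = 5L) {
  n <- length(det_sums)
  stopifnot(length(inst_sums) == n, length(demes) == n)
  det <- matrix(rep(det_sums / (2 * n_loci), times = 2 * n_loci), nrow = n)
  inst <- matrix(rep(inst_sums / (2 * n_loci), times = 2 * n_loci), nrow = n)
  hedgesim:::develop_cohort(det, inst, as.integer(demes), as.integer(n_demes))
}

# Equilibrium mean instability of one replicate under the given overrides;
# NA when the run goes extinct.
eq_inst <- function(..., gens = 2500, seed = 1, record_every = 10) {
  cfg <- sim_config(..., generations = gens, record_every = record_every)
  res <- run_replicate(cfg, seed)
  if (res$status != "completed") return(NA_real_)
  equilibrium_summary(res)$mean_instability
}
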