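# published pair tables reconstructed from the printed counts
paper_tables <- function() make_fixture("paper_tables")$tables

# small standardized, flagged cohort for smoke-level checks
small_cohort <- function(n = 3000, a2 = 0.58, c2 = 0.22, seed = 11,
                         rule = "top-stanine", score = "stanine", n_sib = 0) {
  cfg <- sim_config(a2 = a2, c2 = c2, n_mz = n, n_dz = n, n_sib = n_sib,
                    drift_per_year = 0, seed = seed)
  flag_probands(adjust_and_standardize(simulate_pairs(cfg), score = score),
                rule = rule)
}
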