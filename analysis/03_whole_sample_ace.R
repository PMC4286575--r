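#!/usr/bin/env Rscript
# Whole-distribution twin analysis of the simulated cohort: standardize the
# stanine scores against birth year, then fit the continuous ACE model to
# the twin pairs and compare submodels.

library(twinextremes)
dir.create("results", showWarnings = FALSE)

pairs <- if (file.exists("scratch/cohort_pairs.tsv")) {
  read_pair_table("scratch/cohort_pairs.tsv")
} else {
  simulate_pairs(sim_config(seed = 20260101))
}
std <- adjust_and_standardize(pairs, score = "stanine")
twins <- std[std$relationship != "SIB", ]

r_obs <- vapply(split(twins, twins$relationship),
                function(d) cor(d$score_1, d$score_2), 0)
cat(sprintf("Observed twin correlations: MZ %.2f, DZ %.2f\n",
            r_obs["MZ"], r_obs["DZ"]))
cat(sprintf("Falconer rough estimate: a2 = %.2f\n",
            falconer_ace(r_obs["MZ"], r_obs["DZ"])["a2"]))

fit <- fit_ace_continuous(twins)
print(fit)
cmp <- compare_submodels(twins)
print(cmp$lrt, digits = 3)
cat("(Simulation truth: A = 0.58, C = 0.22, E = 0.20; the stanine's nine\n",
    "levels attenuate the pair correlations slightly relative to the latent\n",
    "scale, so estimates sit a shade below/above truth.)\n")

jsonlite::write_json(list(
  observed_r = as.list(round(r_obs, 4)),
  ace = list(a2 = fit$a2, c2 = fit$c2, e2 = fit$e2,
             ci_a2 = fit$ci_a2, ci_c2 = fit$ci_c2, ci_e2 = fit$ci_e2,
             loglik = fit$loglik),
  lrt = cmp$lrt
), "results/ace_continuous.json", auto_unbox = TRUE, digits = 6,
   dataframe = "rows")
cat("Wrote results/ace_continuous.json\n")
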