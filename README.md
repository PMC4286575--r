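# twinextremes

Quantitative-genetic analysis of **high-scoring extreme groups** from twin
and sibling pair data: is the extreme tail of a trait caused by the same
genetic and environmental factors as normal-range variation, or by
something qualitatively different?

The package targets registry-style cohorts in which a trait (here,
cognitive ability) is recorded on a coarse **stanine** scale (integers 1–9,
nominal mean 5 / SD 2) for large numbers of monozygotic (MZ) twin,
dizygotic (DZ) twin and full-sibling pairs, and the "extreme group"
(probands) is the top category, roughly the top 5%. It provides:

- a **synthetic-cohort simulator** under the ACE liability model
  (`sim_config()`, `simulate_pairs()`): latent liability
  `z = a·A + c·C + e·E` with pair correlations `r_MZ = a² + c²`,
  `r_DZ = r_SIB = a²/2 + c²`, stanine discretisation, birth-year drift and
  a one-pair-per-family sampling rule (`select_study_pair()`);
- **cohort preparation**: birth-year adjustment and standardization,
  proband flagging, 2×2 pair tables, extreme-group means;
- **concordances**: pairwise `c/(c+d)`, probandwise `2c/(2c+d)` and the
  doubling screen `2(p_MZ − p_DZ)`;
- **tetrachoric correlations** by full maximum likelihood over the latent
  correlation and threshold, with a two-step classical estimator and a
  brute-force likelihood lattice as cross-checks;
- **ACE variance decomposition** — continuous (bivariate-normal pair
  likelihood) and liability-threshold (joint multinomial fit to the MZ and
  DZ tables) — with profile-likelihood CIs and boundary-aware submodel
  LRTs;
- **DeFries–Fulker extremes regression** `C = β1·P + β2·R + A`, yielding
  group correlations, group heritability and a family-level bootstrap.

The repository is organised as an analysis workflow: the numbered drivers
in `analysis/` (simulate → replicate printed tables → whole-sample ACE →
liability analysis → DF extremes → full pipeline) narrate the study and
write their tables under `results/`, while all computation lives in the
package so the tests can exercise it directly.

## Worked example

The headline analyses run from printed pair counts alone. With 54
both-high, 131 discordant and 2854 both-low MZ pairs (and 28/168/3000 for
DZ):

```r
library(twinextremes)
mz <- contingency2x2(54, 131, 2854, "MZ")
dz <- contingency2x2(28, 168, 3000, "DZ")

probandwise_concordance(mz)   # 0.4518828
probandwise_concordance(dz)   # 0.25

fit_tetrachoric(mz)
#> Tetrachoric correlation (MZ, joint ML): r = 0.78 (95% CI 0.71-0.84, SE 0.03)
#>   threshold = 1.759 (top 3.9%), loglik = -808.76, n = 3039 pairs

fit_ace_liability(mz, dz)
#> liability ACE model (n = 6235 pairs)
#>   A = 0.42 (0.17-0.68)  C = 0.36 (0.12-0.57)  E = 0.22 (0.16-0.30)
#>   implied r_MZ = 0.78, r_DZ = 0.57, loglik = -1626.75
```

Read: 45% of MZ co-twins of top-group probands are themselves in the top
group (25% for DZ); the latent liability correlates 0.78 in MZ pairs; and
the liability-threshold model attributes 42% of liability variance to
additive genetics, 36% to shared environment and 22% to non-shared
influences — high scores are heritable, and by the same additive
architecture as the full range.

Group-level statistics come straight from group means: probands 1.98 SD
above the population mean whose MZ co-twins average 1.39 and DZ co-twins
0.95 give group correlations `1.39/1.98 = 0.70` and `0.95/1.98 = 0.48`
(`group_correlation()`), hence group heritability
`2·(0.70 − 0.48) = 0.44` (`group_h2_doubling()`).

`run_pipeline()` executes the whole chain (simulate or load → standardize
→ all four analyses) and returns one JSON-serialisable report;
`make_fixture()` provides deterministic cohorts with analytically known
expectations (`"paper_tables"`, `"continuity"`, `"null"`, `"perfect_h2"`).

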