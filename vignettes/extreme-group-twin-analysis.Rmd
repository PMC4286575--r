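---
title: "Quantitative-genetic analysis of high-scoring extreme groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-genetic analysis of high-scoring extreme groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Does membership of the extreme tail of a quantitative trait arise from the
same genetic and environmental factors as variation in the rest of the
distribution, or from something qualitatively different? For cognitive
ability the "continuity" view predicts that the heritability of *being in
the top group* should match the heritability of individual differences
across the whole range, and that the same genes should drive both. The
package implements the full analysis battery used to ask this question in
large twin/sibling cohorts with coarse registry scores:

1. **Concordance statistics** on the dichotomy "top group vs rest";
2. **Tetrachoric correlations** and a **liability-threshold ACE model**
   fitted to the dichotomous pair tables;
3. **Continuous ACE model-fitting** on the whole distribution;
4. **DeFries–Fulker (DF) extremes regression**, which quantifies how far
   relatives of top-group probands regress to the population mean.

A synthetic-cohort simulator generates pair-level data with known ground
truth so that every estimator can be validated by parameter recovery.

## The generative model

Each individual carries a latent liability
\[
  z = a\,A + c\,C + e\,E, \qquad a^2 + c^2 + e^2 = 1,
\]
with \(A, C, E\) independent standard normals: additive-genetic, shared-
environment and non-shared components. \(A\) is identical for MZ co-twins
and correlated 0.5 for DZ twins and full siblings (realised as a shared
plus a unique part weighted \(\sqrt{1/2}\) each); \(C\) is shared within a
pair; \(E\) is independent. Pair correlations are therefore
\(r_{MZ} = a^2 + c^2\) and \(r_{DZ} = r_{SIB} = a^2/2 + c^2\). The
component realisation (rather than drawing directly from the implied
bivariate normal) keeps the simulator extensible to larger sibships.

Scores are emitted on two scales: the continuous latent scale, and a
**stanine** (standard nine) integer scale obtained by cutting the liability
at eight z-boundaries. Registry cohorts of this kind only record the
stanine, so the default analysis route standardizes the stanine.

### Simulator defaults

The defaults of `sim_config()` reproduce the structure of a national male
conscription cohort:

| parameter | default | rationale |
|---|---|---|
| `a2, c2, e2` | 0.58 / 0.22 / 0.20 | whole-range ACE decomposition typical of late-adolescent cognitive ability |
| `n_mz, n_dz, n_sib` | 3039 / 3196 / 354,890 | published pair counts of the cohort emulated |
| `birth_year_range` | 1950–1991 | conscription at age 18 over a four-decade testing window |
| `drift_per_year` | 0.02 SD/yr | a Flynn-type secular trend of ~3 IQ points/decade |
| `stanine_cutpoints` | `"top5"` preset | see below |
| `proband_rule` | top stanine | the registry's extreme-group definition |

Sex is not modelled (the emulated cohort is all male), and twins of
unknown zygosity are not generated (they were excluded from the analyses
the package reproduces). Sibling age gaps are drawn as 1–4 years with
~97% within two years, matching the reported age structure; the exact gap
distribution only matters through the birth-year drift and is otherwise
inert.

### Stanine cut-points

The classical stanine boundaries \(\pm 0.25, \pm 0.75, \pm 1.25, \pm 1.75\)
put 4% of a normal population in the top category; cohorts that report 5%
in the top category must have used a slightly lower upper boundary, so the
`"top5"` preset replaces 1.75 by \(\Phi^{-1}(0.95) = 1.6449\). Which
convention a given testing authority used is generally unknowable, so both
are exposed; the default is `"top5"` because the analyses here define
probands as the top ~5%. One numerical fact worth knowing: a standard
normal discretized at the classical cut-points has mean exactly 5 but SD
1.944, not the nominal 2 — which is why registry stanine SDs are typically
printed as 1.94. The tests assert the closed-form value, not the nominal
one.

## Cohort preparation

`adjust_and_standardize()` stacks both pair members (each individual once),
removes the birth-year trend by OLS and scales residuals to unit SD, so the
adjusted population has mean 0, SD 1 exactly. With a single birth year the
regression is skipped. Constant scores are an error: standardization is
undefined. The operation is idempotent on its own output.

Proband flags come either from the raw stanine (= 9) — mirroring registry
practice, where flags predate any rescaling — or from an empirical top-
quantile rule on the adjusted score (ties included above the threshold).
Means, however, are always computed on the adjusted continuous scale.

**Double entry.** Concordant pairs contribute both members as probands,
each with the other as partner; the number of proband–partner observations
is therefore \(2 c + d\) for \(c\) concordant and \(d\) discordant pairs.
The alternative (randomly selecting one member per concordant pair) wastes
information and adds selection noise; double entry with family-level
bootstrap inference is the standard DF practice and is used throughout.

## Concordance

With \(c\) both-proband and \(d\) one-proband pairs, pairwise concordance
is \(c/(c+d)\) and probandwise concordance \(2c/(2c+d)\) — the morbidity
risk to the relative of a proband. Both condition on pairs containing at
least one proband. The identity \(2c/(2c+d) \ge c/(c+d)\) (equality iff
\(c = 0\)) is enforced as a property test. Doubling the MZ–DZ probandwise
difference gives a rough heritability screen; it ignores the base rate, so
`concordance_h2()` labels its output as rough and warns outside [0, 1).

## Tetrachoric correlation and the liability-threshold ACE model

The symmetric 2×2 pair table has cell probabilities, under a standard
bivariate-normal liability with correlation \(r\) and threshold \(t\):
\[
  p_{hh} = P(Z_1 > t, Z_2 > t), \quad
  p_{disc} = 2\,(\Phi(-t) - p_{hh}), \quad
  p_{ll} = 1 - 2\Phi(-t) + p_{hh}.
\]
`cell_probabilities()` evaluates \(p_{hh}\) by reducing the orthant
probability to a 1-D integral,
\(\int_t^\infty \phi(z)\, \Phi\!\big((r z - t)/\sqrt{1-r^2}\big)\,dz\),
on a fixed 128-node Gauss–Legendre rule over \([\max(t,-8.5),\,8.5]\). The
integrand is analytic, so the rule is accurate to well below 1e-10 (tests
compare against an independent 2-D quadrature and a separately implemented
multivariate-normal CDF at 1e-8). \(r = \pm 1\) is evaluated as the exact
comonotone/antimonotone limit. The vectorised form over \(r\) is what makes
a brute-force likelihood lattice (2001 correlation × hundreds of threshold
values) affordable as an optimizer-free oracle.

`fit_tetrachoric()` maximizes the multinomial likelihood jointly over
\((\operatorname{atanh} r,\; t)\) — the atanh scale keeps \(r\) inside
(−1, 1) and gives the asymmetric CI appropriate near the boundary. SEs come
from the observed information with a delta-method step back to \(r\).
Convergence uses a relative log-likelihood tolerance of 1e-14 (BFGS); the
two-step classical estimator (threshold from the margin, then 1-D
root-finding on the both-high cell) is kept as an independent cross-check,
and zero cells produce a boundary flag rather than an error.

`fit_ace_liability()` replaces the free correlation with the ACE structure
\(r_{MZ} = a^2+c^2\), \(r_{DZ} = a^2/2+c^2\) and fits both tables jointly.
The threshold is **equated across zygosity groups by default** — the two
groups are samples from one population with one base rate; a free-threshold
option exists because the alternative convention is also defensible and
moves the correlation only in the third decimal.

## Continuous ACE model

Scores standardized upstream have mean 0 and variance 1 by construction,
so the pair likelihood fixes both and estimates only \((a^2, c^2)\) on the
simplex (Nelder–Mead on the proportions; submodels AE/CE/E by 1-D golden-
section search on the free component). 95% CIs are profile-likelihood
intervals: endpoints where the profiled log-likelihood drops
\(\chi^2_{1,0.95}/2 = 1.9207\), located by root-finding to 1e-9 and
verified in the tests to sit at exactly that drop (±1e-4). Components are
bounded in [0, 1]; boundary solutions are reported as such, never silently
clipped. A dominance component is deliberately absent: the model class
implies \(r_{MZ} \le 2 r_{DZ}\), and departures are screened by comparing
the observed correlations, not by adding a fourth parameter the two-group
design cannot identify. Non-twin siblings can optionally enter the fit
pooled at relatedness 0.5; the default fits twins only, matching the
classical design.

**Submodel tests.** Dropping a variance component pins it to the boundary
of the parameter space, so the LRT null distribution is not plain
\(\chi^2\): single-component drops use the 50:50 \(\chi^2_0{:}\chi^2_1\)
mixture, and the E model (two boundary constraints) the 1:2:1
\(\chi^2_0{:}\chi^2_1{:}\chi^2_2\) mixture, ignoring the (weak) correlation
between the two constraints.

## DF extremes analysis

`df_transform()` expresses every proband's and partner's score as a
deviation from the population mean divided by the *relationship-specific*
proband mean deviation (the augmented DF convention — chosen because the
transform is meant to absorb MZ/DZ proband mean differences; a pooled
divisor is available behind a flag). Transformed proband means are 1 in
every class, so in the regression
\[
  C = \beta_1 P + \beta_2 R + A, \qquad R \in \{1, 0.5\},
\]
\(\beta_2\) *is* the group heritability, and the class means of the
transformed partner scores are the group correlations \(g_{MZ}, g_{DZ}\).
The companion components \(g_{MZ} - h^2_g\) and \(1 - g_{MZ}\) close the
triple to 1. With equal transformed proband means, OLS gives the exact
identity \(\beta_2 = 2(\bar C_{MZ} - \bar C_{DZ})\), which the tests verify
against a direct least-squares solve.

Inference uses a nonparametric bootstrap over probands' families (2000
resamples, stratified by relatedness class, seeded): double entry makes
rows within a family dependent, and resampling whole families is robust to
that dependence where analytic OLS standard errors are not.

**Continuity as a testable property.** Under bivariate normality,
\(E[\text{partner} \mid \text{proband selection}]\) deviates from the mean
by exactly \(r\) times the proband deviation, so on data simulated under a
single ACE model the group correlations equal the latent pair correlations
and group heritability equals \(a^2\). The acceptance suite simulates
50,000 pairs per twin group under \(a^2 = 0.58\), selects the top 5% on the
continuous scale, and requires the DF estimate to land within three
bootstrap SEs of 0.58. On the stanine route the coarse 9-level scale and
top-category proband definition attenuate group correlations slightly —
one reason registry estimates of group heritability sit below whole-range
heritability even under perfect continuity.

## What the simulator does and does not emulate

It reproduces: the ACE correlation structure, one pair per family,
stanine discretization, secular drift removed downstream by design, the
~5% top-category fraction, and realistic group sizes. It does **not**
model assortative mating (which can mask nonadditive variance in twin
designs without parental data), test unreliability or version changes
(simulated stanines are exact functions of the liability, so simulated
group correlations run slightly above registry values), conscription
exclusions, or sex differences. Passing recovery tests therefore shows the
estimators are correct under the liability model, not that real registry
data satisfy that model.

## Numerical choices and degenerate inputs

- Optimizations are deterministic; the only randomness is the simulator
  and the bootstrap, both driven by a single seed per call.
- Tetrachoric/liability likelihoods floor cell probabilities at 1e-320
  to keep zero-count cells finite; `0·log(0)` terms are dropped exactly.
- Empty tables, single relatedness classes, constant scores, proband-free
  cohorts and singleton families raise immediate, specific errors.
- Ties in family pair-selection resolve to the youngest pair; ties at the
  proband quantile threshold are included above it.
- Test problem sizes: 10^6 draws for scale checks, 10^5 pairs for
  correlation convergence, 200 replicates of 5,000 + 5,000 pairs for
  parameter recovery, 50,000 pairs/group for the continuity check — large
  enough that Monte-Carlo error (3/√n bands) is well inside the assertion
  tolerances, small enough that the full suite runs in well under a minute.

## Known limitations

- The liability ACE CIs are profile intervals; cohorts analysed with other
  software may report slightly different intervals near boundaries.
- Group-ACE components from the doubling estimator are not constrained to
  [0, 1]; out-of-range values are reported with a warning as a signal of
  model misfit or sampling noise.
- The DF regression treats the relationship-specific divisors as known
  when bootstrapping; the divisors are re-estimated per resample only
  through the family resampling, which is adequate at the group sizes used
  here but could understate uncertainty in very small proband groups.
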