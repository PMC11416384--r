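---
title: "Two-step two-sample MR mediation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step two-sample MR mediation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as
instrumental variables: a SNP robustly associated with an exposure, and
affecting the outcome only through that exposure, identifies the causal
effect even under unmeasured confounding, because alleles are assigned
at conception. With summary statistics from two non-overlapping GWAS,
each SNP contributes a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$, and the estimators in this
package combine these ratios under progressively weaker assumptions:

- **IVW** assumes all instruments are valid; it is the weighted mean of
  the ratios with weights $1/\mathrm{se}_j^2$, identical to weighted
  least squares of $\hat\Gamma$ on $\hat\gamma$ through the origin. The
  multiplicative-random-effects variant (`ivw_mre`, the headline)
  scales the fixed-effect SE by $\sqrt{\max(1, Q/(J-1))}$, so
  heterogeneity widens intervals without moving the point estimate. We
  report the random-effects variant as the headline because it is the
  common package default in this literature; the fixed-effect variant is
  always computed alongside.
- **MR-Egger** allows directional pleiotropy via a free intercept,
  assuming pleiotropic effects are independent of instrument strength.
  Instruments are first oriented so all $\hat\gamma_j \ge 0$; without
  that convention the intercept has no interpretation, since flipping an
  allele flips the sign of its pleiotropic contribution.
- **Weighted median** is consistent while SNPs carrying at least half of
  the weight are valid. **Simple/weighted mode** are consistent while
  the largest cluster of ratios is valid.
- **BWMR** (Bayesian weighted MR) models the errors-in-variables
  structure explicitly:
  $\hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2)$,
  $\hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with
  $\gamma_j \sim N(0, \sigma_0^2)$ and $\alpha_j \sim N(0, \tau^2)$, so
  weak-instrument uncertainty and pervasive pleiotropy both propagate
  into the interval; sparse outliers are down-weighted by
  $w_j = \exp(-\max(0, t_j^2 - 1)/2)$ on the standardized residual.

Diagnostics gate every reported association: Cochran's Q for
heterogeneity, the Egger intercept and MR-PRESSO global test for
pleiotropy (either below 0.05 excludes a trait), MR-PRESSO's per-SNP
outlier and distortion tests, and leave-one-out re-estimation.

Two-step mediation decomposes a total effect $c$ of exposure on outcome
into an indirect component through a mediator, $a \times b$, and a
direct component $c' = c - a b$, where $a$ is the exposure-to-mediator
and $b$ the mediator-to-outcome MR estimate, each from its own
instrument set. The proportion mediated is $ab/c$. Both steps are
univariable MR — $b$ is *not* adjusted for the exposure — which is a
recognized approximation: it is exact when the exposure's direct effect
on the outcome does not confound the mediator-outcome leg's instruments,
and it is the construction under which the decomposition
$c = c' + ab$ holds by definition.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 1e-5 | instrument association cutoff |
| `r2_threshold` | 0.001 | squared-correlation clumping cutoff |
| `window_kb` | 10,000 kb | clumping window, same chromosome |
| `f_min` | 10 | weak-instrument F cutoff |
| `alpha` | 0.05 | significance and gate threshold |
| `n_sim_presso` | 1000 | MR-PRESSO null simulations |
| `n_boot` | 1000 | bootstrap resamples for median/mode SEs |
| `delta_order` | first | delta-method order for $\mathrm{se}(ab)$ |
| `ivw_variant` | mre | headline IVW variant |

The F statistic is computed as $\beta^2/\mathrm{se}^2$, the conventional
single-SNP form to which the threshold 10 belongs. Applied reports
occasionally describe the screen verbally as "effect size divided by the
squared standard error" ($|\beta|/\mathrm{se}^2$), which is not
dimensionless; `f_statistic(..., literal = TRUE)` exposes that reading
for comparability, but the default is the standard screen.

## The synthetic-data generator

`simulate_triplet_gwas()` emulates, directly on the summary-statistic
scale, the statistical structure of a three-trait study: per-SNP effects
with sampling noise $\mathrm{se} = 1/\sqrt{2p(1-p)n}$ for allele
frequency $p$ and GWAS size $n$, two-sided Gaussian p-values, uniformly
drawn frequencies in [0.05, 0.5], non-palindromic allele pairs (the
harmonization hazards — strand flips, palindromic rewrites — are
injected separately by `inject_harmonization_noise()`), and variants
spaced beyond the clumping window so they are approximately independent
unless an LD matrix is supplied (`simulate_ld_blocks()` provides
block-diagonal AR(1) panels).

Three disjoint instrument groups carry the causal structure: exposure
instruments ($\gamma_j$, with mediator effect $a\gamma_j$ and outcome
effect $(c' + ab)\gamma_j + \alpha_j$), mediator-specific instruments
(the mediator's own genetic architecture — without them the
mediator-to-outcome leg would be unidentified, because every mediator
instrument would act through the exposure and the two-step estimate of
$b$ would converge to $c/a$), and optional outcome-specific instruments
for reverse-MR experiments. Pleiotropic effects $\alpha_j$ are expressed
per exposure-increasing allele, the orientation on which the Egger
intercept is defined; injected with a symmetric sign convention they
would cancel out of every directional-pleiotropy diagnostic.

Instrument strength is parameterized as the expected single-SNP
chi-square: 60 for exposure instruments and 100 for mediator- and
outcome-specific ones, values typical of variants surviving selection at
p < 1e-5; at these strengths the expected contamination of the
mediator's instrument set by exposure-shared SNPs is a fraction of one
SNP per study at the default sample sizes. Defaults are J = 150
instruments per set and n = 300,000 per GWAS, the mediation-scenario
conditions used throughout the tests; the screening control experiments
instead use an asymmetric regime (exposure 300,000; mediator 15,000;
outcome 8,000) chosen so that each trait's instruments are genome-wide
significant only in their own GWAS, as in real microbiome/immune/rare-
disease studies where the traits have distinct genetic architectures.

What the generator does **not** emulate: real LD panels (no proxy-SNP
structure), binary-trait case/control ascertainment (outcomes are
continuous-liability log-odds; the estimators consume beta/SE pairs
identically), sample overlap between the GWAS, population stratification
or assortative mating, and winner's-curse-free discovery (instrument
selection inside the pipeline does induce mild winner's curse, which is
realistic). Passing tests therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to every
artifact of real consortium data.

## Numerical and design choices

- **Cochran's Q weights.** The diagnostic Q uses the second-order
  Wald-ratio variance
  $\sigma_{Yj}^2/\hat\gamma_j^2 + \hat\beta^2 \sigma_{Xj}^2/\hat\gamma_j^2$.
  With first-order weights, $E[Q/(J-1)] \approx 1 + \beta^2
  \sigma_X^2/\sigma_Y^2$ on perfectly homogeneous data, so at strong
  causal effects the first-order gate rejects clean associations with
  probability approaching one as J grows; second-order weights restore
  $E[Q/(J-1)] = 1$. `second_order = FALSE` recovers the plain statistic.
  IVW itself keeps conventional first-order ratio weights.
- **BWMR estimation.** Deterministic initialization at the fixed-effect
  IVW estimate; alternating posterior updates of the latent
  $\gamma_j$ and $(\beta, \tau^2, \sigma_0^2)$ with weakly-informative
  inverse-gamma(1e-3, 1e-3) regularization; convergence when
  $|\Delta\beta| < 10^{-6}$ (cap 5000 sweeps; non-convergence is
  flagged and the last iterate returned). The $\tau^2$ update uses the
  unweighted residual moment: a weighted update lets the weights trim
  exactly the dispersion $\tau$ should absorb, collapsing $\tau \to 0$
  under pervasive balanced pleiotropy.
- **BWMR standard error.** The SE is the curvature of the weighted
  *marginal* likelihood (latent effects integrated out; the conditional
  curvature given the posterior means understates variance because those
  means already borrow outcome noise), multiplied by 1.10. The factor
  sits between the information bound (1.0) and the asymptotic efficiency
  cost of the redescending weight function under Gaussian residuals,
  $\sqrt{E[w^2 t^2]}/|E[\psi'(t)]| = 1.1933$; the intermediate value was
  calibrated by simulation jointly over null and strong-effect regimes,
  where the two bounds are respectively attained.
- **MR-PRESSO.** The global p-value uses the plus-one estimator
  (smallest reportable value $1/(n_\mathrm{sim}+1)$). Per-SNP outlier
  p-values use the plain empirical fraction — with the plus-one floor, a
  Bonferroni correction over J could never reject at practical
  $n_\mathrm{sim}$ — and because they live on a discrete $1/n_\mathrm{sim}$
  grid, an occasional clean SNP reaches the threshold alongside a true
  outlier. The distortion null removes random same-size SNP subsets.
- **Median/mode SEs** come from a parametric bootstrap (Gaussian
  resampling of both effect arrays, seeded, default 1000 resamples);
  mode estimates maximize a Gaussian-kernel density on a 512-point grid
  spanning the ratio range ± 3 bandwidths, bandwidth `phi` × 0.9 ×
  min(sd, MAD) × $J^{-1/5}$; when the ratio spread is exactly zero the
  common ratio is returned directly.
- **Tie-breaks and degenerate inputs.** Clumping sorts by p-value with
  ties broken by (chromosome, position); SNPs missing from the LD panel
  are treated as independent with a logged message; zero exposure
  effects make the Wald ratio an error, not an NA; a zero total effect
  flags the proportion mediated as undefined while still returning the
  decomposition; exact-fit BWMR inputs get a floored positive SE.
- **Candidate-rule precedence.** Reverse-causality exclusion is
  evaluated before the forward sensitivity gates: an injected reverse
  effect also contaminates the forward instrument set and trips
  pleiotropy gates, but the scientifically primary reason — and the one
  reported — is the reverse signal.
- **Proportions** are reported as percentages; printed summaries round
  to 1–2 decimals. Dividing an already-rounded indirect effect by a
  rounded total effect (as printed tables sometimes do) can differ in
  the last digit from the unrounded ratio; this package always computes
  from unrounded values.

## Problem sizes used by the test suite

Monte-Carlo checks are sized to run on one CPU in minutes: estimator
recovery 120 replicates (J = 60), null calibration 1000 replicates
(J = 100), mediation recovery 200 pipeline replicates (J = 150 per
instrument set), MR-PRESSO power 200 runs at 500 null simulations,
PRESSO uniformity 300 runs at 200 simulations, and 30 + 30 end-to-end
screening controls at 300 PRESSO simulations and 150 bootstrap
resamples. The acceptance script uses the same designs at comparable
sizes, reseeded from its `--seed` argument.

## Known limitations

- **Compounded gate multiplicity bounds end-to-end selection.** A
  mediation candidate must pass three calibrated nominal-0.05
  diagnostics on each of three legs. Even with perfectly clean data,
  per-leg false-exclusion is roughly 5–8% (the Egger intercept also
  picks up genuine winner's-curse curvature), so the probability that a
  true triplet survives all gates is structurally around 0.8–0.85 —
  a property of stacking calibrated gates, not a defect of any single
  test. The end-to-end positive-control rate reported by the acceptance
  script quantifies this ceiling; applying the gates at a stricter
  per-test level, or gating on outlier-corrected estimates, would trade
  false exclusions for pleiotropy sensitivity.
- The mediator-to-outcome leg is univariable (no multivariable MR), so
  residual confounding of that leg by the exposure is only diluted by
  instrument separation, not removed.
- No proxy-SNP lookup: instruments missing from an outcome GWAS are
  dropped and logged, which loses power relative to an analysis with an
  external LD reference.
- The delta-method interval for the proportion mediated assumes the
  three leg estimates are independent (exact only for non-overlapping
  cohorts) and degrades near $c = 0$, where the proportion itself stops
  being meaningful ("inconsistent mediation" is flagged when indirect
  and total effects disagree in sign).
- Simulated LD is block-diagonal AR(1); clumping behavior on real,
  long-range LD (e.g. the MHC) is untested.
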