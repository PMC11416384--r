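# mrmediate

Two-step, two-sample Mendelian randomization (MR) with mediation
analysis, for epidemiologists who want to screen many GWAS-summary-level
exposures (for example gut-microbiome features) against a disease outcome
(for example neuropathic-pain diagnoses), test candidate mediators (for
example immune-cell phenotypes), and decompose total causal effects into
mediated and direct components — all from summary statistics, with the
sensitivity analyses the field expects.

## The model

A SNP j with estimated effect γ̂<sub>j</sub> (SE σ<sub>Xj</sub>) on an
exposure and Γ̂<sub>j</sub> (SE σ<sub>Yj</sub>) on an outcome gives the
Wald ratio β̂<sub>j</sub> = Γ̂<sub>j</sub>/γ̂<sub>j</sub>. Valid
instruments (associated with the exposure, affecting the outcome only
through it) identify the causal effect β. The package implements:

- **Instrument selection**: p < 1e-5, greedy LD clumping (r² < 0.001,
  10,000 kb window), and the weak-instrument screen F = β²/se² ≥ 10.
- **Harmonization** onto the exposure's effect allele, dropping
  palindromic (A/T, G/C) and allele-ambiguous SNPs.
- **Estimators**: fixed- and multiplicative-random-effects IVW
  (inverse-variance-weighted mean of the Wald ratios), MR-Egger
  (free-intercept weighted regression; the intercept estimates
  directional pleiotropy), weighted median, simple and weighted mode,
  and a Bayesian weighted estimator (BWMR) that models measurement error
  in γ̂ and per-SNP pleiotropy α<sub>j</sub> ~ N(0, τ²), down-weighting
  outlying SNPs via w = exp(−max(0, t² − 1)/2).
- **Diagnostics**: Cochran's Q (second-order weights), the Egger
  intercept test, MR-PRESSO (global residual-sum test, per-SNP outlier
  test, distortion test), and leave-one-out re-estimation.
- **Two-step mediation**: with a (exposure→mediator), b
  (mediator→outcome) and c (total exposure→outcome) estimated by
  univariable MR on disjoint instrument sets, the indirect effect is
  a·b, the direct effect c′ = c − a·b, the proportion mediated
  (a·b)/c, with delta-method 95% intervals
  (se<sub>a·b</sub> = √(a²se<sub>b</sub>² + b²se<sub>a</sub>²)).
- **Screening**: batch forward screens, reverse-MR exclusion, and the
  multi-method candidate rule (IVW + BWMR concordant at p < 0.05 plus at
  least one further concordant method, clean diagnostics, no reverse
  signal, sign-consistent mediation).

A synthetic three-trait GWAS generator with known causal structure
(`truth_params()` / `simulate_triplet_gwas()`) makes every stage testable
offline.

## Worked example

```r
library(mrmediate)

tp  <- truth_params(seed = 42)          # a = 0.24, b = -0.27, c' = -0.90
sim <- simulate_triplet_gwas(tp)

inst <- select_instruments(sim$exposure)
pair <- harmonize(inst, sim$outcome)
mr_all_methods(pair, n_boot = 500, seed = 1)
#>            method nsnp   beta     se      pval    or ci_low ci_high
#> 1         ivw_mre   85 -0.971 0.0156  0.00e+00 0.379  0.367   0.390
#> 2          ivw_fe   85 -0.971 0.0118  0.00e+00 0.379  0.370   0.387
#> 3           egger   85 -0.941 0.0391  3.66e-39 0.390  0.361   0.421
#> 4 weighted_median   85 -0.961 0.0249  0.00e+00 0.382  0.364   0.401
#> 5     simple_mode   85 -0.931 0.0496  1.37e-78 0.394  0.358   0.435
#> 6   weighted_mode   85 -0.933 0.0389 3.92e-127 0.393  0.364   0.425
#> 7            bwmr   85 -0.974 0.0240  0.00e+00 0.378  0.360   0.396

sensitivity_report(pair, n_sim = 1000, seed = 1)
#> <sensitivity_report> Q=73.08 (df=84, p=0.797); Egger intercept=-0.0009
#> (p=0.402); PRESSO global p=0.75; clean

mediation_pipeline(sim$exposure, sim$mediator, sim$outcome)
#> <mediation_estimate> a=0.238 b=-0.288 c=-0.971
#>   indirect (a*b) = -0.0684 [-0.0824, -0.0544]; direct (c') = -0.9030
#>   proportion mediated: 7.04% [5.58%, 8.50%]
```

The 85 retained instruments estimate the total effect β ≈ −0.97
(odds ratio 0.38: the exposure is protective), all seven estimators
agree, the diagnostics are clean, and the two-step decomposition
attributes about 7% of the effect to the mediator — close to the
generating truth a·b/c = 6.7%.

The package also ships, in `inst/extdata/mediation_paths.tsv`, published
path-coefficient estimates for five gut-microbiome → immune-cell →
neuropathic-pain triplets (`example_mediation_paths()`); feeding them
through `mediate_decompose()` reproduces the reported indirect effects
(−0.065, −0.171, 0.034, −0.012, −0.057) and mediated proportions
(6.7%, 12.6%, 12%, 3.3%, 7.5%).

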