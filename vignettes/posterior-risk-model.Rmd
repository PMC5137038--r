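---
title: "The posterior-risk model behind niptppr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The posterior-risk model behind niptppr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptppr)
```

## The problem

Non-invasive prenatal testing (NIPT) screens for foetal trisomy 13, 18 and
21 by sequencing cell-free DNA in maternal plasma. The laboratory reports a
Z-score: how many standard deviations the target chromosome's read fraction
lies above the mean of diploid controls. A Z-score above 3 is conventionally
called "positive", but a positive call is not a diagnosis. The probability
that the foetus actually carries the trisomy depends as much on the woman's
pre-test (a priori) risk as on the Z-score itself: the same Z = 3.5 can mean
a few percent for a 25-year-old at low risk and well over half for a woman
whose first-trimester combined test already put her at 1:10. `niptppr` makes
that dependence explicit by computing the personalised a posteriori risk
(PPR) - the Bayesian posterior probability of trisomy given the NIPT result.

## The model

Two Gaussians on the Z scale:

* **Euploid**: `Z ~ N(0, 1)`, by construction of the Z-score. About 99.7% of
  diploid samples fall within ±3 (`euploid_central_coverage(3)`).
* **Trisomic**: the extra chromosome copy is present only in the foetal
  (placental) component of the cell-free DNA, a fraction `f` (in percent) of
  the total. It raises the target chromosome's plasma fraction by `f/2`
  relative to the diploid mean. Measured in control standard deviations -
  the assay's coefficient of variation `CV`, also in percent of the mean -
  the expected Z-score of a trisomic sample is

  $$z_{exp} = \frac{f/2}{CV},$$

  and the observed Z-score is taken as `N(z_exp, 1)`: the trisomic cloud has
  the same unit spread as the controls, shifted by the signal-to-noise ratio
  of the assay. At `f = 6%` and `CV = 0.5%`, `z_exp = 6` and a threshold-3
  call detects `pnorm(6 - 3) = 99.87%` of trisomic samples; at `f = 4%` this
  drops to `pnorm(4 - 3) = 84.13%`. `nipt_sensitivity()` and `required_cv()`
  expose this arithmetic for assay design.

The evidence in an observed Z-score `z` is the likelihood ratio

$$LR(z) = \frac{p_{trisomic}(z)}{\phi(z)},$$

which for a known foetal fraction reduces to the closed form
`exp(z_exp * z - z_exp^2 / 2)`. The posterior follows from the odds form of
Bayes' theorem applied to the a priori risk `p`:

$$PPR = \frac{p \cdot LR}{p \cdot LR + 1 - p}.$$

The model is one-sided: only chromosomal excess is modelled. A Z-score below
`z_exp / 2` yields `LR < 1` and a posterior *below* the prior - evidence
against trisomy is reported as such, which is exactly what matters when
judging potential false negatives at low foetal fractions.

## The foetal fraction as a nuisance parameter

The foetal fraction is often unknown, or known only as a range. `niptppr`
treats it as a nuisance parameter with a prior that is a fixed value
(`ff_fixed`), a uniform range (`ff_uniform`), or a weighted mixture of
uniform ranges (`ff_mixture`), and integrates it out of the trisomic
likelihood:

$$p_{trisomic}(z) = \sum_k w_k \frac{1}{hi_k - lo_k}
  \int_{lo_k}^{hi_k} \phi\!\left(z - \tfrac{f/2}{CV}\right) df.$$

Because every component is uniform and the integrand is a Gaussian in a
linear function of `f`, each integral has an exact closed form,

$$\frac{1}{hi - lo}\int_{lo}^{hi} \phi\!\left(z - \tfrac{f/2}{CV}\right) df
 = \frac{2\,CV}{hi - lo}\left[\Phi\!\left(z - \tfrac{lo}{2CV}\right)
 - \Phi\!\left(z - \tfrac{hi}{2CV}\right)\right],$$

so no quadrature is needed: the marginal density is exact, deterministic and
free of convergence diagnostics. One numerical care is taken: when `z` lies
above the midpoint of the component's expected-Z range, the difference of
two `pnorm` values near 1 would cancel catastrophically, so the symmetric
form `pnorm(u_hi - z) - pnorm(u_lo - z)` is used instead, keeping both terms
in the accurately-represented tail. The likelihood ratio itself is assembled
in log space, so extreme Z-scores (the bundled cohort reaches 28.8, where
the euploid density underflows past 1e-180) remain well-defined. The test
suite cross-checks the closed form against a naive 100,000-node trapezoid
integration to 1e-6 and against the fixed-fraction exponential form to
1e-10.

### The default mixture

When nothing is known about the foetal fraction, the engine uses
`ff_default()`: a mixture of `U(1, 23)` with weight 0.4 and `U(6, 18)` with
weight 0.6 (percent). Mid-gestation foetal fractions span roughly 1-23% with
a typical value near 12%; the narrow component concentrates mass there while
the broad component deliberately keeps more weight on the extremes than a
Gaussian would. The extra weight at low fractions is a safety choice: low
foetal fraction is the dominant cause of weak trisomic signals, so
under-weighting it would overstate the reassurance of a modest Z-score. When
a range is half-specified, the missing bound is completed from the advised
limits of 1% and 23% (`ff_advised_low`/`ff_advised_high` in the
configuration) and the completion is noted in the batch output.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `cv_chr21` | % of mean | 0.5 | close to empirically measured chromosome-21 CVs |
| `cv_chr13`, `cv_chr18` | % of mean | 0.4 | higher read counts give these chromosomes better precision |
| `z_threshold` | Z | 3 | conventional positive-call cutoff (99.7% euploid coverage) |
| `ff_prior` | % | 0.4·U(1,23) + 0.6·U(6,18) | unknown-fraction default, see above |
| `ff_advised_low/high` | % | 1 / 23 | completion of half-specified ranges |

All are overridable per call, per sample row, or through a flat YAML/JSON
configuration (`read_config()`); command-line flags beat the file, which
beats the built-ins. Units are policed: a CV of 5 or more, or a foetal
fraction above 50, is rejected as an almost-certain fraction-vs-percent
mix-up rather than silently producing nonsense posteriors.

## A priori risks

`parse_prior()` accepts decimal probabilities and the ratio forms `1:n` and
`1/n`, both read as *1 in n* (probability `1/n`) - the reading under which
"1:1000" and "0.001" are the same number, as risk figures are quoted
clinically. The strict-odds alternative `1/(n+1)` is deliberately not used.
Age-based priors come from a maternal-age × gestational-age table via
`interpolate_risk()`, which performs plain bilinear interpolation on the
probability scale: exact at grid nodes, linear along rows and columns, and
refusing to extrapolate outside the table - a clinical-safety choice, since
risk tables are only trustworthy over their published hull. Interpolating on
a transformed scale (log-odds) was considered and rejected: the differences
are far below the precision of any published table, and the untransformed
scale keeps the node-exactness property trivially auditable. No clinical
risk table is bundled; the package ships a synthetic fixture
(`synthetic_risk_table_t21.csv`, values invented but of realistic magnitude)
solely to exercise the loader, and users supply their own published tables.

## Reporting

The raw posterior is kept at full precision in the `ppr` column; the
clinician-facing string rounds to an integer percent between 1 and 99,
reports `"<1"` and `"<0.1"` below those marks, and caps at `"99.9"` where
rounding would reach 100. A screening posterior of 1 - 1e-12 is still a
screening result, and displaying "100%" would misrepresent it as diagnostic
certainty.

## The simulator and what passing its checks means

`simulate_cohort()` draws cohorts from the generative model itself: trisomy
status at a chosen prevalence, a foetal fraction per sample from the chosen
prior, then `z ~ N(0,1)` or `N(z_exp(f), 1)`. Draws come from one seeded
generator in a fixed order (status, fraction, z), so cohorts are exactly
reproducible. Because generator and scorer share the model, three things
must hold and are checked on cohorts of 100,000 samples at fixed seeds
(seconds of runtime): the empirical detection rate matches
`pnorm(z_exp - 3)` within three binomial standard errors; the euploid
within-±3 rate matches 0.9973 likewise; and the posterior is *calibrated* -
`calibration_check()` bins samples by PPR and finds the observed trisomy
frequency within three standard errors of the mean PPR in every occupied
bin, while a deliberately mismatched scorer prior is flagged (the negative
control).

What passing does **not** show: the simulator reproduces the Z-score
abstraction only. Read counts, GC bias, sequencing error, confined placental
mosaicism, maternal copy-number variants and the correlation between foetal
fraction and aneuploidy status are all outside the model, and each can move
real-world performance away from these idealised figures. The simulation
results validate the software against its own model, not the model against
biology.

## Known limitations

* Only autosomal trisomies 13, 18 and 21; no sex-chromosome aneuploidy,
  microdeletions, or mosaicism quantification. Mosaicism plausibly widens
  the trisomic Z distribution; with no quantitative basis for choosing a
  larger spread, the unit standard deviation is used throughout.
* The CV is always taken as known. Marginalising an *unknown* CV would need
  a prior over assay precision that there is no principled basis to fix;
  supply a measured CV or the per-chromosome default.
* When the foetal fraction is wholly unknown, the engine marginalises the
  default mixture inside the likelihood ratio. Alternative conventions exist
  (for instance averaging posteriors rather than likelihoods, or
  range-to-bound heuristics), and published calculators are not always
  explicit about theirs, so figures from other tools for the unknown-fraction
  case need not match to the percent. The density-marginalisation used here
  is the standard Bayesian treatment of a nuisance parameter and is the one
  whose calibration the simulator can and does verify.
* Z-scores are taken as given; computing them from reads (normalisation, GC
  correction) is upstream of this package.
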