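---
title: "Models and methods: variance polygenic scores and matched difference-in-differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(varGxE)
```

This vignette is the package's own account of the statistics it
implements: the models, the estimation algorithms, the tunable
parameters, what the synthetic cohort generator does and does not
emulate, and the design choices made where the design was genuinely
open. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific question

Genome-wide association methods usually estimate effects on a trait's
conditional *mean*. A variant can instead (or additionally) affect the
conditional *variance* — a vQTL. A polygenic score built from such
dispersion effects (a vPGS) indexes phenotypic plasticity: how strongly
an individual's phenotype responds to environmental perturbation. The
package pairs a vPGS for BMI with a quasi-experimental environmental
shock — involuntary job loss caused by a business closure — to ask
whether genetic plasticity moderates the effect of the shock. Business
closures are attractive as a shock because they are plausibly unrelated
to any individual worker's characteristics, and because treatment can be
shown empirically to be unrelated to genotype (no gene–environment
correlation), which a balance check on the scores verifies in every run.

## 2. Polygenic scores

`compute_pgs()` forms `PGS_i = Σ_j β_j x_ij` over the variants shared
between a genotype matrix and a weight table, where `x_ij` counts the
weight's effect allele. If the genotype file counts the opposite allele
the dosage is flipped to `2 − x`; variants whose alleles match neither
genotype allele are skipped and counted in the scoring report. Scores
are standardized (mean 0, SD 1, `n − 1` denominator) before entering any
model, so all coefficients are per-SD-of-score. Fractional dosages in
[0, 2] (imputed genotypes) are accepted.

`greedy_clump()` implements PLINK-style clumping against a supplied
pairwise r² table: variants are visited in ascending p-value order and
kept unless they sit within `window_kb` of an already-kept variant on
the same chromosome with r² at or above the threshold (defaults 0.1 and
1000 kb, the conventional values). Ties are broken by
(p, chromosome, position, id), which makes the output independent of
input row order. Clumping is optional and off by default, matching the
use of pre-clumped summary statistics. A supplied r² table is used
rather than LD computed from a reference panel, which is out of scope;
consequently the clumping tests exercise the rule, not realistic LD.

`validate_mpgs_growth_curve()` checks a mean score the way longitudinal
cohorts do: stage 1 fits, per person, `BMI_it = b0_i + b1_i age +
b2_i age² + e` by OLS and keeps the intercepts; stage 2 regresses the
intercepts on the score plus covariates and reports the score's
incremental R². Two open choices were resolved as follows: the model is
fitted as a transparent two-stage procedure rather than a joint mixed
model — the two-stage version is directly testable, and the suite
recovers a planned R² to ±0.015 — and age is centered at the sample
mean, so the intercept is interpretable as expected BMI at the average
age. Persons with fewer than three waves cannot identify a
quadratic and are excluded with a count.

## 3. The double generalized linear model

The validation model for a variance score `G` is

$$y_i = \gamma_0 + \gamma_1 G_i + X_i\Theta + \varepsilon_i,\qquad
\varepsilon_i \sim N\!\big(0,\ \exp(\alpha_0 + \alpha_1 G_i + X_i\Phi)\big)$$

`α1` is the parameter of interest: `exp(α1)` multiplies the residual
variance per SD of score, so the SD changes by
`100·(√exp(α1) − 1)` percent (`interpret_sd_change()`).

`fit_dglm()` uses the standard alternating algorithm for this model
class:

1. **Mean step.** Weighted least squares of `y` on the mean design with
   weights `exp(−Z'α)`.
2. **Variance step.** A gamma GLM with log link fitted to the
   leverage-adjusted squared residuals `d_i/(1 − h_i)` with prior
   weights `(1 − h_i)/2`, where `h_i` are the hat values of the weighted
   mean fit (the REML-style correction for the degrees of freedom the
   mean model consumes).
3. Iterate until the Gaussian log-likelihood changes by less than `tol`
   (default 1e-8, `max_iter = 50`); non-convergence returns a flagged
   result with a warning rather than an error.

Wald inference for `α1` uses the variance-submodel information,
`Var(α̂) = 2 (Z' diag(1−h) Z)^{-1}`; for a standardized score this gives
the familiar `SE ≈ √(2/n)` bound, which the tests verify. Numerical
guards: squared residuals are floored at machine precision before the
gamma step (the log link cannot take an exact zero), hat values are
capped below 1, and singular designs abort naming the collinear columns.

With `reml = FALSE` the variance step uses raw `d_i` with weights 1/2;
the two steps then coordinate-ascend the *exact* Gaussian likelihood, so
the likelihood trace is provably non-decreasing — the property suite
asserts monotonicity on that variant, because the leverage-adjusted
default trades exact monotonicity for small-sample bias correction.
With an intercept-only variance submodel the mean step has constant
weights, so the mean coefficients coincide with OLS (asserted to 1e-8).

Phenotypes are rank inverse-normal transformed before variance
modelling (`inverse_normal_transform()`): `Φ⁻¹((r_i − 3/8)/(n + 1/4))`,
the Blom offset, with average ranks for ties. Blom is the common
epidemiological default among rank offsets, and the choice only affects
discretized phenotypes through the tie rule.

`dispersion_scan()` is the package's stand-in for a heteroskedastic
mixed-model vGWAS: each variant's dosage is the score in a DGLM fit on
unrelated samples. Relatedness handling, random effects, and
meta-analysis across strata are deliberately out of scope; the scan is
documented as a simplified training step, and its calibration (uniform
null p-values) and power (a planted vQTL of 0.3 log-variance units per
allele at n = 20,000 is detected at p < 1e-3) are tested rather than
assumed.

## 4. Propensity scores, kernel matching, and balance

Treatment propensity is a probit on baseline covariates. Missing
covariate values are set to zero with a companion indicator column per
covariate, so matching is on observed values and on the missingness
pattern; one shared design builder applies the same coding in the
propensity and outcome models, keeping the two stages consistent. Common support keeps a treated
observation iff its propensity lies in the closed `[min, max]` interval
of control propensities; controls are never dropped.

Matching weights use the Epanechnikov kernel `K(u) = 0.75(1 − u²)` on
`|u| ≤ 1` with bandwidth 0.06 (the published setting), normalized within
treated unit over the controls of the same exact-match stratum (survey
year × sex), with replacement. Treated units with zero kernel mass are
flagged off support and excluded from the analytic sample, with counts
in the run report. The per-control aggregate `W_j = Σ_i w(i,j)` is what
enters the outcome regression; a renormalization of the aggregate
weights is deliberately not applied (raw `W_j` is passed through), since
WLS coefficients are invariant to a global rescaling.

Standardized bias is `100·(X̄_T − X̄_C)/√((s²_T + s²_C)/2)`. The
denominator uses the average of the two group variances — occasionally
this formula is printed with a minus sign under the radical, but the
average-of-variances form is the standard definition in the matching
literature and is what the package computes. Matched
balance rows use the kernel weights for controls and restrict treated
statistics to the on-support treated; the denominator always uses the
unmatched variances so matched and unmatched rows are on one scale.
The two-sample test is Welch's unequal-variance form (robust to the
groups' different spreads), with a Kish effective sample size for the
weighted control group. A covariate is flagged imbalanced when
|SB| > 5% or p < 0.05.

## 5. The matched difference-in-differences regression

The analytic frame has one observation per treated person (the
post-closure wave, with the prior wave's BMI and covariates attached as
baseline) and one observation per control person per eligible wave —
controls legitimately appear in multiple waves and are treated as
independent observations by default, with a cluster-robust-by-person
option (`cluster = "person_id"`) available. The outcome model is

$$BMI_{it} = \alpha + \lambda BC + \phi\, mPGS + \vartheta\, BC{\times}mPGS
+ \theta\, vPGS + \delta\, BC{\times}vPGS + \tau BMI_{it-2} + X'\beta
+ \varepsilon_{it}$$

estimated by WLS with treated weight 1 and control weight `W_j`, and an
HC1 sandwich covariance (the common small-sample robust correction,
and the one most software reports by default). Because the propensity covariates also enter the regression,
the estimator is doubly robust: consistent if either the propensity
model or the outcome model is correct.

`att_by_genotype()` evaluates `ATT(m, v) = λ + ϑm + δv` with
delta-method intervals from the robust covariance;
`predict_bmi_by_genotype()` evaluates the full linear predictor at
stated (treated, m, v) with all other covariates at their weighted
sample means — including `τ ·` (lagged BMI at that profile). The
profile (weighted means over the matched sample) is the package's
documented choice.
`did_fit_from_coefs()` lets the same algebra run on published
coefficient tables. FDR adjustment (`bh_fdr()`, the step-up procedure)
is applied per results table, mirroring the asterisk convention of a
regression table; the family is a function argument, not a global.

The event-time study replaces `λ BC` with event-time indicators at
−4, 0, +2 years (reference −2, the wave before the loss); the full
sample variant controls additionally for the vPGS, and stratified
variants split at the vPGS median over the distinct persons of the
analytic sample, ties to the lower stratum. The baseline matching
weights are reused for all event times (re-matching per event time is
the flagged alternative); treated persons keep weight 1 at each of
their event observations.

## 6. The synthetic cohort generator

The generator produces the statistical structure the analysis assumes,
with every parameter retained for recovery tests.

* **Genotypes**: biallelic dosages `Binomial(2, maf)` under
  Hardy–Weinberg equilibrium, maf uniform on `maf_range`
  (default 0.05–0.5), linkage equilibrium between variants.
* **Architecture**: disjoint (by default) mean- and variance-causal
  variant sets with Gaussian per-allele effects — disjointness emulates
  the decorrelation of mean and dispersion effects that the vGWAS
  method is designed to achieve, without implementing the mixed model.
* **Phenotype**: `y = Σβx + ε`, `ε ~ N(0, exp(α0 + Σαx))` — the DGLM's
  own generative form.
* **Panel**: six biennial waves; baseline age uniform on 50–70 (the
  cohort restriction of the motivating design); BMI follows a
  mean-reverting AR(0.9) process around a person level
  `μ_i = 27.5 + 0.8·mPGS_i` (≈7% of between-person level variance from
  the mean score, the realistic share), with per-wave process noise of
  `bmi_noise_sd = 1` kg/m² — a realistic magnitude for self-reported
  BMI; it is a config parameter, not an asserted value.
* **Confounding**: a covariate index (income, tenure, smoking, sex,
  age) shifts each person's steady-state BMI at `drift_per_wave = 0.3`
  kg/m² per SD per wave, and the same covariates — plus firm size and a
  service-industry indicator with larger loadings, since closures are
  firm events — drive a probit latent index for treatment
  (`confounding_strength = 2`, person-level treated fraction 0.1,
  matching the motivating cohort's person-level rate). Firm-dominated
  selection also gives the propensity distribution enough spread for a
  0.06-bandwidth kernel to be informative — i.e. it makes the published
  matching design well-posed on the synthetic cohort. A raw pre/post
  contrast is therefore biased (the confounders predict both selection
  and BMI drift) while matching plus regression adjustment is not.
* **Treatment effect**: `λ + ϑ·mPGS + δ·vPGS` (defaults −0.1, 0, 0.25
  kg/m²) enters the AR state at the event wave and decays thereafter — a
  transient shock, consistent with an event study that finds no
  persistence two years on. `att_stratum = "below_median"` confines the
  effect to the lower half of the vPGS distribution for the stratified
  event-study check.
* **Assignment** never sees genotype, so the absence of
  gene–environment correlation holds by construction and is verified
  empirically (score balance) each run.

Two deliberate idealizations deserve emphasis. First, there is no
permanent unobserved person heterogeneity: person levels are functions
of the genetic score and observed covariates, and persistent individual
differences beyond that arise from the AR state. The lagged-outcome
regression the design estimates *assumes* no unobserved permanent
confounder; the generator therefore emulates the structure under which
the estimator is consistent, and a passing recovery test certifies the
estimator under those assumptions — not robustness to fixed-effect-style
confounding in real data. Second, variants are in linkage equilibrium
and treatment is exactly probit: passing tests show correct
implementation and calibration, not robustness to LD, attrition,
survey design, or mortality selection, none of which are emulated.

In the orchestrated workflow the dispersion-scan-trained weights are
used for the score-validation arm (train on the 80% split, score and
validate on the 20% split), while the causal arm scores the cohort with
the true architecture weights. At desk-scale variant counts the trained
dispersion weights are noise-dominated and would attenuate the
interaction estimate mechanically; using oracle weights keeps the causal
recovery test about the causal machinery. This simulator privilege is
unavailable in real data, where attenuation from noisy scores is part of
the measurement problem.

## 7. Problem sizes and numerical choices

The validation suite runs at the generator's study conditions:
n = 20,000 individuals for matching balance, DiD recovery (50
replicates), and the dispersion scan; n = 50,000 × 20 replicates for
DGLM accuracy and n = 5,000 × 200 for interval coverage; n = 3,000 ×
200 replicates for event-study pre-trend calibration. These sizes were
chosen so each check is statistically meaningful for its tolerance
(e.g. the DGLM accuracy band of ±0.01 is ≈7 Monte-Carlo standard errors
at those settings) while the whole suite completes in minutes on one
core.

Other numerical conventions collected in one place: kernel weights sum
to 1 per treated unit to 1e-10 and are invariant to a constant shift of
all propensities; score standardization is idempotent; clumping and the
whole workflow are deterministic under a fixed seed (a single global
seed fans out to named per-stage child seeds, all below 2³¹); the
treated/control boundary case `P = max(control P)` is on support (closed
interval); the vPGS median split assigns ties to the lower stratum;
BH-FDR adjusted p-values are capped at 1.

## 8. Known limitations

* The dispersion scan ignores relatedness; results stand in for, and do
  not reproduce, a heteroskedastic mixed-model analysis.
* Kernel matching inherits boundary bias where the control propensity
  density is steep; the residual standardized bias after matching is
  diagnosed in the balance table rather than corrected.
* The event-study at +2 years reuses the baseline match; re-matching at
  each event time is a design alternative the package flags but does
  not implement.
* The generator's realism is structural, not numerical: its defaults
  emulate magnitudes (BMI level ≈27.5, ≈7% mean-score R², ≈10% treated,
  τ ≈ 0.9), but no synthetic quantity should be read as a substantive
  estimate about any real cohort.
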