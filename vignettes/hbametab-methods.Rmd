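---
title: "Methods: ethnicity-stratified Bayesian lognormal regression of metabolites on HbA1c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ethnicity-stratified Bayesian lognormal regression of metabolites on HbA1c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Circulating amino acids, ketone bodies and lipoprotein subclass particle
concentrations shift with chronic glycemia, and the shape of that
relationship differs between ethnic groups. The analysis this package
implements asks, within each of three groups (Dutch with European, Ghanaian
and African Surinamese background), how the concentration of each of 24
NMR-measured metabolites changes per 10 mmol/mol of HbA1c, separately for
prediabetic and diabetic participants and for men and women, adjusted for
sex, age, diabetic status and BMI. Because the two source cohorts were
sampled and measured at different times, absolute metabolite levels are
never compared across groups; only within-group associations are reported.

# Model

Each metabolite is fitted independently (24 separate models, matching the
per-metabolite reporting convention; no multivariate outcome model is
attempted). Concentrations are positive and right-skewed, hence a lognormal
likelihood: for participant $i$ with ethnicity $e$, female indicator $f$,
diabetic indicator $d$,

$$\log y_i \sim \mathrm{Normal}(\mu_i, \sigma),\qquad
\mu_i = \alpha_e + (\beta_{e,d} + \eta f)\,x_i + \gamma_s f + \gamma_a a_i
+ \gamma_d d + \gamma_b b_i,$$

where $x_i$, $a_i$, $b_i$ are HbA1c, age and BMI centered at the full-cohort
mean and scaled by 10 mmol/mol, 10 years and 5 kg/m². Centering uses one
center for the whole cohort, not per group: per-group centering would change
what the group-specific intercepts mean. A coefficient $\beta$ is the change
in log concentration per 10 mmol/mol HbA1c; $e^\beta - 1$ is the implied
proportional concentration change and is reported alongside.

**Slope structure.** The published figures show separate coefficients per
ethnicity × sex × diabetic status, but male and female intervals within a
subgroup are near-identical shifts of one another. The default
parameterization therefore uses one slope per ethnicity × status cell plus a
single additive female offset $\eta$ (7 slope parameters); a
`fully_crossed` option (12 slopes, no $\eta$) is available when that
assumption is unwanted. A diabetic-status main effect $\gamma_d$ is included
in addition to the status-specific slopes; whether the original analysis
included it is not documented, and including it is the conservative choice
(it only absorbs level differences between strata).

**Priors.** "Regularizing priors" were unspecified upstream; the package
uses Normal(0, 1) on all intercepts and coefficients of scaled covariates
and Exponential(1) on $\sigma$, all configurable via `prior_spec()`. At the
fitted sample sizes (hundreds of observations per group) these priors are
weakly informative: posterior shrinkage of the intercepts (whose true scale
is log-concentration, of order 4–6) is of order $SE^2/(SE^2+1) < 10^{-3}$.

# Missing data

Two missingness mechanisms affect the outcome and are both treated by full
Bayesian imputation — every missing cell is a parameter with a posterior
distribution, not a plugged-in value:

* **Below the limit of detection.** The imputed concentration is constrained
  to $(0, m)$ where $m$ is the minimal *observed* value of that metabolite
  over the whole cohort (no stratification — the bound is a property of the
  assay, not of a subgroup). Internally the cell is sampled as a scaled
  logit, $z = m\,\mathrm{logit}^{-1}(u)$, with the log-Jacobian
  $\log m + \log p + \log(1-p)$ added to the unconstrained density, so the
  constrained-space density is exactly the truncated lognormal likelihood.
* **QC-rejected.** The imputed concentration is a free positive parameter
  whose only density is the lognormal likelihood itself — equivalent to
  marginalizing the cell out. Sampled as $\log z$ with Jacobian $\log z$;
  on the log scale the two terms cancel into a plain normal density.

Missing covariates (HbA1c, BMI) are imputed on the raw measurement scale
from $\mathrm{Normal}(\mu_e, s_e)$ with ethnicity-specific mean and SD,
because the hyperprior rates are stated in raw units: Exponential(0.025)
and Exponential(0.2) for the HbA1c mean and SD (prior means 40 and
5 mmol/mol, matching the known population moments) and Exponential(0.04)
and Exponential(0.2) for BMI. Note the BMI mean rate 0.04 implies a prior
mean of 25 kg/m² while the motivating population mean is nearer 27; the
printed rate is used as-is. All missingness is assumed missing at random.

**Non-centered covariate imputation.** The hyperparameters $(\mu_e, s_e)$
are informed only by the handful of imputed values, which creates a funnel
($s_e \to 0$ with the imputed values collapsing onto $\mu_e$) that defeats a
shared-step-size sampler: in early testing a study-scale fit showed split-R̂
up to 2.8 and hundreds of divergent transitions. The package therefore
samples standardized residuals $r \sim \mathrm{Normal}(0,1)$ and sets
$x = \mu_e + s_e r$, which is the same model with benign geometry; the same
fit then yields split-R̂ < 1.01 on every parameter and no post-warmup
divergences.

# Inference

The sampler is Hamiltonian Monte Carlo written for this model, with exact
analytic gradients of the unconstrained log-posterior (verified against
numerical differentiation in the test suite at tolerance $10^{-4}$ across
all slope structures). Defaults follow the published analysis: 4 chains of
2000 iterations. The warmup/sampling split within those 2000 is not
documented upstream; the package adopts the referenced software's
convention of discarding the first half, so 1000 draws per chain are
retained — both knobs are explicit in `sampler_config()`.

Warmup adapts the step size by dual averaging (target acceptance 0.8) and,
at 80% of warmup, estimates a diagonal mass matrix from the preceding
window's draws (regularized toward unity) before re-adapting the step size.
The number of leapfrog steps is jittered uniformly over the upper half of
`leapfrog_steps` (default 16) to avoid periodic trajectories. A transition
whose energy error exceeds 1000, or that reaches a non-finite density or
gradient, counts as a divergence and is rejected; post-warmup divergences
are reported on the fit object. Chains are initialized by jittering around
empirical moments of the observed data (group means of log concentration,
the residual spread, the covariate centers) rather than by pure prior
draws: prior draws put intercepts far from the data's log-concentration
scale and waste warmup; up to 10 re-initializations are attempted if the
initial density is not finite.

Summaries pool retained draws across chains: posterior mean, SD,
equal-tailed 95% interval as the empirical 2.5%/97.5% percentiles (not HPD —
percentile intervals are the referenced software's default summary),
split-chain R̂, and an effective sample size from summed autocorrelations
with Geyer's initial-positive-sequence truncation, capped at the total draw
count. Conventions for degenerate cases: identical constant chains give
R̂ = 1 and ESS = total draws; constant-but-distinct chains give R̂ = ∞.

Three independent oracles guard the sampler in the test suite: (i) a
conjugate subcase (one homogeneous subgroup, covariates at their centers,
$\sigma$ held fixed via `model_spec(fixed_sigma=)`) where the intercept
posterior is available in closed form; (ii) the diffuse-prior limit with
complete data, where the posterior mode (computed by BFGS on the same
log-posterior, `map_estimate()`) must match least squares on log
concentration to $10^{-3}$; (iii) parameter recovery and interval coverage
on synthetic cohorts.

# The synthetic cohort generator

The generator exists because the motivating data are access-controlled. Its
defaults *are* the study conditions: group sizes 301/255/217; female
fractions 0.445/0.525/0.659; per-group age, BMI and HbA1c means and SDs from
the published characteristics table; diabetic fractions 0.126/0.388/0.705.
Age, BMI and HbA1c are drawn truncated-normal (positive) — the published
table gives only means and SDs, so normality is an assumption of the
generator, not a reported fact. Diabetic participants draw HbA1c shifted
+15 mmol/mol so that status and glycemia correlate; fasting glucose is drawn
consistent with the assigned status (diabetic > 7 mmol/L, prediabetic in
(5, 7]), and only prediabetic/diabetic participants are emitted, matching
the binary strata of the reported results. Metabolite concentrations are
generated by the *same* `linear_predictor()` the model fits (with centers
implied by the configured means), plus Normal(0, $\sigma$) log-scale noise —
with $\sigma = 0$ the generator is an exact evaluation of the model, which
the tests exploit.

Ground-truth slopes echo the reported per-analyte magnitudes (0.14 for
isoleucine and −0.29 for acetoacetate in prediabetic Europeans, up to 0.47
for extremely large VLDL, ±0.02–0.1 elsewhere), attenuated by a fixed grid
for diabetics and the non-European groups; $\eta = 0.01$, modest covariate
effects, and $\sigma = 0.3$ per metabolite, consistent with the width of the
published intervals at the published sample sizes. Missingness defaults are
a 5% below-LOD quantile, 2% QC rejection and 2% missing covariates —
Nightingale-style panels rarely reject more; the recovery validations use
the heavier 10%/5% setting. The LOD is defined per metabolite as an
empirical quantile of the simulated values rather than an absolute
concentration, which keeps the censored fraction controllable across
analytes; QC rejection is simulated MCAR, a special case of the MAR
assumption the model makes, so generator and model assumptions cannot
disagree. Ground truth (parameters, per-metabolite LODs, masked-cell
indices, seed) is always exportable as a JSON sidecar.

What the generator does **not** emulate: metabolite–metabolite correlation
(each analyte is simulated and fitted independently), assay batch effects,
medication/diet/activity covariates, non-normal covariate distributions,
and informative (MNAR) missingness. Passing recovery and coverage tests
therefore demonstrates the estimator is correct *under its own
assumptions*; they say nothing about robustness to violations real cohort
data may contain.

Five of the eight amino acids on the panel are fixed by the motivating
analysis (isoleucine, leucine, valine, tyrosine, alanine); the upstream
description never names the other three, so the defaults (phenylalanine,
glutamine, histidine) are documented placeholders and replaceable via
`default_panel(amino_acids=)`.

# Reporting

`coefficient_table()` emits one record per metabolite × ethnicity × sex ×
status (12 per metabolite, 288 for the default panel), with subgroup slopes
composed draw-wise — the female slope interval is the percentile interval
of $\beta_{e,d} + \eta$ over draws, never a sum of summaries. Whether the
original figures plot composed subgroup slopes or separately fitted
stratified models is not stated; composed-draw reporting is the default
here and is what the record layout documents. No multiple-testing
adjustment is applied, mirroring the original presentation; a flag column
marks intervals excluding zero, since exactly those are narrated. The
baseline-characteristics table uses the tie-corrected Kruskal–Wallis test
(χ² reference with $k-1$ degrees of freedom) for continuous rows and the
uncorrected χ² test of independence for categorical rows, as footnoted in
the original table; single-group inputs and zero-variance categorical rows
are rejected as errors rather than silently dropped.

# Problem sizes used in the validations

The packaged validations run at sizes chosen to make the checks sharp but
routine on a single CPU: gradient and density-identity checks on cohorts of
~200; the conjugate oracle at $n = 150$ with 4×2000 iterations; slope
recovery at the full study composition ($n = 773$, 10% below-LOD, 5% QC,
4×2000); interval coverage over 50 replicates at $n = 200$ with 4×1000;
the empirical-slope generator check at $n = 20\,000$; and the full-panel
report shape on a reduced cohort with short chains, where only the record
count and layout are asserted.

# Known limitations

* The sampler is plain HMC with jittered trajectory lengths, not NUTS;
  mixing is verified empirically (R̂, ESS) rather than guaranteed by
  dynamic termination.
* One model per metabolite: no sharing of information across analytes, no
  multivariate residual structure.
* The covariate-imputation hyperparameters are informed only by the imputed
  cells (plus their hyperpriors), following the stated model; with very few
  missing covariates their posteriors remain close to the hyperpriors.
* Equal-tailed intervals can include regions of negligible density for
  strongly skewed marginals (e.g. imputed below-LOD cells near their
  bounds); the regression coefficients themselves are near-symmetric.
* The HbA1c percent → mmol/mol conversion uses the IFCC master equation
  rounded to one decimal, which is the convention of the source tables, not
  a statement about assay precision.
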