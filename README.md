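# hbametab

Bayesian lognormal regression of circulating metabolite concentrations on
glycated hemoglobin (HbA1c), with ethnicity-specific intercepts and slopes
and full Bayesian handling of two kinds of missing metabolomics data. The
package is aimed at epidemiologists and biostatisticians analysing NMR
metabolomics panels (amino acids, ketone bodies, lipoprotein subclass
particle concentrations) against glycemia in multi-ethnic cohorts, and at
anyone who wants a tested, self-contained implementation of this model class
to validate against.

Because the motivating cohort data (three Dutch ethnic groups: European,
Ghanaian, African Surinamese) are access-controlled, the package ships a
synthetic cohort generator that reproduces the study conditions — group
sizes 301/255/217, the published sex/age/BMI/HbA1c/diabetes composition,
lognormal metabolites with subgroup-specific slopes, below-LOD censoring and
QC rejection — together with exported ground truth, so every part of the
pipeline is verifiable by parameter recovery and interval coverage.

## The model

For participant *i* with ethnicity *e*, sex *f* (1 = female), diabetic
status *d* (1 = diabetic, 0 = prediabetic) and metabolite concentration
*y<sub>i</sub>* > 0:

    log y_i ~ Normal(mu_i, sigma)
    mu_i = alpha[e] + (beta[e,d] + eta * f) * hba1c_u
           + gamma_sex * f + gamma_age * age_u + gamma_diab * d
           + gamma_bmi * bmi_u

HbA1c, age and BMI are centered at the cohort mean and scaled so one unit
means 10 mmol/mol, 10 years and 5 kg/m², respectively; a slope *beta* thus
reads as the change in log concentration per 10 mmol/mol HbA1c, and
`exp(beta) - 1` as the proportional concentration change. A `fully_crossed`
option replaces the shared female offset *eta* with one slope per
ethnicity × status × sex cell.

Missing data are parameters of the joint posterior:

* concentrations **below the limit of detection** are imputed constrained to
  (0, minimal observed value of that metabolite);
* **QC-rejected** concentrations are imputed as free positive values under
  the lognormal likelihood (marginalized out);
* **missing HbA1c/BMI covariates** are imputed from normal distributions
  with ethnicity-specific mean and SD carrying exponential hyperpriors —
  Exponential(0.025) and Exponential(0.2) for HbA1c (prior means 40 and
  5 mmol/mol), Exponential(0.04) and Exponential(0.2) for BMI.

Regularizing priors are Normal(0, 1) on coefficients and Exponential(1) on
the residual SD. Inference is Hamiltonian Monte Carlo (analytic gradients,
dual-averaging step size, diagonal mass adaptation), by default 4 chains ×
2000 iterations with the first 1000 per chain discarded as warmup. Summaries
are posterior means with equal-tailed 95% credible intervals, split-R̂ and
effective sample size.

## Worked example

```r
library(hbametab)

cfg <- sim_config(seed = 42)          # the study conditions, 773 participants
sim <- simulate_cohort(cfg)
print(sim$cohort)
#> <cohort> 773 participants x 24 metabolites
#>   groups: african_surinamese=217, european=301, ghanaian=255
#>   cells:  observed=17275, below_lod=936, qc_rejected=341

fit <- fit_metabolite(sim$cohort, "isoleucine",
                      sampler = sampler_config(seed = 1))
print(fit)
#> Bayesian lognormal regression fit: isoleucine
#>   n = 773 (719 observed, 39 below LOD, 15 QC-rejected)
#>   slope structure: ethnicity_x_diabetes_plus_sex_offset
#>   4 chains x 2000 iterations (1000 warmup); 0 divergences
#> HbA1c slopes (per 10 mmol/mol, posterior mean [95% CI]):
#>   european           prediabetic male    0.110 [ 0.066,  0.156]
#>   european           prediabetic female  0.122 [ 0.076,  0.169]
#>   european           diabetic    male    0.075 [-0.045,  0.191]
#>   ...
```

The generating slope for prediabetic Europeans was 0.14; the posterior mean
0.110 [0.066, 0.156] recovers it within its credible interval. Slopes
convert to proportional changes via `proportional_change()`:

```r
sl <- subgroup_slope(fit, "european", "male", diabetic = FALSE)
100 * proportional_change(mean(sl))
#> 11.6   # percent concentration increase per 10 mmol/mol HbA1c
```

`coefficient_table()` assembles the 12 subgroup records per metabolite
(drawing the female slopes draw-wise), `summarize_characteristics()`
produces the per-group baseline table with Kruskal–Wallis / χ² P values, and
`run_pipeline()` runs cohort → scaling → 24 fits → coefficient/
characteristics CSVs + manifest in one call. A thin command-line wrapper
with `simulate` / `fit` / `characteristics` subcommands lives in
`inst/scripts/hbametab-cli.R`.

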