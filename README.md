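# corthick

Covariate-adjusted analysis of regional cortical thickness for
observational neuroimaging cohorts. The package targets a common
situation in lifespan brain-structure studies: a subject variable of
interest (years of education, or a cognition composite) whose plausible
effect on cortex is small, distributed, and entangled with age, gender
and in-scanner head motion. It implements three complementary analyses
over 68-region (Desikan–Killiany) thickness tables:

- **Region-wise GLM** — per region,
  `thickness ~ 1 + education + gender + cognition + rFD + age` with
  Z-standardized covariates, two-sided t-tests and Benjamini–Hochberg
  FDR control per covariate across regions.
- **Variance permutation test** — after residualizing thickness on the
  nuisance covariates, a median split on the covariate of interest and a
  region-wise log variance ratio `log F = log(Var_HIGH / Var_LOW)`,
  tested two-tailed against a permutation null in which the
  thickness-to-subject assignment is shuffled and the residualization
  recomputed each iteration.
- **Adjusted PCA-regression** (Scaled Subprofile Model variant) — the
  projector `I − C(CᵀC)⁻¹Cᵀ` removes the confounders from both the
  (grand-mean-removed) thickness array and the dependent variable; PCA
  of the residualized array, leave-one-out PRESS selection of the number
  of leading components, a unit-L2-norm loading pattern `v = V β`,
  subject scores `w = rTHXᵀ v` (orthogonal to every confounder by
  construction), bootstrap percentile intervals on the loadings, and a
  regression of the pattern-orthogonal residual signal
  (`RESS = mean(E²)` per subject, where `rTHX = v wᵀ + E`) on all
  covariates.

A synthetic-cohort generator (`sim_config()`, `generate_subjects()`,
`generate_thickness()`) with known ground truth — realistic covariate
correlations, region-wise effects, an embedded mixed-sign education
pattern, optional age-dependent residual variance — backs every stage
with parameter-recovery and calibration tests. See the methods vignette
(`vignettes/cortical-thickness-patterns.Rmd`) for the model details and
design rationale.

## Worked example

```r
library(corthick)

cfg <- sim_config(seed = 20260901, age_hetero_slope = 0.03)
subjects <- generate_subjects(cfg)
thx <- generate_thickness(subjects, cfg)$thickness
cov <- standardize_covariates(subjects)

fit <- ssm_pattern(thx, cov, dv = "education", k_max = 15,
                   n_boot = 10000, seed = 42)
fit$K                 # PRESS-selected number of components
fit$pattern$fit_R     # score-education correlation
subset(fit$bootstrap, robust)[1:4, ]
fit$ress_stats
```

On this simulated cohort the chain selects K = 1 and finds a
score–education correlation R = 0.1777 (p = 0.0008); the dominant robust
loadings recover the planted pattern geometry — positive on the right
isthmus (+0.538 [0.486, 0.567]) and posterior cingulate (+0.450), and
negative on the right superior temporal gyrus (−0.410) and temporal pole
(−0.503) — and the RESS regression shows the planted age-dependent
residual variance as a positive age effect (T = 4.79, p = 2.4e-06) with
all other covariates null. Subject scores correlate with the confounders
at machine zero, as guaranteed by the projector.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `05_recovery.R`) that write their tables
under `results/`; `run_pipeline()` executes all stages from one config
and emits a JSON manifest.

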