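---
title: "Covariate-adjusted analysis of regional cortical thickness"
author: "corthick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted analysis of regional cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corthick)
```

## The problem

Whether early-life education leaves a measurable trace on the adult
cortex is hard to settle with region-by-region tests: education, general
cognition, age, gender and even in-scanner head motion are mutually
correlated in any observational cohort, and plausible education effects
are an order of magnitude smaller than ageing effects. `corthick`
implements a three-pronged analysis of region-averaged cortical thickness
(the 68 Desikan–Killiany regions, in mm) against these five subject
variables:

1. **Region-wise multiple regression** with Benjamini–Hochberg FDR
   control, asking where single regions relate to single covariates.
2. **A median-split log variance-ratio permutation test**, asking whether
   the *inter-subject spread* of residual thickness differs between
   subjects above and below the median of a covariate of interest.
3. **A covariate-adjusted PCA-regression** (a Scaled Subprofile Model
   variant), asking whether a *distributed* loading pattern — possibly
   with mixed signs — relates to education (or cognition) once every
   other covariate has been projected out of both sides.

Because no subject-level imaging data can ship with the package, a
synthetic-cohort generator with known ground truth accompanies the
analyses; every stage is validated by parameter recovery and calibration
on simulated cohorts.

## Data model

A `subject_table` carries `subject_id`, `age` (years), `gender`
(1 = men, 2 = women), `education` (years), `rfd` (mean relative
framewise displacement from whatever functional runs are available,
averaged within runs across volumes and then across runs with equal run
weights), and total cognition. Total cognition is the mean of the
Z-scores of 12 cognitive tests, three per domain (memory, speed,
reasoning, vocabulary); completion-time scores (Trail Making A) are
sign-reversed so that higher always means better. With exactly three
tests per domain the 12-test mean and the mean of the four domain means
coincide, so the `composite` argument of `compute_total_cognition()` is
a documentation device rather than a fork in the results.

A `thickness_matrix` is a 68 × N matrix in a fixed canonical region
order: alphabetical within hemisphere, left block first. The order is a
package convention (nothing downstream depends on which convention is
chosen, only that one is fixed); readers for wide CSV, long CSV and the
FreeSurfer `aparcstats2table` convention all normalize labels
(`lh_bankssts_thickness` → `lh-bankssts`) and reorder into it. Values
must be positive; values outside (0.5, 6.0) mm only warn, since the
matrix may legitimately hold transformed data.

All fits use Z-standardized covariates (sample SD, n − 1), so
coefficients are mm per SD of the covariate. Gender is Z-scored from its
1/2 coding, so its coefficient is mm per SD of the coding; with the
2 = women convention, positive gender coefficients indicate thicker
cortex in women. Missing-data policy is complete-case with a logged count; no
imputation.

## Region-wise regression

For each region `i`,

$$\mathrm{thickness}_i = \beta_{0}
  + [\,\mathrm{edu}\ \mathrm{gender}\ \mathrm{cog}\ \mathrm{rFD}\ \mathrm{age}\,]\,\beta_i
  + \varepsilon_i,$$

an ordinary least-squares fit with two-sided t-tests at n − 6 degrees of
freedom. An intercept is always included: thickness is not centered, so
a no-intercept fit would be meaningless. FDR is controlled per covariate
across the 68 regions (the step-up procedure applied to each covariate's
68 p-values), which matches reporting conventions that count "regions
significant for age", etc.; a pooled correction across all 340 tests is
available via `fdr_scope = "pooled"`. The same model with the
across-region mean as dependent variable is `fit_mean_thickness()`.

## Variance permutation test

Education might plausibly compress (or widen) the *spread* of thickness
rather than shift its mean. For a covariate of interest, the thickness
data are first residualized on the *other* covariates plus an intercept
— the intercept matters: without it, residuals keep their means and the
between-group variance comparison would be contaminated by mean offsets.
Subjects are split at the covariate median (HIGH strictly above; ties go
to LOW, a deterministic convention), and per region

$$\log F_i = \log\frac{\widehat{\mathrm{Var}}_i(\mathrm{HIGH})}
                       {\widehat{\mathrm{Var}}_i(\mathrm{LOW})}$$

with sample variances. The null distribution permutes the assignment
between the thickness array and the *whole* covariate table, redoing the
residualization each iteration — this preserves the covariate
intercorrelations under the null, which shuffling only the covariate of
interest would not. Two-tailed p-values compare `|log F|` against the
permuted statistics with add-one smoothing, `(1 + #exceed)/(n_perm + 1)`,
which keeps p > 0 and unbiased; an empirical tail-doubling rule is
available via `tail = "double"`. A parametric two-sided F-test p is
emitted as a diagnostic column only.

## Adjusted PCA-regression

Let `C` be the N × 4 matrix of confounders (everything except the
dependent variable), augmented internally with an intercept column. The
residualizing projector is

$$P = I - C\,(C^{\top}C)^{-1}C^{\top},$$

applied to the dependent variable and, along the subject dimension, to
the thickness array. Before residualization, the grand-mean pattern is
removed: each subject's across-region mean is subtracted (every profile
then sums to zero) and afterwards the group-mean residual image. This
costs exactly one principal component — a full-rank 68 × N array retains
67 components — and means all loadings are interpreted *relative to each
subject's overall mean thickness*.

PCA (via SVD) of the residualized array gives orthonormal region-space
components `V` and subject scores `W`. The dependent variable is
regressed on the leading K scores; K is chosen by leave-one-out
cross-validation minimizing the mean predicted residual sum of squares
(PRESS), computed through the hat-matrix identity
`e_loo = e/(1 − h)` and verified in the test suite against explicit
refits. Only leading sets PC1..PCk are candidates; ties (including the
all-zero PRESS of a noiseless fit) resolve to the smallest k, judged
with a tolerance of `1e-10` times the dependent variable's mean square.
PCA is computed once on the full residualized data and LOO applies to
the regression stage only; this is the standard SSM practice, and the
stricter fold-wise-PCA variant would change PRESS by O(1/N) at the cost
of re-deriving the basis per fold (its omission is a documented leakage
trade-off, not an oversight).

The pattern is `v = V[, 1:K] β`, L2-normalized so that the squared
loadings sum to one — all scale information then lives in the subject
scores `w = rTHX' v`. The fit is summarized by the Pearson correlation
between `w` and the residualized dependent variable, with a parametric
two-sided p at n − 2 df (a permutation p can be obtained by running the
chain under permuted dependent variables). Because `w` is a linear image
of data already orthogonal to the confounder span, the correlation
between subject scores and every confounder is zero by construction;
the code asserts `|r| < 1e-8` on every run rather than trusting the
algebra.

**Bootstrap.** Loading uncertainty comes from resampling subjects with
replacement (paired dependent variable and thickness profiles), rerunning
PCA and the regression with K *fixed* at the point estimate's selection,
and taking per-region [2.5%, 97.5%] percentile intervals over the
iterations. K is fixed because re-selecting it would mix patterns of
different dimension into one interval; the literal re-run-everything
reading is available via `reselect_k = TRUE`. Each bootstrap pattern is
sign-aligned to the point estimate (flipped when the inner product is
negative) — without alignment the ± indeterminacy of PCA would make
percentile intervals meaningless. Resamples with rank collapse or a
constant dependent variable are redrawn and counted. A region is
"robust" when its interval excludes zero; note this speaks to the
*stability of the loading*, and is only interpretable when the
score–DV correlation itself is significant.

**Residual signal.** Writing `rTHX = v w' + E`, the per-subject mean of
squared residuals, `RESS = mean(E^2)` over regions, is regressed on the
intercept plus all five Z-scored covariates. A positive age coefficient
means the derived pattern accounts for less of the thickness variation
in older subjects.

## The synthetic cohort

`sim_config()` defaults define the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 353 | cohort size |
| `target_corr` | cohort values | latent covariate correlations (education–cognition 0.32, cognition–age −0.23, …) |
| `baseline` | 2.2–2.9 mm | per-region mean thickness, cohort mean ≈ 2.55 mm |
| `region_effects` | ±0.01–0.07 mm/SD | gender (+, women thicker), rFD (−), age (−) region effects |
| `true_pattern` | mixed-sign, unit norm | +0.5 on right isthmus/posterior cingulate, −0.5 on right superior temporal/temporal pole, ±0.03 elsewhere |
| `pattern_strength` | 0.055 mm/SD | education effect on pattern expression |
| `pattern_expr_sd` | 0.25 mm | education-independent pattern expression SD |
| `noise_sd` | 0.1 mm | independent region-level noise SD |
| `age_hetero_slope` | 0 | residual-SD multiplier per SD of age |

Latent covariates are multivariate normal with the target correlations
(non-positive-definite targets error out; no silent repair), then mapped
to observable scales: age uniform on [40, 80] via the normal CDF,
education 16.3 ± 2.4 years, rFD lognormal around 0.15 (motion summaries
are right-skewed), gender dichotomized at the latent median. These
monotone maps attenuate Pearson correlations by at most a few
thousandths at the default targets, verified by Monte-Carlo tests.

Thickness is baseline plus region effects times the Z-scored covariates,
plus the planted pattern times a per-subject *expression*
`pattern_strength·z_edu + pattern_expr_sd·η`, plus independent noise
whose SD scales as `1 + age_hetero_slope·z_age` (floored at 5%).

Two generator choices deserve justification:

- **Pattern expression variance.** The planted pattern is expressed with
  subject-level variation beyond its education link. This makes the
  pattern a genuine covariance axis of the thickness data — which is how
  real cortical data behave, and the regime PCA-regression is designed
  for. Without it (set `pattern_expr_sd = 0`), a pattern pinned to a
  score–education correlation of 0.2 has a rank-1 signal far below the
  detectability threshold of the leading principal components, and *no*
  method operating in the leading-PC subspace could recover its
  loadings. The defaults place the score–education correlation near 0.2
  (the effect scale reported for real cohorts of this size) while
  keeping the pattern recoverable: mean loading recovery ≈ 0.85–0.9 over
  replicate cohorts.
- **Heteroscedasticity mechanism.** Age-dependent residual SD is
  multiplicative in Z-age — the simplest mechanism producing the
  positive RESS–age association seen in real data. A planted slope of
  0.03 yields RESS-age T statistics of ≈ 4–6 at N = 353, matching the
  magnitude reported in comparable cohorts; it is the value used in the
  recovery experiments (the default is 0, a homoscedastic null).

What the generator does **not** emulate: spatially correlated noise
between regions, non-Gaussian thickness distributions, longitudinal
change, or scanner/site effects. One visible consequence: with
independent region noise, averaging 68 regions shrinks the noise of the
mean by √68, so mean-thickness T statistics on synthetic data are far
larger than on real data. Passing tests therefore demonstrate
correctness of the estimators and calibration of the inferential
procedures under the stated generative model, not robustness to the
spatial dependence structure of real cortical data.

## Numerical choices

- Sample SD (n − 1) throughout; ties at the median go LOW; BH-FDR per
  covariate by default.
- Singular values below 1e-8 of the largest are treated as null when
  counting components.
- PCA component signs are fixed by making the largest-|loading| element
  positive; bootstrap patterns are sign-aligned by inner product.
- Permutation p-values use add-one smoothing; seeds are global integers
  expanded per stage through an injective counter scheme
  (`stage_seed()`), so sweeps over consecutive seeds never share RNG
  streams across stages.
- Problem sizes in the test suite follow the study scale where the
  property demands it (N = 353, 68 regions; 25-seed recovery, 50-sim
  bootstrap coverage at 500 iterations, 30-dataset permutation
  calibration at 1,000 permutations) and drop to small fixtures where
  exact oracles exist (8-subject exhaustive enumeration of all 8!
  relabelings, explicit leave-one-out refits, per-column OLS residual
  oracles).

## Known limitations

- The bootstrap keeps K fixed; when PRESS selection is unstable across
  resamples the intervals understate model-selection uncertainty.
- "Robust" loadings are stability statements about a basis direction;
  with an insignificant score–DV correlation, a stable leading PC will
  still produce intervals excluding zero.
- The parametric fit p at n − 2 df treats the scores as fixed; it
  ignores the selection of K (PRESS is out-of-sample, which limits but
  does not remove the optimism).
- Complete-case handling only; motion is a summary scalar (mean rFD)
  and carries no run-level information into the models.
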