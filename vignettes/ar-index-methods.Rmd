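---
title: "Composite adipokine indexes and their case-control evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite adipokine indexes and their case-control evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arindex)
library(dplyr)
```

## The indexes

Adiponectin and resistin are adipokines with diametrically opposed
associations with insulin resistance: low adiponectin and high resistin both
mark increased risk of type 2 diabetes (T2DM) and the metabolic syndrome
(MS). The adiponectin–resistin index folds both into one number,

$$AR = 1 + \log_{10}(R_0) - \log_{10}(A_0),$$

with fasting serum total resistin $R_0$ in ng/mL and adiponectin $A_0$ in
µg/mL. The ratio is deliberately unit-asymmetric: the numeric values in
those units enter the logs directly, and no rescaling to a common unit is
performed. The index is invariant to scaling both adipokines by a common
factor and increases by one unit per decade of the resistin/adiponectin
ratio.

The insulin-resistance extension divides AR by QUICKI,
$QUICKI = 1/[\log_{10} I_0 + \log_{10} G_0]$ (insulin $I_0$ in µU/mL,
glucose $G_0$ in mg/dL), giving

$$IR_{AR} = \frac{AR}{QUICKI} = \log_{10}(I_0 G_0)\,
  \bigl[1 + \log_{10}(R_0/A_0)\bigr].$$

`irar_index()` evaluates the expanded right-hand side; the test suite
enforces the algebraic identity against `ar_index()/quicki()` at $10^{-12}$
relative tolerance on random valid inputs, so the two routes are
interchangeable.

The classical surrogates (HOMA-IR, Bennett, the two McAuley regressions) are
provided for comparison. Several of them circulate in more than one
algebraic dress, so every such choice is pinned in a `formula_dialect()`:

* **Glucose unit.** Cohort files carry glucose in mmol/L (the reporting
  unit) while QUICKI and $IR_{AR}$ need mg/dL. The default conversion factor
  is 18.0182 mg/dL per mmol/L (the molar mass of glucose divided by ten);
  it is configurable because some sources round to 18.0.
* **HOMA-IR** uses the standard form $I_0 \times G_0(\text{mmol/L})/22.5$.
* **Bennett** defaults to natural logs with glucose in mmol/L. This is the
  only dialect consistent with typical published group values: the index is
  a convex (reciprocal) transform, so by Jensen's inequality its group mean
  must exceed its value at the group-mean inputs, which holds for this
  dialect (0.255 at typical control means against a reported group mean near
  0.31) and fails for the base-10 variants.
* **McAuley** defaults to the published regression coefficients
  $\exp(2.63 - 0.28\ln I_0 - 0.31 \ln TG)$ and the insulin-only reduction
  $\exp(2.63 - 0.28\ln I_0)$; both coefficient sets are configurable.

Non-positive or non-finite inputs are rejected with errors naming the
offending field — never silently imputed. The one deliberate soft spot is a
missing triglyceride *column* in `compute_indices()`, which degrades to an
`NA` McAuley-TG column with a warning so a whole pipeline run does not abort
on an optional input (set `require_all = TRUE` to make it an error).

## Risk bands

The published band system for Malaysian men aged 40–70 was derived from the
95% confidence intervals of the group means (not from ROC analysis):

```{r}
risk_thresholds()
```

Three interpretation decisions make classification total and deterministic:

1. Each cut-off is left-closed ("or greater" wording), so boundary values
   classify into the higher-severity band.
2. The published $IR_{AR}$ bands leave gaps (4.305–4.403 and 4.791–5.305);
   each band extends to the next band's lower bound, so the only
   indeterminate zones are the ones explicitly published as "minimum
   cut-off" intervals (AR 1.206–1.244, $IR_{AR}$ 3.538–3.955).
3. Values below the printed lower reference bounds classify as
   healthy/insulin-sensitive: the published ranges bound group means, not
   individual floors.

Thresholds are configuration, not constants, so the system can be
recalibrated for other populations without touching code.

## The synthetic cohort generator

No subject-level data are distributed with the study, so the generator
emulates its design: 208 controls, 174 MS without T2DM, 171 T2DM without MS
and 256 subjects with both (809 men in total), each group split across
Malay/Chinese/Indian strata at the published counts, with every published
group mean and 95% CI for age, anthropometrics, lipids, glucose, HbA1c and
insulin encoded as targets.

Distributional choices:

* **Positive, right-skewed biomarkers** (lipids, glucose, HbA1c, insulin,
  adipokines, BMI, waist, WHR) are log-normal, moment-matched on the natural
  scale to the target mean and to an SD back-derived from the reported CI via
  $SD = \sqrt{n}\,(CI_{hi}-CI_{lo})/(2 \times 1.959964)$. The symmetric-CI
  back-derivation is an approximation for skewed variables; the reported
  insulin CIs are visibly asymmetric, which is what motivates the log-normal
  marginals in the first place.
* **Age** is a symmetric normal truncated to [40, 70] (the study's inclusion
  window), with the location parameter solved numerically so the *truncated*
  mean hits the target. Blood pressures are plain normals.
* **Insulin** is additionally left-truncated at 2 µU/mL, a typical assay
  detection limit, via the inverse CDF of its latent normal. At the
  published coefficients of variation an untruncated log-normal occasionally
  produces fasting insulin below 1 µU/mL, where the Bennett index
  ($\ln I_0 > 0$) is undefined and which is not physiologically observed.
  The truncation preserves the copula rank structure and shifts group means
  by well under one standard error.
* **Dependence** among insulin, glucose, adiponectin and resistin is induced
  by a Gaussian copula over their latent normals, with rank-correlation
  targets carrying the published full-cohort sign structure (e.g.
  adiponectin–resistin $-0.105$). Infeasible target matrices are rejected
  before any sampling. Note that the *pooled* cross-group correlations of a
  generated cohort are stronger than the within-group targets, because the
  group means themselves separate in opposite directions — pooling adds a
  between-group component on top of the copula's within-group one.
* **Adipokine group means** are not published as numbers (figures only).
  The defaults — adiponectin 8.7/6.9/6.0/5.2 µg/mL at CV 0.45, resistin
  12.44/13.89/17.35/21.29 ng/mL at CV 0.40 across
  control/MS/T2DM/T2DM+MS — were fixed once so that the log-normal-implied
  group mean AR lands mid-interval of each published AR band
  (≈ 1.163/1.31/1.47/1.62). They are calibration targets, not published
  values, and are marked as such.
* **Binary covariates** (smoking, hypertension, family history) are
  group-wise Bernoulli draws at the published rates; they are carried for
  realism and unused by the index mathematics.

Generation is deterministic given `(spec, seed)`: a single RNG stream per
cohort, exact group-by-ethnicity counts, and the seed recorded in the output
metadata. Rows violating `hdl < total_chol` are redrawn, so every record
satisfies the schema invariants. Scaled designs (`scale` argument) use
round-half-up group sizes and largest-remainder ethnicity splits; SD
back-derivation always uses the full-scale $n$ that produced the published
intervals.

What passing tests on this generator do **not** show: the generator has no
measurement error model, no missing data, no treatment dynamics, and its
within-group distributions are exactly log-normal — real cohorts are messier
in all four respects. Agreement of the statistical harness with its oracles
is evidence about the harness, not about any real population.

## The statistical harness

**ANCOVA.** Each variable is tested with the general linear model
`variable ~ group + age` (group a fixed factor, age the only covariate,
matching the study description; ethnicity enters through stratified
resampling, not as a model term) and Type III sums of squares. With no
interaction terms the Type III group test equals the full-versus-reduced
residual-SS F test, and the suite checks the implementation against exactly
that explicit least-squares oracle at $10^{-8}$ relative tolerance.

**Pairwise contrasts.** Group differences are bootstrapped with 1,000
stratified replicates by default: resampling with replacement within each
group-by-ethnicity cell, cell sizes preserved. The bootstrap statistic is
the raw difference in group means; age adjustment lives in the omnibus test.
(The original description does not say whether raw or model-adjusted
differences were bootstrapped; the report tables therefore carry both raw
and ANCOVA-adjusted group means, labelled.) Intervals are BCa:

* bias correction $z_0 = \Phi^{-1}[(\#\{\theta^* < \hat\theta\} +
  \tfrac12 \#\{\theta^* = \hat\theta\})/B]$, ties counted with weight 1/2
  and the extremes clamped to $1/(2B)$ so $z_0$ stays finite;
* acceleration $a$ from the leave-one-out jackknife skewness over all
  subjects;
* endpoints read off the bootstrap distribution at rank $(B+1)\alpha$ with
  interpolation between adjacent order statistics linear on the
  normal-quantile scale, clamped to the extreme order statistics.

With $z_0 = a = 0$ the construction reduces exactly to the percentile
interval. A degenerate bootstrap (all replicates identical) collapses to a
point interval with a warning. Significance grades use nested intervals:
`*` when the 95% interval excludes zero, `**` at 99%, `***` at 99.9% —
matching the $p^* < 0.05$, $p^{**} < 0.01$, $p^{***} < 0.001$ star
convention, and nested by construction since the interval widens with the
level. A known limitation, visible in the calibration simulations: for
strongly skewed statistics at moderate $n$ (the log-normal mean at
$n = 50$), BCa's true coverage sits slightly below nominal, around 91–92%
for 95% intervals.

**MANCOVA.** For the joint (adiponectin, resistin) response, the hypothesis
matrix is the increase in the residual cross-product when the group factor
is dropped (Type III), and the four classical statistics are computed from
the eigenvalues $\lambda_i$ of $E^{-1}H$: Pillai
$\sum \lambda_i/(1+\lambda_i)$, Wilks $\prod 1/(1+\lambda_i)$, Hotelling
$\sum \lambda_i$, Roy $\max \lambda_i$, with the standard F approximations
(Pillai and Hotelling via the $s, m, n'$ layout, Wilks via Rao's F, Roy as
an upper-bound F). At the full design (4 groups, 2 responses, 809 subjects)
this yields the df pattern 6/1608, 6/1606, 6/1604 and 3/804. Since Roy's
root and Hotelling's trace jointly determine both eigenvalues of a
two-response problem, Pillai and Wilks can be recomputed from a published
pair of those statistics — a consistency check the acceptance suite runs.

**Spearman correlations.** Average ranks for ties, rho as the Pearson
correlation of ranks, and two-tailed p-values from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df (the nonparametric choice
because most of these biomarkers are right-skewed). Constant variables give
`NA` with a warning rather than an arbitrary value.

## Numerical and design notes

* All bootstrap work in an evaluation runs off one seeded RNG stream;
  results are bitwise reproducible given (seed, replicate count, package
  version). The resampling draw order is documented in the source and
  relied on by the exactness tests.
* The rank-deficiency check in the ANCOVA names the aliased terms instead
  of silently dropping them.
* `read_cohort()` rejects invalid rows (non-positive biomarkers, age
  outside [40, 70], `hdl >= total_chol`) with row-numbered warnings and
  errors on structural problems; validation can be switched off.
* Problem sizes used by the test and acceptance suites were chosen as the
  smallest that make each property sharp: 10,000 random inputs for the
  $IR_{AR}$ identity, 100 random datasets for the ANCOVA oracle, $B = 2000$
  for BCa exactness, 1,000 simulations for BCa coverage, a ~50,000-subject
  cohort (scale 62) for parameter recovery, 100 full-scale seeds for the AR
  group ordering, and 200 permutations for null calibration.

## Worked example

```{r example}
cohort <- generate_cohort(default_cohort_spec(scale = 0.25), seed = 42)
ev <- evaluate_case_control(cohort, replicates = 200, seed = 1,
                            variables = c("ar", "ir_ar", "insulin"))
tidy(ev)
ev$comparisons$pairwise[[1]]
```

## Limitations

The published cut-offs were derived in Malaysian men aged 40–70 and are not
population-general; the package treats them as configuration for that
reason. The generator reproduces first and second moments and a rank
correlation skeleton, not the full joint distribution of a real cohort, so
downstream F statistics and correlations from synthetic data are
qualitatively, not numerically, comparable with the study's. Real-cohort
test statistics cannot be reproduced without the (undeposited)
subject-level data; the harness is instead validated against independent
oracles and the published internal-consistency constants.
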