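---
title: "Modelling longitudinal multivariate trials with rmasca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal multivariate trials with rmasca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmasca)
```

## The problem

Longitudinal intervention studies in metabolomics and proteomics measure a
panel of J correlated variables on I subjects at K occasions, in H treatment
groups. Two features make such data awkward for classical ANOVA-PCA hybrids:
repeated measurements on the same subject are not independent, and real
trials are unbalanced, with substantial missing data. `rmasca` addresses
both by estimating the effects of time, group, and their interaction with
column-wise *random-intercept linear mixed models*, decomposing the fitted
fixed effects into per-factor *effect matrices*, visualizing each with PCA,
and quantifying uncertainty with a group-stratified case bootstrap.

## The model

Each response column is modelled as

$$ y_{ihk} = (\beta_0 + \gamma_{0i}) + \sum_m \beta^{(T)}_m t_{mk}
   + \sum_l \beta^{(G)}_l g_{lh} + \sum_{m,l} \beta^{(TG)}_{ml} (t_{mk} g_{lh})
   + e_{ihk}, $$

with a subject random intercept $\gamma_{0i} \sim N(0, \sigma_u^2)$ and
residuals $e_{ihk} \sim N(0, \sigma_e^2)$, both independent. Stacking the
column fits gives the multivariate form $Y = XB + ZU + E$ with $B$ the
$p \times J$ fixed-effect matrix, $Z$ the subject incidence matrix, and $U$
the random intercepts. Fitting is delegated to `lme4::lmer()`, one response
at a time, with rows dropped per column where the response is missing — the
all-available-data property that makes these models usable at realistic
missingness levels, provided the data are missing at random (MAR).

Time is **always reference-coded with baseline as reference**. That choice
is load-bearing: it makes the baseline rows of the time and interaction
effect matrices exactly zero, so trajectories read as changes from
baseline, and it enables the *constrained* model below. Group coding is
free: sum coding expresses the time effect as the average across groups,
reference coding anchors it to a reference arm.

Four model families are available through `model_spec()`:

* `rm_unconstrained` (ucLDA): baseline responses in $y$, group main effect
  included. Interaction coefficients compare within-group changes, without
  baseline adjustment.
* `rm_constrained` (cLDA): the group main effect is omitted, so all groups
  share the modelled baseline mean; the interaction is thereby adjusted for
  baseline differences. Appropriate for randomized trials, where the
  pre-treatment expectation genuinely is common across arms.
* `ancova`: follow-up responses only, with the subject's baseline value of
  the same variable entering as a covariate (swapped in per response
  column at fit time). Subjects missing baseline are excluded per column.
* `changes`: follow-up minus baseline as the response, baseline not in the
  model.

The families are mathematically related, and the package's tests exercise
those relations: unconstrained interaction estimates coincide with
analysis-of-changes group estimates on complete balanced data, and the
constrained interaction converges to the ANCOVA group effect as I grows.
For non-randomized cohorts the baseline-adjusted estimand answers a
different question than the unadjusted one (Lord's paradox); the package
deliberately leaves the family choice to the analyst.

## Effect matrices and their PCA

An effect matrix zeroes every design column outside the requested families
and multiplies: $M_f = X_f B_f$. Useful combinations:

* $M_T$ — the average time trajectory;
* $M_T + M_{T \times G}$ — group trajectories anchored at baseline
  (`rm_constrained` makes these baseline-adjusted);
* $M_G + M_{T \times G}$ under double reference coding — deviations from
  the control arm's trajectory.

Each combination is mean-centered over model rows and decomposed by SVD
(`center_and_pca()`). Because rows are observed records rather than unique
design cells, cells with more records weigh proportionally more; this
matches the matrix algebra above and is also what the bootstrap re-centers
per replicate. Explained fractions are singular values squared over their
total. Augmented scores, $(M + ZU + E - \text{center})P$, project the
per-subject offsets and residual variation onto the effect components,
giving a qualitative read of effect size against unexplained variation;
with no covariates in the model this equals projecting the (centered) raw
values.

With reference-coded time the effect matrices are **not** mutually
orthogonal, so the squared-Frobenius-norm decomposition of $\|Y\|^2$ that
holds for balanced, fully sum-coded, fixed-effects designs does not apply.
`variance_decomposition()` still reports each $\|M_f\|^2$ but also always
reports the discrepancy term rather than hiding it; on a balanced sum-coded
fixed-effects fit the discrepancy is numerically zero (relative magnitude
below 1e-8), and under the package defaults it is visibly nonzero.

## Preprocessing

Concentration-type variables are commonly log- or square-root transformed
(`apply_transform()`, with domain checks that name the offending variable
and row). `scale_to_baseline_sd()` then divides every column by the sample
standard deviation (n−1 denominator, all available baseline cells) of its
non-missing baseline observations, putting variables on a
change-per-baseline-SD scale that emphasizes variables with higher
variability over time. Degenerate columns (constant or all-missing at
baseline) fail loudly rather than being dropped silently. The recorded
`scaling_state` is sufficient to re-apply identical preprocessing to new
data.

## Bootstrap validation

`bootstrap_rm_asca()` resamples whole subjects with replacement *within
each group*, keeping every group at its original size, so the design's
imbalance is preserved. Per replicate it:

1. reassigns fresh ids to duplicated subjects — each copy gets its own
   random intercept; treating copies as one subject would misstate $Z$ and
   shrink the within-subject variance;
2. re-applies the transform and **recomputes** the baseline-SD scaling from
   the replicate;
3. refits, rebuilds the effect matrix, re-centers, and re-decomposes;
4. Procrustes-rotates the replicate loadings toward the reference loadings
   (closed-form SVD solution) and applies the same rotation to the scores,
   removing rotational and sign ambiguity;
5. accumulates cell scores and loadings.

Percentile bounds (linear interpolation between order statistics, 2.5th
and 97.5th at the default `alpha = 0.05`) form the intervals. Replicates
whose fit fails are skipped — not retried, since retrying would bias the
sample toward easy resamples — and the skip count is surfaced, with a
warning above 10%. A master seed spawns one sub-seed per replicate, so runs
are reproducible and replicates independent.

Two caveats are inherent to the method. Rotating toward the loadings
naturally narrows the loading intervals, and percentile intervals are an
approximate uncertainty measure, not parametric 95% confidence intervals.
The package's small-scale coverage study (see the validation tests)
accordingly checks for near-nominal, not exact, coverage.

## The synthetic-data generator

`generate_dataset()` simulates directly from the generative model:
$Y = XB_{\text{true}} + Z\gamma + E$ with categorical time, subject
intercepts $\gamma \sim N(0, \sigma_u^2)$, residuals
$N(0, \sigma_e^2)$, and configurable missingness — MCAR per cell or per
record at per-timepoint rates, or MAR with dropout probability logistic in
the subject's observed baseline value of the same variable. Ground truth is
returned alongside, on the same coding the fitting uses, so recovery is
directly checkable.

Two presets mirror common trial shapes. `neoava_like` is a randomized
two-arm design (62/60 subjects, 3 timepoints, 16 variables,
record-level MCAR at 14/36/29%): half the variables drift down and half up
over time, with final-timepoint magnitudes 0.4–1.2 baseline-SD units, and
the treated arm's change amplified by 50%. `bariatric_like` is a
non-randomized three-arm design (60/27/19 subjects, 5 timepoints, 21
variables, MCAR 0/7/8/12/32%) mixing a sustained step response with a
transient post-intervention response, and one arm diverging on a subset of
variables. Both use $\sigma_u = \sigma_e = 0.7$, so the baseline
between-subject SD is near 1, the natural scale of baseline-SD-standardized
data. These values were fixed once as a realistic moderate-effect regime.

What the generator does *not* emulate: correlated residuals across
variables (each column is generated independently; real metabolite panels
are cross-correlated), heavier-than-Gaussian tails, drift in measurement
batches, or MNAR dropout. Passing tests on these presets therefore
demonstrate correctness of the estimation and resampling machinery under
the stated model, not robustness to every failure mode of real data. An
MNAR stress case (dropping high follow-up values) is included in the test
suite precisely to show the resulting bias, not to certify against it.

## Numerical choices

* Fitting uses maximum likelihood (`ML`) by default for reproducibility of
  effect estimates across families; `REML` is available by flag.
* $\sigma_u^2$ is kept non-negative by `lme4`'s parameterization; boundary
  estimates are reported as 0 with a warning, not an error. Optimizer
  non-convergence is an error (and a skipped replicate inside the
  bootstrap).
* Rank deficiency after missing-row dropping is an error naming the
  collinear columns.
* PCA sign convention: each loading column is flipped so its
  largest-magnitude element is positive, ties broken by the first index —
  a deterministic output across platforms.
* `A` defaults to `min(rank, 5)`; requesting more than the rank zero-pads
  with a warning. The bootstrap carries the same `A` as the reference
  decomposition (2 in the standard presentation).
* When more than 20% of subjects contribute a single row, the
  $\sigma_u^2/\sigma_e^2$ split is weakly identified and a warning is
  raised.
* Rows with residual-missing cells contribute zero to augmentation and are
  dropped (and reported) from augmented-score projections.

## Problem sizes used in the checks

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is cleanly visible: algebraic
identities on 20–50 subjects; the moment-estimator comparison at I = 50,
K = 4; the family equivalences at I = 40 (exact) and I = 2000
(asymptotic, tolerance 0.05); parameter-recovery curves at I = 50/200/800
on the two-arm preset; the null-data bootstrap at I = 50 with 500
replicates; and the coverage study at 12 outer simulations with 60
replicates each. Production analyses would typically use 1000 or more
bootstrap replicates.

## Known limitations

* Only random intercepts: no random slopes or continuous-time (spline)
  trends — within-subject correlation is assumed exchangeable across
  occasions.
* No formal hypothesis tests (no permutation or likelihood-ratio testing);
  the bootstrap bands are descriptive.
* Mixed models are fit per variable; panels of tens of thousands of
  variables would be slow, and a dimension-reduction front end would be
  the better tool there.
* The Frobenius variance decomposition is not interpretable as a clean
  partition under the default coding; the discrepancy term must be read
  alongside it.
* Explained-variance fractions are computed on model rows; with heavy,
  uneven missingness the implied cell weighting follows the observed data.

## A worked example

```{r example, eval = FALSE}
sim <- generate_dataset(simulation_preset("neoava_like"), seed = 7)
ds <- scale_to_baseline_sd(sim$dataset)$dataset

spec <- model_spec("rm_constrained",
                   group_coding = coding_scheme("reference", "control"))
fm <- fit_multivariate(ds, spec)

m <- construct_effect_matrix(fm, c("time", "time:group"))
dec <- center_and_pca(m, A = 2)
dec$explained_fraction
scores_by_cell(dec)

br <- bootstrap_rm_asca(sim$dataset, spec, c("time", "time:group"),
                        A = 2, n_boot = 1000, seed = 7)
plot_scores(dec, br)
plot_loadings(dec, br)
```

The same analysis runs end to end, with figures and tables on disk, via
`run_pipeline()` or the `rmasca` command-line script under `exec/`.
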