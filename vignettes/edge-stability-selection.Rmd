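---
title: "Discriminative edge discovery for two-group functional connectivity studies"
author: "FCSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative edge discovery for two-group functional connectivity studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FCSelect)
```

## The problem

Resting-state fMRI studies often ask whether whole-brain functional
connectivity (FC) can distinguish a patient group from healthy controls, and
— more usefully — *which* connections carry that distinction. With an
atlas of $n$ regions of interest (ROIs) there are $n(n-1)/2$ edges (4005 for
the 90-region parcellation this package defaults to) but only a few dozen
subjects, so any single model fit is unstable. FCSelect implements a
discriminative-edge discovery pipeline built around *stability*: which edges
keep being selected when the subject sample, the cross-validation split and
the penalty are all perturbed.

The pipeline, per training fold:

1. **Univariate screen.** A pooled-variance two-sample t-test per edge on
   the training subjects; edges with $p < P_0$ survive.
2. **Inner CV-LASSO.** The training subjects are split into $k_{\text{in}}$
   groups (default 10). Leaving out each group in turn, a LASSO regression
   of the 0/1 group label on the screened edges (squared-error loss, i.e. a
   linear-probability fit) is computed with the penalty chosen by the
   one-standard-error rule: the largest $\lambda$ whose cross-validated MSE
   is within one standard error of the minimum. This yields
   $k_{\text{in}}$ candidate feature sets.
3. **Occurrence threshold.** Edges appearing in at least $N$ of the
   $k_{\text{in}}$ sets become the fold's LASSO features.
4. **Linear SVM.** A soft-margin linear SVM with cost $c$ is trained on the
   selected edges and evaluated on the held-out fold (accuracy,
   sensitivity, specificity, recall, precision, decision scores).

The outer loop repeats $k$-fold cross-validation `repeats` times with fresh
splits (default $100 \times 10$, hence 1000 test-fold evaluations), reports
each metric as mean ± SD over folds and pools the decision scores into one
ROC/AUC. Edges selected in more than half of the training folds
(occurrence > 500 of 1000 at the defaults) form the *stable set*, which is
then tested for group differences with Bonferroni family-wise-error
correction, and summarized with a model-derived weight (the mean absolute
standardized SVM weight over the folds containing the edge).

## Parameters that matter

| Parameter | Meaning | Default | Grid |
|---|---|---|---|
| `p0` | t-test screening threshold | 0.05 | 0.001, 0.005, 0.01, 0.025–0.2 (step 0.025) |
| `nOccurrence` | inner occurrence threshold $N$ | 5 | 1–10 |
| `svmCost` | SVM cost $c$ | 1 | 0.1–2 (step 0.1) |
| `kOuter`, `kInner` | fold counts | 10, 10 | — |
| `repeats` | outer repetitions | 100 | — |
| `lambdaFolds` | nested $\lambda$-selection CV folds | 5 | — |

The defaults for the searched triple are the mid-grid values; a study should
normally let `gridSearch()` choose them. Note that `gridSearch()` follows
the protocol of maximizing *test-fold* accuracy directly, so the winning
accuracy is an optimistically biased estimate; treat it as a model-selection
device, and wrap it in an outer CV of its own if an unbiased performance
estimate is needed. Ties are broken toward sparser models (larger $N$), then
smaller $c$, then smaller `p0`.

Two places the procedure is underdetermined and this package fixes a
convention:

- **Where the inner CV-MSE curve comes from.** Each of the $k_{\text{in}}$
  inner fits needs its own cross-validated MSE curve to apply the 1SE rule,
  which implies a third nesting level; FCSelect uses a 5-fold split
  (`lambdaFolds`) inside each inner fit.
- **Standardization.** LASSO penalties and SVM margins are scale-dependent.
  Features are standardized on the fitting subjects inside every fit
  (population variance convention); held-out data are transformed with the
  training parameters, which are stored in the fitted model.

## Temporal cleaning and connectivity

`cleanTimeseries()` applies, in fixed order: linear detrending, least-squares
regression on the confound columns (motion, motion derivatives, CSF, white
matter, spike indicators) plus intercept and trend, and a zero-phase
second-order Butterworth band-pass (default 0.01–0.1 Hz) run
forward-backward. The band must lie inside the Nyquist range $1/(2\,TR)$.
Collinear confound columns are dropped with a warning.

Because the forward-backward pass has magnitude response $|H(f)|^2 < 1$
everywhere except at the filter's center frequency, re-cleaning an already
cleaned series attenuates in-band components slightly further (about 5% at
0.05 Hz with TR = 2 s): detrending and confound regression are exactly
idempotent, the filter only approximately so. The tests therefore pin the
filter by its frequency response (in-band retention within 10%, >90%
attenuation at 0.2 Hz) rather than by idempotency.

Edges are the strict upper triangle of the Pearson correlation matrix,
flattened row-major: edge $k$ runs over $i = 1..n-1$, $j = i+1..n$, 1-based,
so edge 1 is ROI pair (1, 2) and edge 4005 is (89, 90). Raw $r$ is the
feature; a Fisher-z option exists (`fisherZ = TRUE`) but is off by default.

## The synthetic-data module

No subject-level data ship with the package, so the generators in
`SyntheticSpec()` / `simulateEdgeTable()` / `simulateROITimeSeries()` define
the study conditions every test runs under: 30 controls vs 39 patients, 90
ROIs (4005 edges), 205 timepoints at TR = 2 s, and five signal edges.

Two routes produce data with known ground truth:

- **Direct edge route** (`simulateEdgeTable()`): edge values are independent
  Gaussians on the Fisher-z scale (sd 0.2) and the patient group is shifted
  by $d \times 0.2$ at the signal edges, so the planted standardized effect
  is exactly $d$ (default 1.5). This is the fast route used for statistical
  calibration.
- **Time-series route** (`makeGroupCovariances()` +
  `simulateROITimeSeries()`): a shared background correlation structure is
  drawn from a rank-5 factor model, the signal edges of the patient
  covariance are shifted by `delta` (default 0.3, the correlation-scale
  analogue of $d = 1.5$ at sd 0.2), and positive definiteness is restored by
  clipping eigenvalues at $10^{-6}$ and re-normalizing to unit diagonal.
  Construction is rejected if a planted correlation would leave $(-1, 1)$ or
  if the repair distorts a planted difference by more than 0.02.

What the generators deliberately do *not* emulate: spatial structure and
hemodynamics (no volumes, no HRF), correlated edges (the direct route draws
edges independently, while real FC edges sharing an ROI are dependent),
heavy-tailed or site-dependent noise, and motion-FC coupling. Passing tests
therefore validate the *procedure* — no leakage, correct calibration under
the null, power to recover sparse planted signal — not any claim about real
patient data. In particular the classification accuracy reached on synthetic
cohorts is a property of the planted effect size, not a reproduction of any
empirical cohort's accuracy.

## Numerical choices

- LASSO fits go through coordinate descent (glmnet) with the objective
  $(1/2n)\sum(y - \beta_0 - X\beta)^2 + \lambda\|\beta\|_1$; the penalty
  path has 100 log-spaced values down to $10^{-3}\lambda_{\max}$.
  Single-feature problems use the closed-form soft threshold. The
  single-penalty fit (`fitLasso()`) is checked against an exhaustive KKT
  sign-pattern oracle to $10^{-4}$.
- The linear SVM goes through libsvm (e1071) at termination tolerance
  $10^{-8}$. When the solution has no free support vectors the dual does not
  determine the bias; the bias is then recomputed as the exact minimizer of
  the 1-D hinge problem (breakpoint search, midpoint of the optimal
  interval), which also makes degenerate no-signal fits behave sensibly.
  The fitted objective is checked against an exact dual active-set
  enumeration oracle to $10^{-6}$ (within the cost grid 0.1–2).
- AUC is the Mann–Whitney probability with ties counted 1/2; the emitted
  ROC curve integrates (trapezoid) back to the same number to $10^{-10}$.
- The permutation test re-runs the pipeline on permuted labels with the
  chosen parameter triple fixed (re-searching per permutation is possible
  but costly and off by default) and uses the add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$. A run in which every
  fold fails (no features survive selection) contributes the majority-class
  accuracy and AUC 0.5 — the same deterministic fallback for observed and
  permuted runs, which keeps the statistics exchangeable.
- Folds are stratified by group by default (`stratified = FALSE` reverts to
  simple random splits). A fold whose selected feature set is empty is
  recorded as failed and excluded from aggregates, with the count reported.
- All randomness descends from one master seed through deterministic 32-bit
  child seeds, so a `CVResults` is bit-reproducible end to end.

## Problem sizes used by the test suite

The validation suite runs the full pipeline at reduced scale so that the
whole suite completes in minutes: structural counts use a 10-ROI cohort for
the $100 \times 10$ fold-count contract; null calibration uses 20 full-size
(39 vs 30, 4005-edge) no-signal cohorts at $1 \times 10$-fold CV plus 200
reduced cohorts (28 edges, 16 vs 12 subjects, $3\times3$-fold CV, B = 19 —
a permutation count chosen so the discrete p-value grid stays fine relative
to the Kolmogorov–Smirnov resolution at 200 simulations) for permutation-p
uniformity; signal recovery uses 50 full-size cohorts at $1 \times 10$-fold
CV. These sizes are the package's own validation design; the pipeline
defaults remain $100 \times 10$.

## Known limitations

- The grid search reproduces a protocol that selects hyper-parameters on
  test-fold accuracy; its headline accuracy is biased upward. The package
  reports it as such rather than silently nesting the search.
- Post-hoc group-difference tests on stable edges are circular (selection
  and testing share the sample); the report prints this caveat.
- "Recall" is reported as TP/(TP+FN), identical to sensitivity, with
  precision alongside; studies that report recall as a distinct number
  should state their definition.
- The LASSO-on-labels formulation is a linear-probability model, not a
  calibrated classifier; it is used only for selection, never prediction.
- Complete recovery of a sparse planted signal is not guaranteed even at a
  nominal effect of d = 1.5: with 69 subjects the realized effect of each
  planted edge varies substantially (the standard error of an observed
  Cohen's d is about 0.27 here), and the occurrence ranking reflects an
  edge's *conditional* utility given the edges already in the sparse model,
  not its marginal group difference. When one planted edge realizes a weak
  effect in a given cohort, noise edges that correlate better with the
  residual label variation can out-rank it consistently — at any number of
  CV repetitions. In the validation suite this shows up as all five planted
  edges reaching the top 10 by occurrence in roughly 80–90% of simulated
  cohorts rather than always; the incomplete recoveries trace to
  realized-effect sampling, not to leakage or fold noise.

## A worked example

```{r example, eval = FALSE}
library(FCSelect)

spec <- SyntheticSpec(seed = 1)          # 39 vs 30, 4005 edges, 5 signal edges
tab <- simulateEdgeTable(spec)

params <- PipelineParams(repeats = 10, seed = 2)
res <- runRepeatedCV(tab, params)
aggregateMetrics(res)$metrics

rep <- stabilityReport(res, tab)
rep                                       # stable edges, weights, FWE t-tests
signalEdges(tab)                          # ground truth to compare against

perm <- permutationTest(tab, params, B = 19, repeats = 1)
perm
```
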