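---
title: "Preparing missing, imbalanced, and sparse emergency-medicine data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing missing, imbalanced, and sparse emergency-medicine data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrprep)
```

## The problem

Electronic medical records from emergency departments are an attractive
source for early-warning prediction models, but three pathologies make them
hard to model directly:

* **Missing values.** Lab panels are ordered selectively, so per-variable
  missingness routinely reaches 80–100%.
* **Class imbalance.** Outcomes such as sudden death affect roughly 5% of
  visits, so maximum-likelihood classifiers drift toward predicting the
  majority class.
* **Sparse binary features.** Free-text diagnoses explode into hundreds of
  rare indicator columns, some of which occur *only* in positive patients.
  Such columns quasi-completely separate a logistic regression: the
  likelihood is monotone in their coefficients, estimates diverge, and the
  reported odds ratios become astronomically large and meaningless.

`emrprep` implements a three-step preparation pipeline for these data —
random-forest single imputation, k-means centroid-proximal undersampling,
and principal-component reduction of the sparse diagnosis block — together
with the surrounding screening, variable-selection, model-fitting and
internal-validation machinery, and a synthetic cohort generator that
reproduces all three pathologies with ground truth retained.

## Variable screening

Screening happens before any modeling:

* **Synonym merging** (`merge_synonyms`): free-text diagnoses yield several
  columns per clinical entity; a many-to-one mapping combines them by
  logical OR.
* **Missingness filter** (`filter_missingness`, default threshold 0.8):
  a variable is dropped when its missing fraction is **greater than or
  equal to** the threshold. The boundary drops — a variable missing in
  exactly 80% of patients is filtered out — because the rule is phrased as
  "when 80% of the values are missing the variable should be filtered out".
* **Prevalence filter** (`filter_prevalence`, default threshold 0.05,
  diagnosis variables only): kept only when the diagnosis appears in
  **strictly more than** 5% of the population. With `per_class = TRUE`
  (the default) the prevalence is computed within each outcome class and
  passing in either class suffices. We default this on because with ~5%
  positives an overall denominator would discard every diagnosis that is
  frequent among cases but absent in controls — exactly the clinically
  interesting ones.
* **L/N/H discretization** (`discretize_lnh`): continuous labs are mapped
  against their reference range to the ordinal codes 0 (below), 1 (within,
  bounds inclusive), 2 (above). Boundary handling is not dictated by any
  clinical convention we know of; inclusive-into-normal was chosen once and
  is documented here. Downstream models treat the code as a single ordinal
  predictor, so an odds ratio refers to one step L→N or N→H.

## Random-forest single imputation

`rf_impute` runs a four-step, single-sweep protocol per variable, in
ascending order of missing fraction (better-observed variables are imputed
first so that, within one sweep, the cleanest targets are handled under the
least temporary-fill noise):

1. rows observed for the target variable form the training set, rows
   missing it the test set;
2. remaining missing covariate cells are *temporarily* filled with the mean
   (continuous) or mode (discrete) of currently observed values;
3. a regression forest (continuous target) or classification forest
   (discrete target) is trained and predicts the missing cells;
4. repeat for the next variable.

Temporary fills are recomputed from the original observed values for every
target and discarded afterwards — imputed values are never reused as
covariates within the sweep. This is a single pass, not an
iterate-to-convergence scheme such as missForest; the one-sweep design is
deliberate and kept. Forests default to 100 trees, unlimited depth, with a
per-variable seed derived from the global seed, so a fixed seed gives a
bit-identical imputed matrix.

`evaluate_imputation` quantifies quality without ground truth: per
variable, the observed rows are split 80/20, the model is trained on the
80% and scored on the held-out 20% — coefficient of determination R² for
continuous targets, Cohen's κ for discrete ones — and the report summarises
medians and IQRs. Variables with fewer than `min_obs` (default 25) observed
rows are reported as *not evaluable* rather than silently skipped. Constant
baselines (`method = "mean"/"mode"/"median"`) provide the comparison arm; a
constant prediction has R² ≈ 0 by construction, so any genuine covariate
signal shows as a positive gap.

Degenerate κ: when the held-out values and predictions share a single
category, expected agreement is 1 and κ is 0/0; we return 1 when observed
agreement is also perfect and 0 otherwise.

## Cluster-centroid undersampling

`kmeans_undersample` clusters the majority class into `k` groups with
Euclidean k-means and keeps, per cluster, the *real* member row nearest the
centroid — a centroid is an average, not a patient, so a real
representative stands in for it. Design choices:

* Features are z-scored before clustering (`standardize = TRUE`); Euclidean
  distance across raw lab units would be dominated by whichever lab has the
  widest scale. Ordinal L/N/H codes enter as numeric 0/1/2 and binary
  diagnoses as 0/1 — a documented approximation.
* Ten seeded restarts with distinct-row initial centers; best
  within-cluster sum of squares kept. Nearest-member ties break toward the
  lowest row index. An empty cluster (rare) is re-seeded at the unselected
  row farthest from the current selection, so exactly `k` distinct real
  rows are always returned.

`build_ratio_datasets` converts target minority:majority ratios (defaults
1:10, 1:5, 1:2, 1:1) into `k = round(n_minority * b / a)` and appends the
untouched original-ratio dataset.

## Principal-component reduction of sparse diagnoses

`pca_fit` centers the diagnosis matrix, forms the sample covariance
`C = X'X/(n-1)` and eigendecomposes it; being real symmetric, `C` has a
full orthonormal eigenbasis. Components are sorted by descending
eigenvalue; each component's sign is fixed so its largest-magnitude loading
is positive (reproducible reports); eigenvalues above −1e−10 but below 0
are clamped to 0. Columns are centered but *not* scaled to unit variance:
for 0/1 indicators, variance p(1−p) is exactly the information that should
decide which directions survive, and scaling would inflate the rarest
(noisiest) columns.

`select_k` keeps the smallest rank whose cumulative variance fraction
reaches the threshold (study value 0.982); an explicit `k` can be given
instead, since either the count or the fraction can be treated as primary.
`pc_transform` computes `Y = (X − center) P` with `P` the leading `k`
eigenvectors. The scores are dense and exactly orthogonal, so
multicollinearity disappears by construction.

Why this fixes separation: a rare diagnosis that occurs only in positives
carries little variance, so its direction lands among the trailing
eigenvalues and is truncated by the variance rule. The logistic fit on the
scores then simply has no axis along which the likelihood can diverge. The
package's headline regression test builds exactly this construction — two
rare arrest-style indicators present only in positives on top of common
diagnoses that carry the bulk of the covariance — and checks that the raw
fit trips the separation flag while the PC fit converges with all
|log OR| < 10. Note the converse: if the separating column is *common*
enough to survive truncation, PC regression inherits the separation; the
method's effectiveness depends on the separating features being rare,
which is the regime the pipeline targets.

`loading_report` ranks the original variables by |loading| within a
component; for interpretation, components with Wald P < .05 are ordered by
|log OR| and unpacked into their top-loading variables. The significance
rule is a ranked report, not a hard cutoff.

## Variable selection and model fitting

The laboratory track (on a 1:1 rebalanced dataset, ordinal-coded) runs:

1. **Chi-square prefilter** (`chi_square_filter`): Pearson chi-square
   without continuity correction per variable×outcome table; exclude when
   P > .10; zero-margin levels are dropped and noted.
2. **Univariate logistic filter** (`univariate_lr_filter`): exclude when
   the Wald P of the single slope exceeds .05. A univariate fit showing
   separation is flagged and set aside rather than judged on its
   meaningless P value.
3. **Expert reintroduction** (`reintroduce`): previously excluded variables
   can be returned to the candidate set; reintroducing a never-excluded
   variable errors, keeping the audit trail honest.
4. **Forward group selection** (`forward_group_selection`): candidate
   groups are scored standalone by repeated-subsampling mean AUROC; the
   best group seeds the model and the rest are tried in descending
   standalone order — kept only on *strict* improvement. The split seeds
   are reused across steps so comparisons are paired. The visiting order
   had to be fixed somewhere; descending standalone AUROC is the greedy
   choice consistent with "add successively and keep if AUROC improves".
5. **Multivariate fit** (`fit_multivariate_lr`): maximum-likelihood
   logistic regression reported as odds ratios. CIs default to Wald
   (`exp(beta ± 1.96 se)`); a bootstrap mode (percentile over refits on
   stratified 70% subsamples) is also provided because summarising across
   repeated fits yields much narrower intervals — both modes are recorded
   in the result, neither is canonical.
6. **Separation detection** (`detect_separation`): flag when any
   |coefficient| exceeds 10 (odds ratio e¹⁰ ≈ 2·10⁴ per step; clinically
   plausible ordinal ORs live well below 20, pathological ones at 10⁹ and
   beyond) or when the optimizer stalls with fitted probabilities pinned
   at 0/1.

`train_model_zoo` fits the comparison models (logistic, LASSO via glmnet,
random forest via ranger, gradient boosting via xgboost, RBF-SVM via
e1071), each tuned by a small grid under stratified 5-fold CV AUROC, then
evaluated with the common subsampling protocol.

## Internal validation and calibration

`subsample_evaluate` implements the "500-fold bootstrapping" protocol as it
is actually described: B independent *stratified 70/30 subsamples without
replacement*, model refit per repeat, AUROC / AUPRC / recall / F1 (at the
0.5 probability threshold) computed on each 30% part, summarised as means
with 2.5/97.5 percentile intervals. We name it subsampling, not
bootstrapping, in the documentation. Stratification guarantees both classes
in every test part even at 5% prevalence.

The metric implementations are oracles-first: AUROC is the Mann-Whitney
mean-rank form (ties count ½), tested against exhaustive pairwise
concordance; AUPRC integrates the precision envelope (linear interpolation
in PR space is optimistically biased); the Brier score and reliability
curves (equal-width bins, empty bins omitted with a note) assess
calibration.

`ratio_experiment` fixes a stratified original-ratio test set *before* any
undersampling — the clustering never sees test rows — then trains at each
ratio and evaluates everything on that common test set. Undersampling to
1:1 shifts the model intercept by roughly the log of the sampling ratio, so
recall and F1 rise while the Brier score worsens; the package's acceptance
suite checks this direction on 5%-prevalence synthetic cohorts in at least
8 of 10 seeds.

## The synthetic cohort generator

`cohort_spec`/`generate_cohort` emulate the study's data shape: ~5%
positive prevalence by default (977 positives against 17,959 negatives in
the motivating cohort), mixed variable kinds, per-variable missingness up
to the screening threshold, and sparse diagnosis indicators including
perfectly separating ones.

* **Continuous labs** are class-conditional Gaussians — the effect size is
  the mean shift (in SD units) added to positives — with an optional shared
  latent factor (`dependence`, default 0.5) so variables are mutually
  informative and imputation has signal to recover.
* **Discrete variables** are noisy quantile-binned copies of a continuous
  partner (`discrete_dependence`, default 0.7) or i.i.d. categorical when
  independence is wanted.
* **Diagnoses** are Bernoulli indicators; `diagnosis_effect` shifts the
  positive-class prevalence on the log-odds scale, and `separating_vars`
  are forced to zero in all negatives, producing true quasi-complete
  separation.
* **Missingness mechanisms**: MCAR is an independent Bernoulli mask; MAR
  masks rows above the median of a named fully observed driver at three
  times the rate of rows below it (expected rate equals the request); MNAR
  deterministically masks the top `rate` quantile of the variable's own
  values. The motivating study argues only that MAR is the workable
  assumption for real EMR data, so the generator exposes all three rather
  than guessing.

What the generator does *not* emulate — and hence what passing tests do not
establish about hospital data: realistic lab marginals beyond location and
scale, longitudinal structure, informative-presence correlation between
panels, and coding drift over time. Recovery results on the generator are
evidence the algorithms work as specified, not that any particular R² or κ
will be attained on real records.

## Numerical choices and degenerate inputs

* Covariance uses 1/(n−1); the normalization does not affect component
  directions or variance fractions.
* A constant matrix yields all-zero eigenvalues; `select_k` errors on zero
  total variance rather than returning an arbitrary rank.
* Chi-square tables with zero-margin rows or columns drop those levels and
  record a note; fully degenerate tables are reported with `NA` statistics.
* `kmeans_undersample` with `k` equal to the row count short-circuits to
  the identity; when distinct rows are fewer than `k` the distinct-row
  representatives are padded with the lowest unused indices.
* All randomness flows from explicit integer seeds; per-repeat and
  per-variable seeds are derived deterministically from the master seed.

## Problem sizes used by the shipped checks

The test-suite and acceptance script exercise cohorts of 1,000–10,000 rows
with 10–35 variables, 10-seed replications for the paired imputation and
calibration experiments, and B between 5 and 100 subsampling repeats
(500 remains the user-facing default for real analyses). These sizes give
stable qualitative results for every property checked while keeping a full
run in the order of a minute.

## Known limitations

* Single imputation only; imputation uncertainty is not propagated.
* One sweep of the forest imputer; no iteration to convergence.
* The PC fix for separation presumes the separating features are rare.
* Firth-penalized regression, SMOTE/ADASYN oversampling and isotonic
  recalibration are out of scope by design.
* Odds ratios from observational EMR data are associations, not causal
  effects.
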