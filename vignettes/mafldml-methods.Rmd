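---
title: "Methods: missingness-aware MAFLD risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: missingness-aware MAFLD risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mafldml` implements a complete pipeline for building MAFLD risk models
from T2DM clinic data under realistic missingness. This vignette
explains the statistical model behind each stage, the defaults and why
they were chosen, and the limits of what the synthetic experiments can
show.

## The synthetic cohort generator

No patient-level clinical dataset ships with the package. Instead, the
generator emulates the statistical structure such a cohort presents to
the downstream pipeline: 25 continuous laboratory/anthropometric
variables and 6 binary history variables, with class-conditional
distributions calibrated to published descriptive statistics of a
~3,700-record T2DM clinic population (per-class mean/Q1/Q3 for each
continuous variable, per-class positive rates for each binary one).

**Marginals.** Clinical laboratory variables are typically right-skewed
and non-normal, so each continuous variable is modelled per class as a
*shifted log-normal*, `X = c + exp(mu + sigma * Z)`. The three
parameters are solved in closed form from the three targets: the
skewness ratio `r = (mean - Q1)/(Q3 - Q1)` pins `sigma` (by a 1-D root
solve of a monotone shape function), the IQR pins `exp(mu)`, and the
mean pins the shift `c`. When `r < 1/2` the target is left-skewed and
the reflected family `X = c - exp(mu + sigma * Z)` is used; `r = 1/2`
degenerates to a plain normal. This covers every default calibration
row exactly, including the boundary case where the mean equals Q3
(`sigma = 2 * Phi^{-1}(0.75)`). Targets too extreme for the family
(mean beyond what any `sigma <= 12` produces) fall back to matching
mean and Q3 only and are flagged, but no default target triggers this.

**Dependence.** Cross-variable dependence is imposed through a Gaussian
copula: a latent multivariate normal `Z ~ N(0, R)` is pushed through
each marginal's quantile function, so the calibrated marginals are
preserved *exactly* regardless of `R`. The default `R` encodes
moderate, plausible structure — 0.6 among the anthropometrics (weight,
BMI, waist, hip), 0.5 between ALT and AST, 0.3 among the lipid panel,
zero elsewhere — because the calibration source publishes no
correlations. Every entry is overridable; positive-definiteness is
validated at configuration time.

**Class labels** are assigned at the exact configured prevalence
(`round(prevalence * n)` class-1 records, then shuffled), which makes
class-conditional sample sizes deterministic under a seed.

**Missingness injection.** Six variables (sex, age, height, weight,
DBP, BMI) are always complete, mirroring fields captured at every
visit. The remaining 25 receive missingness at configurable per-column
rates; the default profile (roughly 3%–40%, highest for specialised
assays such as insulin, HOMA, CRP and vitamin D, lowest for routine
chemistry) is a package design choice meant to look like a clinic
export, since the emulated study reports only which columns were
incomplete, not their exact rates. Under MCAR each eligible cell is
independently masked; under MAR a logistic model on standardised
always-observed drivers (default: slope 1 on age, 0.5 on BMI) scores
each record and exactly `round(rate * n)` cells per column are masked
by probability-weighted sampling without replacement. The exact-count
realisation makes downstream amputation-rate checks exact rather than
binomial. Ground truth of every masked cell is retained.

**What the generator does not emulate:** measurement error and assay
batch effects, nonlinear physiological relationships (e.g. the
BMI–weight–height identity is only approximated through correlation),
time structure, and missingness mechanisms driven by unobserved values
(MNAR). Tests passing on this cohort therefore certify the *pipeline
machinery* — calibration, rate exactness, mechanism detectability,
scoring arithmetic — not clinical performance on real data.

## Missingness diagnostics

`littles_mcar_test()` implements the classic chi-square test of the
MCAR hypothesis: group the records by missingness pattern, estimate the
grand mean and covariance by EM under the multivariate normal model,
and compare each pattern's observed-variable means against the grand
mean:

```
d2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j),
df = sum_j p_j - p
```

with `mu_j`, `Sigma_j` the EM estimates restricted to pattern `j`'s
observed set. The EM implementation sweeps patterns (conditional means
and covariances of the missing block given the observed block),
guarantees a non-decreasing observed-data log-likelihood, and stops at
a log-likelihood change below `1e-6` (cap 500 iterations; hitting the
cap raises an error carrying the last iterate).

Two design points deserve comment. First, *every* pattern contributes
to `d2`, however few records it holds: with 25 incomplete columns most
patterns are singletons, and because the covariance blocks come from
the pooled EM estimate (not per-pattern sample covariances) they remain
invertible for patterns of any size. An earlier variant that merged
small patterns into neighbours by observed-set intersection was
abandoned: intersection shrinks the observed sets so aggressively that
`df` can go negative at realistic dimension, whereas the classic
formulation yields df in the thousands for a 31-variable cohort, which
is also the order of magnitude reported for comparable clinical tables.
Second, binary variables enter the normal model as 0/1 numerics; this
mirrors common implementations but is an approximation — the chi-square
reference distribution is asymptotic and the normality assumption is
violated for indicators, so the test's size was verified by simulation
(type-I error within [0.03, 0.07] at alpha = 0.05 over 1,000 MCAR
replicates; power above 0.8 under a logistic-slope-2 MAR mechanism at
n = 1,000).

## Learned-MAR amputation

To benchmark imputers one needs missing cells with known truth whose
mechanism resembles the real one. The package replicates the observed
mechanism rather than assuming one:

1. split the data into random halves;
2. on half B, model each incomplete column's missingness indicator
   (missing = 1) from all other feature columns, choosing among eight
   classifier families (logistic regression, k-NN, SVM, decision tree,
   random forest, extra-trees, AdaBoost, gradient boosting) by mean
   cross-validated F1 — F1 rather than accuracy because the indicator
   classes are heavily imbalanced at typical missingness rates;
3. extract the fully observed subset of half A;
4. for each column, predict missingness probabilities on the complete
   subset and null exactly the top `round(rate * n)` records, where
   `rate` is the column's observed missingness fraction.

Predictor columns on half B contain their own missing entries; they are
placeholder-filled (median/mode) for classifier training, a pragmatic
choice made explicit because the amputation literature offers no
standard here. All columns' null sets are computed from the
*pre-amputation* complete values and applied jointly, so results do not
depend on an arbitrary column order; a sequential variant (earlier
nulls visible to later predictions) was considered and rejected as
order-dependent. Probability ties at the selection boundary are broken
by record order for determinism. Default tuning grids are compact
literature-standard ones (tree depth {3, 5, 10}, neighbours
{3, 5, 11}, SVM cost {0.1, 1, 10}, boosting depth {3, 5} at 100
rounds), all overridable.

## The imputation benchmark

Nine imputers are compared on the amputated cells: chained equations
with seven estimator families (ridge, SVM, tree, random forest,
extra-trees, AdaBoost.R2, gradient boosting), a k-nearest-neighbour
imputer, and an iterative random-forest imputer. The chained-equations
engine initialises with median/mode fills, visits variables in
ascending missingness order, fits the estimator on the observed rows of
each variable against all other (currently completed) columns, and
stops when the mean scaled change of imputed values drops below `1e-3`
(cap 10 sweeps). Binary columns use the classifier counterpart of each
family with a 0.5 threshold. The KNN imputer uses a missingness-aware
standardised Euclidean distance (scaled by `p / |common coordinates|`)
and averages the k = 5 nearest donors; standardisation departs from
some reference implementations but prevents large-scale variables
(platelets) from dominating the metric. The iterative forest imputer
refits per-variable random forests until the normalised difference
between successive completed matrices first increases, returning the
previous iterate.

Scoring follows the benchmark design: R² over amputated cells per
continuous variable (total sum of squares about the truth mean of those
cells, so a constant imputation at that mean scores exactly 0),
accuracy per binary variable, each variable weighted by its missingness
proportion, and the weighted averages reported separately for
continuous and binary variables. The winner is chosen on the continuous
aggregate — binary accuracies typically differ only in the third
decimal and would make the selection unstable. A mean/mode baseline is
always scored for reference but never wins. Whether a shared amputation
plan per seed should serve all methods is not specified by the
benchmark's source; the package shares it, which removes
amputation noise from the method comparison.

## Cleaning, outliers, balancing

Cleaning runs range filter → sparse-feature drop → sparse-row drop →
de-duplication, in that order. Range bounds are broad physiologic
plausibility limits declared in the schema (they are a package
convention, not published values); boundary values are retained (closed
interval). Thresholds are strict: a feature is dropped only when its
missing fraction *exceeds* 45%, a row only above 50%. The sensitivity
analysis re-runs cleaning under alternative feature cutoffs
(30%/45%/60% by default) and compares surviving cohorts pairwise by
standardised mean difference and two-sample Kolmogorov–Smirnov tests.

Outlier screening uses the local outlier factor on standardised
continuous features of the *imputed* table (so missingness patterns
cannot masquerade as isolation). Defaults k = 20 and score threshold
1.5 are conventional; the flagged count is data-dependent and
deliberately not a calibration target. LOF is O(n²) here, acceptable at
cohort scale (thousands of records).

Balancing offers random undersampling of the majority class (the
default, matching the mild imbalance regime where discarding a few
dozen records is harmless) and SMOTE (convex interpolation between
minority neighbours, binary features snapped to the nearer endpoint).

## Modelling and evaluation

The modelling stage performs a stratified 80/20 split; all tuning and
selection touch only the training subset (verified by a test that
perturbs the held-out rows and checks selections are unchanged).
Hyperparameters come from exhaustive grid search under stratified
5-fold CV with accuracy as the criterion, ties broken by grid order.

Four feature-selection strategies wrap any classifier:

* **Filter**: ANOVA F for continuous features, mutual information for
  binary ones; `k` tuned by CV accuracy.
* **PCA**: components of the standardised feature matrix; the count
  tuned by CV accuracy and capped at the feature count.
* **RFECV**: drop the least-important feature per round, using the
  classifier's own importances where it has them and a univariate
  score as the elimination ranking otherwise (k-NN and RBF-SVM expose
  none); keep the subset size with the best CV score.
* **Genetic algorithm**: binary masks, tournament selection (size 3),
  uniform crossover, per-bit mutation, elitism 1, 40 generations with
  early stop after 10 stagnant ones, fitness = mean CV accuracy, with
  memoisation of repeated masks. The GA's own population size,
  crossover rate and mutation rate are chosen by running one GA per
  row of a Taguchi L9 orthogonal array and adopting the best row — a
  design-of-experiments shortcut that probes 3 levels of 3 factors in
  9 runs instead of 27.

Evaluation repeats stratified 5-fold CV under multiple seeds (10 by
default) and reports accuracy, precision, recall, F1 (threshold 0.5)
and AUC per fold. The 95% CI uses `mean ± t(0.975, folds-1) * SD /
sqrt(folds)`; because it is ambiguous whether such intervals should be
taken over folds within a repeat or pooled over all fold-repeats, both
aggregations are emitted. Held-out test metrics come from one fit on
the full training set. Feature importances (gain for boosted trees,
impurity decrease for forests, per-SD absolute coefficients for
logistic regression, importance-weighted stump sums for AdaBoost) are
normalised to sum to one per model and averaged across the top three
models by CV accuracy; models without importances are excluded and
logged.

Two classifier identifiers deserve a note: `gradient_boosting` and
`light_gradient_boosting` are both served by the xgboost engine with
distinct growth policies — exact depth-wise trees without shrinkage
penalties for the former, histogram-binned leaf-wise growth
(`max_leaves`-capped) for the latter — so the grid spans the
depth-wise/leaf-wise design axis those names conventionally denote.

## Problem sizes used by the automated checks

The shipped checks run the generator calibration at 10,000 records per
class; Little's-test size and power at n = 500 (1,000 MCAR replicates)
and n = 1,000 (200 MAR replicates); the amputation procedure on
~1,200-record cohorts; the GA-versus-exhaustive-search comparison on a
10-feature problem (all 1,023 non-empty subsets enumerated); and the
end-to-end pipeline at 700–2,000 records. These sizes were chosen so
that every stochastic assertion has comfortable margins under its
stated tolerance while the whole suite stays desk-scale.

## Known limitations

* The Gaussian copula cannot express tail dependence or nonlinear
  coupling; deterministic identities between anthropometric variables
  are only approximated.
* Little's test with 0/1 indicators treats binary variables as normal;
  its size was verified empirically but the approximation degrades as
  rates approach 0 or 1.
* Chained equations produce a single completed dataset; between-
  imputation variance (Rubin's rules) is out of scope because the
  benchmark design scores point imputations.
* The GA's fitness is a CV estimate; its comparison against the
  exhaustive optimum is made under a shared fold split to isolate
  search quality from fold noise.
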