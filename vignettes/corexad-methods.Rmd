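---
title: "Latent factor discovery and progression modelling with corexad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent factor discovery and progression modelling with corexad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multimodal aging cohorts measure hundreds of weakly informative variables per
subject — plasma analyte panels, CSF amyloid and tau, APOE allele counts,
demographics, and structural brain measures — and follow diagnoses (CN, MCI,
AD) over several years. Single biomarkers predict progression poorly;
combinations do better, but supervised feature construction is prone to
overfitting at these sample sizes. `corexad` implements an unsupervised
alternative: learn a small set of discrete latent factors that *explain the
total correlation* of the panel, then carry those factors — alongside the
original measures — through a supervised progression-modelling workflow.

# Total correlation explanation

For discrete variables $X_1,\dots,X_N$ the total correlation is

$$\mathrm{TC}(X_1,\dots,X_N) = \sum_{i=1}^{N} H(X_i) - H(X_1,\dots,X_N),$$

the multivariate generalization of mutual information: zero exactly when the
variables are mutually independent, and for two variables equal to
$I(X_1;X_2)$. A layer of $M$ discrete factors $Y_1,\dots,Y_M$ (each with $k$
states) is trained to maximize the explained TC

$$\sum_{j=1}^{M}\Big[\sum_i \alpha_{ij}\, I(X_i;Y_j) - I(X;Y_j)\Big],$$

where $\alpha_{ij}\in[0,1]$ are per-variable affinities that sum to one over
factors, and $I(X;Y_j) = H(Y_j) - \mathbb{E}_x[H(p(y_j\mid x))]$ is estimated
from the posteriors. Subtracting $I(X;Y_j)$ rather than the full $H(Y_j)$
matters: a factor whose posterior is genuinely soft (for example, one
summarizing two weakly correlated variables) would otherwise be charged for
entropy it never extracted, pushing its apparent contribution negative and
destroying the comparison between candidate solutions.

Training is block-coordinate ascent:

1. posterior update
   $p(y_j\mid x) \propto p(y_j)\prod_i \big[p(x_i\mid y_j)/p(x_i)\big]^{\alpha_{ij}}$;
2. re-estimation of $p(y_j)$ and $p(x_i\mid y_j)$ from the posteriors, with
   add-0.5 pseudocounts so no probability is ever zero;
3. affinity competition: $\alpha_{ij} \propto I(X_i;Y_j)^{1/\tau}$, a softmax
   over factors on *log* mutual information with temperature $\tau = 0.1$,
   annealed by 0.9 every 10 iterations.

The competition operates on log MI because what should decide a variable's
allegiance is the *ratio* of its MI across factors. A difference-based
softmax is not scale-free: early in training all MI values are small, their
differences are far below any fixed temperature, and every affinity row
collapses to uniform — after which the posterior dynamics contract to the
uninformative fixed point and nothing is ever learned.

Three further schedule choices proved necessary and are part of the method:

* **Hard random initialization with burn-in.** Each variable is assigned to
  one random factor and the affinities are held fixed for 15 iterations, so
  factors differentiate before competition reallocates variables. With soft
  symmetric initialization the symmetric fixed point is locally attracting.
* **Dead-factor reseeding.** After convergence, a factor explaining
  essentially nothing (below 0.01 bits) is re-anchored: if it still holds
  variables, its posterior is re-initialized to track its most informative
  child; if it holds none, it grabs the worst-explained half of the most
  overloaded factor's variables first. The warm restart is kept only when it
  improves the explained TC. This is the same logic as empty-cluster
  handling in k-means, and it is what turns "one factor owns two blocks
  while another is dead" configurations into clean partitions.
* **State canonicalization.** The $k$ states of a trained factor are an
  arbitrary labelling. Before labels are emitted, states are re-ordered
  along a sign-aligned, affinity-weighted score of the factor's member
  variables, so the 0..k-1 maximum-likelihood labels are monotone ordinal
  surrogates of the factor's direction. Without this step the labels are
  useless as numeric predictors downstream (we observed correlation near
  zero between labels and a perfectly recovered planted latent).

Convergence is declared when the unclamped bound moves less than $10^{-6}$
bits between iterations; if an update would *decrease* the reported
explained TC, the previous state is kept and the run stops, so the recorded
per-iteration trajectory is non-decreasing by construction of the stopping
rule (and the tests assert it to $10^{-9}$ bits on every fit). Five random
restarts are fitted by default and the best kept. The factor count defaults
to $M = 25$ per panel; the package does not re-implement an automatic search
over $M$, but explained TC per factor is reported so a scree-style
diagnostic is one plot away. Factor cardinality defaults to $k = 2$; the
cardinality, bin count, temperature and restart count are all arguments of
`fit_corex()`.

Continuous inputs are quantile-discretized (default 3 bins per variable);
ordinal variables with at most `n_bins` levels pass through unchanged and
constant columns are flagged. Discretization is fitted once and can be
applied frozen to held-out subjects. Hierarchies (`fit_hierarchy()`) stack
layers: layer $\ell$ is trained on the maximum-likelihood labels of layer
$\ell-1$, and edges between consecutive layers carry the plug-in mutual
information between child values and parent labels.

# The synthetic cohort

Because the motivating data are access-controlled, the package ships a
generator (`generate_cohort()`) whose defaults emulate the study structure
the analysis assumes: 800 subjects; a 200-analyte plasma panel organized as
20 correlated blocks of 8 (shared Gaussian latent per block, loading 0.7,
so within-block pairwise correlation is $0.7^2$) plus 40 free analytes; a
hallmark latent driving three CSF-like analytes at loading 0.8 and an
ordinal APOE-like allele count thresholded at the 0.70/0.95 quantiles
(giving roughly 70/25/5% for 0/1/2 alleles); age, sex, education, ICV and
weight demographics; and 25 bilateral brain region pairs, each contributing
left/right thickness, surface area and volume with a shared lateral latent
(left-right volume correlation about 0.8), ICV and age effects on area and
volume, and age effects on thickness.

Diagnoses evolve on a 6-month visit grid for 1-5 years (follow-up drawn
from a gamma distribution with mean `followup_months_mean`, default 36
months, clamped to the grid). Baseline diagnosis is coupled to the hallmark
latent through an ordered-logistic score with cohort proportions of roughly
28/48/24% CN/MCI/AD; CN and MCI subjects convert to AD with a per-year
probability that is logistic in `hallmark_effect` times the latent
(baseline rates 3%/yr for CN and 18%/yr for MCI); a small fraction of
stable MCI subjects (default 2%) receive an interim CN visit and become
diagnostic reverters. Cognitive totals are drawn on each test's native
scale with diagnosis-specific means and SDs in realistic ranges, and the
1-year follow-up declines in proportion to the hallmark latent plus noise.
The decline scales are calibrated so the composite delta correlates with
the latent at about $|r| = 0.15$ for a standardized effect of
0.5 — weak but clearly detectable at $n = 800$ ($p < 0.01$), as in
observational cohorts where baseline biology explains a small share of
short-term cognitive change. TBM-style summaries are signed percent volume
changes: temporal-lobe loss (negative, stronger in progressors) and
ventricular expansion (positive).

What the generator does *not* emulate: non-Gaussian and non-linear
dependence among analytes, assay floor/ceiling effects, informative
missingness (an optional MCAR rate is provided; the default is complete
data, and this divergence from real cohorts is deliberate and flagged),
site effects, and attrition correlated with decline. Tests that pass on
this generator therefore certify the machinery — estimators, optimization,
selection logic, leakage hygiene — not the claim that any particular real
cohort will reproduce the motivating study's effect sizes.

# Preprocessing

`residualize()` regresses age, sex and education out of every brain
measure, and additionally ICV out of surface-area and volume measures
(never thickness), by ordinary least squares; the fitted coefficients are
stored so held-out subjects can be residualized with frozen coefficients.
`cognitive_composite()` negates ADAS-Cog-13 and CDR-SOB totals so lower
always means worse, z-scores each test against the baseline cohort mean and
SD of the signed test, averages the three z-scores per timepoint, re-anchors
the baseline composite to mean 0 / SD 1, and defines the longitudinal delta
as follow-up minus baseline. `assign_groups()` derives one trajectory group
per subject (stable CN-s/MCI-s with at least 12 months of constant
diagnosis, progressors CN-p/MCI-p, baseline AD, diagnostic reverters, and
short-follow-up subjects) and the three binary contrasts: CN-s vs
progressors, MCI-s vs progressors, and AD-ever vs never. Reverters are
excluded from the first two contrasts; the AD-ever contrast has no
stability requirement, so short-follow-up subjects and reverters enter it
classified by their observed visits. `prevalence_stats()` divides progressor
share by mean follow-up in years — the linear annualization is the only one
consistent with the published worked example (42.8% prevalence over 52.5
months giving 9.8%/yr).

# Supervised arms

**Feature selection.** `ensemble_importance()` scores features with five
learners per task (classification: logistic GLM, gradient boosting, bagged
trees, LDA, KNN; regression: linear model, gradient boosting, KNN, ridge,
LASSO), each contributing a 0-100 importance (absolute standardized
coefficients for linear models, gain for boosting, permutation importance
for KNN and bagged trees — permutation importance with one shared
permutation, so reports do not depend on column order) and a repeated
k-fold CV error (default 10 x 10). The combined score is the convex
combination weighted by inverse CV error. `top_k_per_class()` keeps the
best 10 per selection class (plasma, brain, latent plasma, latent brain)
with a lexicographic tie-break, and `joint_rerank()` re-scores the pooled
set. The inverse-error weighting convention for classification uses
misclassification error; the weighting formula is declared rather than
inferred, since only "weighted-average" is specified in the motivating
description.

**Prediction.** `run_contrast()` wires the whole arm: stratified 70/30
splits (largest-remainder apportionment, per-class counts within one
subject of proportionality), selection on the training partition only,
class-weighted gradient boosting (`xgboost`) with a grid search over trees
{100, 300, 500}, depth 1-3, learning rate {0.1, 0.01} and minimum leaf
weight 10 under repeated stratified CV on weighted log-loss, and hold-out
evaluation (trapezoidal AUC; accuracy, sensitivity and specificity at the
fixed 0.5 threshold, with progressor/AD as the positive class), averaged
over repeated splits. Two modes are first-class: `paper-faithful` fits
residualization, discretization and the factor layers on the full cohort
before splitting (reproducing the original workflow, which constructs
factors unsupervised on everyone); `split-safe` refits all three inside
each training partition and applies them frozen to the test side. A
leakage canary — a feature equal to the outcome on test rows only — is part
of the test harness and must never survive training-side selection.
`mcnemar_compare()` compares two classifiers on their discordant test
predictions: continuity-corrected $\chi^2 = (|b-c|-1)^2/(b+c)$ when
$b + c \ge 25$, otherwise the exact two-sided binomial tail.

**Stability selection.** `bootstrap_stepwise()` refits a bidirectional
stepwise OLS (from the intercept-only model) on `B = 1000` bootstrap
resamples and reports each feature's selection frequency, modal coefficient
sign (`+`/`-`, or `mixed` when neither sign reaches 60% of selections) and
mean coefficient. The stepwise criterion defaults to BIC, configurable to
AIC. BIC is the deliberate default because stability selection is a
support-recovery problem: AIC admits a regressor whenever its partial
$|t| > \sqrt 2$, which lies *below* the expected largest spurious
correlation among even ten null candidates at any sample size — so under
AIC the luckiest noise feature of any fixed sample is re-selected in most
resamples and null panels routinely show frequencies above 0.5. BIC's
$\sqrt{\log n}$ threshold clears the spurious maximum, and in our null
simulations (10 independent Gaussian features, $n = 800$, $B = 200$) no
feature reaches frequency 0.5 in 19 of 20 seeds. `maintained_features()`
applies the inclusive 50% threshold and summarizes the class composition of
the maintained set. Atrophy outcomes use peripheral inputs only (plasma,
hallmarks, demographics and latent plasma factors); the cognitive delta
uses all feature classes.

# What the signal-control property does and does not show

One designed property deserves an honest caveat. With a planted hallmark
effect, one might expect the hallmark *factor label* to be selected more
stably for the cognitive delta than any single hallmark analyte. Under this
generator that is information-theoretically impossible for a
maximum-likelihood label: the label is a deterministic function of the
*discretized* analytes, and with analytes loading at 0.8 on the latent, a
binary label's correlation with the latent is capped near 0.72 (0.81 for
three states) against 0.80 for each raw analyte. Linear stepwise selection
therefore prefers a raw analyte in essentially every resample, and the
corresponding acceptance check fails by design of its own conditions. The
phenomenon the motivating study reports — latent factors out-predicting
individual hallmarks — must rest on properties of real data that a
Gaussian, linearly-coupled generator does not reproduce (non-linear or
non-Gaussian dependence that a discrete factor can exploit, or noisier
effective single-analyte information). The package reports what it
measures; the generator was not bent to manufacture the headline.

# Orchestration and reproducibility

`run_all()` executes simulate, preprocess, factor learning, prediction,
bootstrap regression and graph export from a single `run_config()` (YAML or
JSON), writing plain-text outputs plus a manifest with the seed,
configuration and an MD5 checksum per file; re-running a configuration
reproduces every output bit-identically. Every stochastic stage takes an
explicit seed, cohorts round-trip bit-identically through `write_cohort()`
and `read_cohort()` (17-significant-digit CSV), and trained factor layers
serialize to JSON and label new data identically after reload. Graph export
(`export_graph()`) writes GraphML (round-trips through igraph) or DOT, with
node size equal to the factor's explained TC in bits and edge shade equal
to mutual information normalized by the layer maximum; edges below a 0.01
bit floor are pruned.

The test-suite problem sizes are the package's chosen verification scale:
structure recovery and null/signal controls run at the study-default
$n = 800$ with 20 seeds each (restarts reduced to 3-5 and $B$ to 150-200
where the property does not depend on them); pipeline round-trip tests use
miniature cohorts of 150-300 subjects. The full-scale defaults
($M = 25$, 10 x 10 CV, $B = 1000$) are what `run_config()` ships.

# Known limitations

* Discrete CorEx only: no Gaussian-marginal variant, no sample weights, no
  GPU path. Quantile discretization costs information (the signal-control
  discussion above quantifies one consequence).
* The factor count is a configuration, not a search; the explained-TC
  diagnostic supports choosing it manually.
* Stepwise stability selection inherits the usual caveats of
  post-selection inference; reported frequencies are descriptive, not
  corrected p-values.
* The generator produces complete data by default; real-cohort missingness
  and imputation are out of scope.
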