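---
title: "Predicting behavior from multi-state functional connectomes: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting behavior from multi-state functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A functional connectome is the matrix of Pearson correlations between the
fMRI time series of pairs of brain regions — one symmetric matrix per
participant and per *brain state* (resting scan or a task such as the
monetary-incentive delay, stop-signal or N-back task). This package asks
how well such connectomes predict behavioral phenotypes (cognitive,
personality and mental-health scores) in multi-site developmental
cohorts, and — just as importantly — *which* connections carry the
prediction, whether those predictive features are shared across
behaviors of the same domain, and whether models and features transfer
from one behavior to another.

## The prediction model

The core learner is kernel ridge regression with a correlation kernel:
the similarity of two participants is the Pearson correlation between
their vectorized connectomes (strict lower triangle, row-major), and a
test participant's score is a regularized weighted average of the
training participants' scores,

$$\hat y_t = \bar y + K_{t,\cdot}\,\alpha,\qquad
  \alpha = (K + \lambda I)^{-1} (y - \bar y).$$

The target is mean-centered before the dual solve and the training mean
acts as the intercept; this is the standard identifiability convention
for ridge models. The kernel is a Gram matrix of standardized edge
vectors and hence positive semidefinite; eigenvalues are floored at zero
and a jitter of $10^{-8}\,\mathrm{tr}(K)/n$ keeps the solve well posed.

**Multistate (multikernel) prediction.** To combine the four brain
states, the combined kernel is a convex combination
$K = \sum_s w_s K_s$ with $w$ on a simplex lattice (default step 0.25)
searched jointly with $\lambda \in \{10^{-4},\dots,10^{4}\}$ (13
log-spaced points). At a lattice vertex the model reduces exactly to
single-kernel regression on that state, and the dual solve is unchanged
— this convex-combination formulation is the package's own design
choice for the multistate framework. Two control families are provided:
*mean FC* (single kernel on the per-edge Fisher-z mean across states,
which separates "more data" from "state diversity") and *linear ridge*
on standardized edges (to show that predictive features are robust to
the regression family once inverted).

## Cross-validation that respects sites

Multi-site data are not exchangeable across sites. Sites are therefore
combined into 10 *site clusters* by a deterministic greedy balancing
(sites sorted by descending size, each assigned to the currently
smallest cluster), and evaluation is leave-3-clusters-out over all
$\binom{10}{3} = 120$ folds, so a site is never split between training
and test. Within each fold:

1. head-motion confounds (mean FD, mean DVARS; optionally age and sex)
   are regressed from the target with coefficients estimated on the 7
   training clusters and applied to the 3 test clusters;
2. hyperparameters are selected by leave-one-cluster-out cross-validation
   within the training clusters, maximizing the Fisher-averaged
   validation correlation; ties break toward larger $\lambda$ (more
   regularization) and then smaller kernel-weight entropy;
3. the model is refit on the full training set and applied to the
   held-out clusters.

Accuracy is the Pearson correlation between predicted and observed
(residualized) scores, plus a coefficient of determination whose
baseline is the *training* mean of the residualized target — an
out-of-sample convention chosen because the test mean is not available
to a deployed model. Correlations are Fisher r-to-z averaged across
folds and measures.

All targets passed as columns of one matrix share the per-fold kernel
eigendecompositions, so hundreds of permuted or simulated targets cost
little more than one — this is what makes full-procedure permutation
testing practical.

## Inference

*Better-than-chance accuracy* is tested by shuffling the behavioral
measure across participants **within each site** (sites are the
exchangeable blocks) and re-running the entire nested cross-validation
per permutation; $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$,
one-tailed. *Model comparisons* use the corrected resampled t-test on
fold-paired accuracy differences: cross-validation folds share training
data, so the variance is inflated by $(1/K + n_{test}/n_{train})$; the
ratio uses per-fold counts averaged over folds. Its Gaussianity
assumption is checked with a Kolmogorov–Smirnov test on studentized
differences; because the mean and SD are estimated, this check is
conservative (the Lilliefors situation), which we accept — it can only
under-flag. Multiple comparisons are controlled with Benjamini–Hochberg
FDR at $q = 0.05$, with test families configurable by the caller rather
than hard-coded counts.

## Interpreting the models

Raw regression weights mislead in the presence of suppressor variables:
an input that only cancels noise can receive a large weight. The package
instead inverts each fitted model into *predictive features* (Haufe
inversion): for each edge and state, the training-set covariance between
the edge's connectivity and the model's predicted target, computed per
fold and averaged over folds. Pure covariance is used (no normalization
by the prediction variance); the sign convention is that positive
features mean higher connectivity predicts higher scores. For
multikernel models one feature matrix is produced per state from the
same prediction.

Downstream feature statistics:

- **Network blocks.** Features are averaged within and between the
  region groups (18 groups at the full 419-region scale: 17 cortical
  networks plus subcortex), giving $G(G+1)/2$ unique blocks (171 for
  $G = 18$). Within-block averages use unique unordered region pairs;
  singleton groups have no within-block value and are flagged missing.
- **Sign consistency.** For a pair of feature matrices, the fraction of
  unique blocks with matching sign, against the analytic chance level
  $p^2 + (1-p)^2$ for a pooled positive fraction $p$. Exact zeros agree
  only with zeros — a conservative, measure-zero convention.
- **Block significance.** A within-site permutation null re-runs each
  fold (confound regression, refit, inversion, block average) on the
  shuffled target. By default the permutation refits reuse the fold's
  previously selected hyperparameters — the selection is ancillary under
  the null and re-searching for 2000 permutations is disproportionate —
  but `reselect = TRUE` re-runs the full search.
- **Conjunction and region maps.** Blocks significant in *all* states
  with the same sign everywhere keep their cross-state mean; region-level
  maps sum positive and |negative| features across each region's row,
  with percentile ranks.
- **Similarity and clustering.** Feature matrices are vectorized,
  concatenated across states, and correlated across behaviors; behaviors
  are clustered by average-linkage (UPGMA) hierarchical clustering on
  the correlation distance via `stats::hclust`, cut at $k = 3$ domains.
  Domain-average feature matrices weight measures equally (accuracy
  weighting was considered and rejected as an extra researcher degree of
  freedom).

## Cross-behavior generalization

*Model transfer* predicts a target behavior as the average of other
behaviors' model predictions on the same fold (donors z-scored within
fold before averaging — behaviors live on different scales, and Pearson
accuracy is scale-invariant anyway). *Feature transfer* goes further and
discards the donors' models entirely: donor features are averaged across
donors and states, the top 10% of edges by |feature| are selected using
training-fold information only, and the prediction is the mean
connectivity over positive-feature edges minus the mean over
negative-feature edges (participant connectivity is the Fisher-mean
across states). Ties at the selection boundary break by edge index.

One caveat established during validation: on a *single* cohort the
cross-domain transfer accuracy is not exactly zero even when the domain
factors are independent, because the sample correlation between factors
($|\rho| \sim 1/\sqrt{n}$) is amplified by the model accuracy on both
sides; at $n = 400$ this produces values around $\pm 0.1$. Transfer is
zero across orthogonal domains in expectation, and the meaningful
comparison is within-domain versus between-domain on the same folds.

## The synthetic cohort generator

The study's data are access-restricted, so validation runs on a
generator whose *defaults are the study conditions* of this package:
400 participants, 60 regions in 6 networks, 10 sites, 4 states, and
16 + 9 + 11 measures in three domains (cognition, personality, mental
health). Connectivity is assembled in Fisher-z space, which is closed
under addition, and mapped through tanh so entries stay in $(-1, 1)$:

- a dominant participant-level edge profile shared across states
  (SD 0.5) with small state-specific modulation (SD 0.1) — individual
  differences dominate task modulation, the regime the analysis assumes;
- per-domain latent factors expressed on disjoint planted edge sets
  (5% of edges each, effects ~0.35 z-units), with each measure mixing
  the domain factor (share 0.8) with a measure-specific, brain-unrelated
  factor;
- a motion confound entering both connectivity (uniform +0.15 z per SD
  of mean FD) and behavior (calibrated to a 0.3 motion–behavior
  correlation);
- additive site offsets on behavior (SD 0.2), so that within-site
  permutation differs measurably from a global shuffle.

Where the source literature does not characterize true effect sizes,
these values were chosen once for testability — strong enough that
planted structure is recoverable at desk scale, weak enough that noise
behaviors stay at chance — and not revisited. The generator does **not**
emulate hemodynamics, parcellation geometry, family/heritability
structure, scanner differences, or realistic behavioral distributions
(skew, floors); passing recovery tests therefore demonstrates the
pipeline's internal correctness and calibration, not expected real-data
effect sizes. Real-data accuracies are far lower than the synthetic
ones.

## Problem sizes used in the shipped validation

The test suite and acceptance script run at the default desk scale. Two
deliberate economies: the type-I-error study (200 repetitions x 99
within-site permutations, batched as 20,000 target columns) fixes the
ridge penalty instead of re-running the inner search — permutation
validity does not depend on the selection rule — and the
domain-structure study (20 generator seeds) uses the mean-FC family,
whose features are representative of all families once Haufe-inverted.
The multikernel weight lattice uses step 0.5 in the acceptance script's
comparison run; the package default remains 0.25.

## Known limitations

- The multikernel objective is a convex combination with a shared
  penalty; per-kernel penalties are not implemented.
- Upstream image processing (registration, filtering, global-signal
  regression) is out of scope: inputs are region-level time series or
  ready connectomes. Frame censoring, run QC and the 4-minute state rule
  are implemented on the time-series side only.
- Confounds are regressed from behavior, not from connectivity.
- Block permutation p-values have a floor of $1/(B+1)$; at the default
  $B = 2000$ the smallest attainable p is $5 \times 10^{-4}$.
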