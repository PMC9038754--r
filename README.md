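# predictome

Connectome-based behavioral prediction with multikernel ridge regression
and Haufe feature inversion.

## What this package is for

Large developmental neuroimaging cohorts ask whether a child's
functional connectome — the matrix of Pearson correlations between
regional fMRI time series, one per brain state (rest, monetary-incentive
delay, stop-signal, N-back) — predicts cognitive, personality and
mental-health scores, and which connections carry that prediction.
`predictome` implements the full analysis for researchers working with
such data:

- **Connectome construction** with motion-based quality control: frames
  with FD > 0.3 mm or DVARS > 50 are censored together with 1 frame
  before and 2 after, surviving segments shorter than 5 frames are
  dropped, runs with more than half their frames censored or max FD >
  5 mm are excluded, states with under 4 minutes of usable data are
  discarded, and per-run Pearson FC matrices are Fisher-z averaged.
- **Prediction** by kernel ridge regression with a correlation kernel:
  a test participant's score is the regularized weighted average
  \(\hat y_t = \bar y + K_{t,\cdot}(K+\lambda I)^{-1}(y-\bar y)\), where
  \(K_{it}\) is the Pearson correlation between participants' vectorized
  connectomes. Brain states combine through a convex multikernel
  \(K=\sum_s w_s K_s\); mean-FC and linear-ridge control families are
  included. Evaluation is leave-3-site-clusters-out nested
  cross-validation (10 greedily balanced site clusters, 120 folds,
  never splitting a site), with head-motion confounds regressed from
  behavior using training-fold coefficients only.
- **Interpretation** by Haufe inversion: each model becomes a
  region-by-region predictive-feature matrix (covariance of each edge
  with the model's prediction), robust to suppressor variables, then
  network-block averaging, sign-consistency statistics against the
  analytic chance level \(p^2+(1-p)^2\), within-site permutation tests
  per block, cross-state conjunctions and region-level maps.
- **Generalization**: cross-behavior model transfer (averaged donor
  predictions) and feature transfer (aggregate FC over the top 10% of
  donor feature edges).
- **Inference**: within-site permutation nulls re-running the entire
  nested CV (batched, so hundreds of permutations are cheap), corrected
  resampled t-tests for fold-paired comparisons, a KS Gaussianity
  check, and Benjamini–Hochberg FDR.
- **A synthetic-cohort generator** with planted ground truth
  (domain-structured behaviors on disjoint edge sets, a dominant
  individual connectivity component, motion confounding, site effects)
  so every claim above is testable without access-restricted data.

## Worked example

```r
library(predictome)
library(SummarizedExperiment)

cohort <- generateCohort(cohortConfig(nParticipants = 200, nRegions = 30,
                                      seed = 42))
cset <- cohort$connectomes
cset
#> ConnectomeSet: 30 regions (435 edges) x 200 participants
#>   states: rest, mid, sst, nback
#>   networks: 6 groups
#>   sites: 10

clusters <- buildSiteClusters(colData(cset)$site, nClusters = 10)
fit <- nestedCV(cset, cohort$behavior$cognition_01, family = "multikernel",
                clusters = clusters, kTest = 3, weightStep = 0.5)
fit
#> PredictionResult (multikernel): 120 folds x 1 measure(s)
#>   Fisher-mean r: y001=0.687
```

The Fisher-mean test correlation of 0.687 says the multikernel model
predicts the planted cognition measure well out of site-cluster — at
this synthetic signal strength, not a real-data effect size. A
within-site permutation test confirms it is far above chance:

```r
perm <- permutationNullAccuracy(cset, cohort$behavior$cognition_01,
                                nPerm = 19, seed = 7,
                                family = "single_kernel", state = "rest",
                                clusters = clusters, kTest = 3)
c(observed = round(perm$observed, 3), p = perm$p)
#> observed        p
#>    0.687    0.050   # the floor, 1/(19+1)
```

Inverting the model yields one predictive-feature matrix per state;
block averaging summarizes it over network pairs (values are
edge-prediction covariances, scaled here by 1000):

```r
feats <- haufeInvert(cset, fit)
blocks <- blockAverage(featureMatrix(feats, "nback", 1), networkLabels(cset))
round(blocks[1:3, 1:3] * 1000, 3)
#>        net01  net02  net03
#> net01 -0.119  0.048 -0.032
#> net02  0.048  0.306 -0.097
#> net03 -0.032 -0.097 -0.059
round(100 * consistencyChanceLevel(uniqueBlocks(blocks)), 2)
#> 50.11   # chance level of sign agreement for this block pool
```

Positive blocks mean higher connectivity within/between those networks
predicts higher scores. `runPipeline()` chains generation, all model
families, inversion, clustering, transfer and permutation testing into
one output directory with a JSON manifest.

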