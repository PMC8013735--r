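---
title: "Dynamic connectivity states: model, estimators and design choices"
author: "dfcstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

Resting-state network dynamics are summarized in four steps. First, each
subject's node time courses (here: seven default-mode subnodes in precuneus,
anterior and posterior cingulate) are converted into a sequence of windowed
connectivity estimates with a tapered sliding window. Second, the windows of
all subjects are pooled and partitioned by k-means under correlation distance
into K recurring *connectivity states*; K is chosen by the elbow criterion on
the within/between cluster-distance ratio. Third, each subject's window-wise
state sequence is reduced to the K&sup2; empirical transition probabilities
`P(j->i)`, a compact dynamical fingerprint. Fourth, those fingerprints carry
the inference: per-state elastic-net logistic regression quantifies
patient-control separability and ranks connectivity features by how long they
survive along the regularization path, and covariate-adjusted partial
correlations with Benjamini-Hochberg FDR relate transition probabilities to
symptom severity. Because raw clinical fMRI cannot ship with a package, a
covariance-switching simulator generates cohorts with known ground truth, and
the test suite validates every stage by parameter recovery.

# Windowed connectivity

## The taper

The window is a rectangle smoothed by a Gaussian: a unit rectangle spanning
`windowTRs` = L TR intervals (40 s at the default L = 20, TR = 2 s) is
convolved with a unit-mass Gaussian kernel of standard deviation
`sigmaSeconds` = 3 s sampled on an integer grid out to four standard
deviations (truncation error < 1e-4), and the result is cropped to its
central L + 1 samples and renormalized to unit sum.

Two details deserve justification:

* **Support of L + 1 samples.** A window whose *duration* is L TR intervals
  touches L + 1 sample points (fencepost counting), and a rectangle of L + 1
  samples convolved with an odd symmetric kernel has odd length, so the
  central L + 1 crop is exactly symmetric — an even-length rectangle would
  make a symmetric odd-length crop impossible. This convention also fixes the
  window count at T = N − L with unit step, which reproduces both scan
  lengths of interest: 144 usable timepoints give 124 windows and 157 give
  137.
* **Unbiased weighted covariance.** Within each window the node signals
  (z-scored per subject over the whole series, so feature scales are
  comparable across subjects) are summarized by the taper-weighted
  covariance with the weighted mean removed and the reliability-weights
  correction `1 / (1 - sum(w^2))`. Without the correction the estimator is
  biased downward by about 6% at these window sizes; with it, the mean over
  windows of an i.i.d. stretch recovers the generating covariance, which the
  tests assert against a brute-force oracle.

A `--window-stat` style switch is exposed as `stat = c("covariance",
"correlation")` in `slidingDFC()`/`computeDFC()`; covariance is the default.
The 21 node-pair features are the strict upper triangle in row-wise order;
the feature-to-pair map is serialized with every output.

# State decomposition

`kmeansCorrelation()` implements Lloyd's algorithm with distance
`d(x, c) = 1 − Pearson(x, c)`, arithmetic-mean centroid updates (not
renormalized, matching common dynamic-connectivity practice), k-means++-style
seeding, and best-of-`nReplicates` selection by total within-cluster
distance. Convergence is declared when assignments stop changing; an emptied
cluster is re-seeded from the window farthest from its assigned centroid.
The phrase "1,000 iterations" in this literature is ambiguous between Lloyd
iterations and restarts; here `maxIter = 1000` bounds Lloyd iterations per
replicate and `nReplicates` (default 50) controls restarts, both
configurable. Windows of all subjects and both groups are pooled before
clustering. A window with zero variance across features has no defined
correlation distance; such windows are rejected with advice to drop or
jitter them rather than silently perturbed.

`selectKElbow()` computes, for each candidate k, the ratio R(k) of mean
within-cluster distance to mean between-centroid distance and selects the
interior k maximizing the discrete second difference
R(k−1) − 2R(k) + R(k+1); ties go to the smallest k. The criterion names the
quantity, not the knee detector, so the detector is our choice; the second
difference is the simplest one that is exact for a piecewise-linear elbow.
The *knee strength* — the maximal second difference divided by the curve's
total drop — is returned so a weak elbow is visible: on structureless data
(a single isotropic Gaussian) strengths fall well below the 0.15 flag
threshold, while the five-state preset sits around 0.25-0.40. Ranges shorter
than three candidates cannot support the rule and fall back to the smallest
candidate with a warning.

`matchStates()` aligns two centroid sets by maximizing total Pearson
correlation over one-to-one assignments (exact enumeration up to 8 states,
greedy beyond, partial greedy matching for unequal K) and always returns the
full similarity matrix so weak matches stay visible. `stateSummary()`
averages centroids within and between anatomical node groups, the six-block
summary used for three groups.

# Transition features

The state sequence is treated as an observed first-order chain:
`matrix[j, i]` is the count of j-to-i steps divided by the occupancy of j
before the final window — the maximum-likelihood transition frequencies.
No latent-chain (Baum-Welch) fitting is performed: with hard k-means
assignments the observed-state estimator is exactly the conditional
probability of interest, and full hidden-Markov fitting is out of scope.
Rows for states never occupied before the final window are zero, flagged,
and propagated as NA in the flattened subject-by-K&sup2; feature matrix so
that downstream correlations drop them pairwise; no Laplace smoothing is
applied by default (a pseudo-count argument would be trivial to add, but
smoothing would bias the planted-link recovery checks). Storage is
`[from, to]` row-major with names `P(j->i)`, making the direction convention
unambiguous in every output. Occupancy and mean dwell time are provided as
auxiliary summaries.

# Group discrimination

Per state, the default sample is one row per subject: the elementwise median
of the subject's windows assigned to that state. The alternative
window-level unit is retained (`sampleUnit = "window"`) with folds grouped
by subject, but subject-median is the default because window-level samples
from one subject are strongly dependent and would leak across
cross-validation folds. Subjects without windows in the state are excluded
and listed.

`nestedCVClassify()` runs 10-fold nested cross-validation with a 9:1
train-test ratio in both loops (outer 10, inner 9). The inner loop fits the
elastic-net logistic path — mixing parameter alpha, default 0.5 as the
conventional equal L1/L2 compromise since no value is dictated by the
problem, and a fixed grid of 100 logarithmically spaced penalties between
1e-5 and 1e5 — and selects the penalty minimizing inner-CV
misclassification error (ties to the sparser model). Features are z-scored
with training-split statistics only. Outer-fold test predictions are pooled
into a single ROC/AUC. Feature importance is the *retention proportion*: the
fraction of inner models (inner folds x grid points) in which a feature's
coefficient stayed nonzero. A one-way ANOVA across features on per-fold
retention followed by Tukey comparisons (family level 0.05) yields the group
of top features — the feature with maximal mean retention plus everything
not significantly below it. Group differences over that set use Welch
two-sample tests with BH correction within the state's selected set; the
test behind published "corrected p" thresholds in this setting is typically
unspecified, and Welch + BH is the robust default. Degenerate cases are
defined away explicitly: a feature constant in both groups gets p = 1, and
identically-zero retention variance returns all features with a warning.

# Symptom association

`partialCorrelation()` residualizes both variables on an intercept plus the
covariate design by least squares and correlates the residuals; the p-value
uses `t = r sqrt((n − 2 − k) / (1 − r^2))` on n − 2 − k degrees of freedom.
Categorical covariates enter as indicator columns; covariates constant over
the subjects in use (e.g. a single acquisition site) are dropped rather than
breaking the design. Missing symptom scores are handled by pairwise
deletion, mirroring cohorts where a few patients lack scores. The FDR family
is the K&sup2; transition features within one symptom scale; pooling scales
into one family is a defensible alternative and a one-line change, but
per-scale families match the convention of correcting over the feature set
reported per scale. Residuals that are numerically constant (a variable that
is an exact function of a covariate) make r undefined; it is reported as NA
with a degeneracy note rather than 0.

# The synthetic cohort

`generateCohort()` draws, per subject, a hidden state sequence from a
first-order Markov chain (uniform initial state) and, at each timepoint, a
zero-mean Gaussian node vector with the active state's covariance. This is
the simplest generative model under which the windowed-covariance + k-means
pipeline is consistent, and it defines exactly what "truth" means for
recovery tests: per-timepoint states, per-group transition matrices, and the
per-subject empirical 2-to-4 transition probability underlying the symptom
link. Window-level truth labels are the taper-weighted majority state over
the window's support.

The default preset (`defaultCohortConfig()`) emulates a single-site
schizophrenia cohort: 89 controls and 68 patients, seven nodes, five states,
144 timepoints at TR = 2 s (149 volumes minus five discarded dummy scans).
Its design values, chosen once:

* **State covariances.** Unit-variance rank-one patterns
  `(1 − a^2) I + a^2 h h'` with `a = 0.8` and `h` five near-orthogonal
  sign patterns over the seven nodes (rows of an order-8 Hadamard matrix
  with the constant column dropped). Vectorized centroids of different
  states correlate below 0.3 — the documented "well-separated" regime that
  makes elbow-recovery tests meaningful.
* **Group contrasts.** Precuneus-posterior-cingulate coupling is raised by
  0.15 in patients in states 1 and 4, and anterior-cingulate coupling is
  lowered by 0.15 in patients in states 2 and 4; matrices are floored to a
  minimum eigenvalue of 0.05 afterwards.
* **Dynamics.** Self-transitions of 0.985 (mean dwell ~130 s) keep windows
  state-pure enough for label-recovery checks while every state still
  recurs across a 40-subject cohort. Patients enter state 2 more often
  (0.0075 vs 0.00375 per step) and leave it faster (self-transition 0.90),
  with the exit toward state 4 elevated (0.04); this makes the 2-to-4
  probability estimable in most patients, which the symptom link needs.
* **Symptom link.** The PANSS-total score is
  `58 + a P̂(2->4) + N(0, 15)`, with the slope calibrated against the
  cohort's empirical spread of `P̂(2->4)` so the correlation hits the target
  (default 0.40) in expectation; positive and negative scales are
  independent noise. About 6% of patients have missing scores, emulating
  scores being available for 64 of 68. An infeasible link (no spread in
  `P̂`) is an error, not a silent degradation.
* **Covariates.** Age, gender and site are generated independent of
  symptoms, so covariate adjustment is a no-op in expectation; an optional
  multi-site preset (`nSites`, `siteEffect`) plants a site confound to
  verify that adjustment removes it.

What the generator deliberately does **not** emulate: hemodynamic response
and within-state temporal autocorrelation, scanner noise and motion
artifacts, spatial maps (the package consumes node time courses, not
images), eyes-open/eyes-closed differences, and any within-group
heterogeneity of covariance structure. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real fMRI confounds.

# Numerical conventions and degenerate inputs

* Ties: elbow ties go to the smallest k; penalty-selection ties to the
  largest (sparsest) penalty; assignment ties to the first state.
* Row-stochasticity is enforced to 1e-12; taper weights sum to 1 to 1e-12;
  oracle equivalences are asserted to 1e-10.
* Reruns with one master seed are identical: every stochastic stage derives
  its seed as a hash of the master seed and the stage name
  (`deriveSeed()`), recorded in the provenance JSON.
* Constant signal columns z-score to zero (their pairs have zero
  connectivity); constant windows are rejected before correlation-distance
  clustering; unvisited transition rows are flagged, not smoothed.

# Problem sizes in the shipped checks

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in a few minutes on one core: 40-subject cohorts for state
recovery (10 master seeds), 150 patients for link recovery (50 replicates),
200 null replicates for FDR calibration, chains of length 1e5 for
transition-estimator convergence, and 10-20 nested-CV replicates for
classifier calibration. These sizes give Monte-Carlo slack comfortably
inside the asserted tolerances; all are parameters, not constants, so larger
studies are a function call away.

# Known limitations

Correlation-distance k-means with arithmetic-mean centroids is the field's
convention but lacks a strict descent guarantee under this metric (the tests
assert non-increase empirically to 1e-8). The elastic-net path at extremely
small penalties can be unstable under perfect separation; iterations are
capped and finite estimates kept. The elbow criterion degrades gracefully
but cannot manufacture a knee where cluster structure is absent — the knee
strength should always be inspected. Finally, the per-state classification
sample size equals the number of subjects visiting the state, which can be
small for rare states; such states are reported as skipped rather than
classified from too little data.
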