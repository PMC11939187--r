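---
title: "maldiDx: methods and design notes"
author: "maldiDx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maldiDx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiDx)
```

# Scope

`maldiDx` implements a complete MALDI-TOF serum-peptidome diagnostic
workflow: spectrum cleaning, peak detection, cross-sample alignment into a
relative-area feature matrix, volcano-style differential screening,
multi-classifier benchmarking, attribution-based consensus feature
selection, clinical-utility validation (Youden-optimised ROC and decision
curves), and unsupervised concordance checks. Because case–control serum
cohorts of this kind are generally not deposited, the package ships a
synthetic cohort generator with a full ground-truth channel; every
statistical claim the test suite makes is made against that known truth.

# The synthetic cohort model

`generateCohort()` simulates, per replicate spectrum, on a common m/z grid:

* a shared set of Gaussian peptide peaks (per-peak area $A_p$, common
  width $\sigma$ in Da). Gaussians are the standard linear-mode MALDI peak
  approximation and are analytically integrable, so the planted "true
  area" is exact;
* log-normal between-sample intensity variation with a configurable
  coefficient of variation (CV), and a tighter log-normal replicate CV on
  top — multiplicative noise matches strictly positive intensities and
  makes fold-change semantics exact on the mean scale;
* a smooth baseline $b(m) = a\,(e^{-4u} + 0.15(1-u)^2)$, $u$ the relative
  position in the mass range — the slowly decaying morphology that white
  top-hat correction is designed to remove;
* additive Gaussian trace noise;
* one uniform mass drift per spectrum within ±`massJitterPpm`
  (instrumental drift), applied to all centroids of that spectrum;
* Poisson-count spurious "matrix cluster" peaks confined to m/z
  1500–2000.

Differential structure is planted by multiplying the cancer-group mean
areas of `nUp` peaks by $2^{\mathrm{log2fcUp}}$ and of `nDown` peaks by
$2^{\mathrm{log2fcDown}}$, so the true group-mean log2 ratio equals the
configured effect exactly.

The frozen reference configuration, `defaultCohortConfig()`, mirrors the
study design the package targets: 240 cancer and 249 healthy samples in
triplicate over 1000–15,000 Da (1 Da grid), 120 shared peaks, 19
upregulated and 23 downregulated peaks at log2FC ±2, 15% within-group CV,
5% replicate CV, ±1500 ppm drift, and 0.3 expected artifact peaks per
spectrum. Peak centroids are drawn log-uniformly with a minimum relative
spacing of 1.2% so that drifted copies of *different* peptides can never
fall inside one alignment window; with 120 peaks over a 15-fold mass
range this is an unconstrained draw in practice. The remaining free
choices (baseline amplitude 20, noise SD 1, mean peak area 600 with
0.45 log-SD) were set once to give realistic peak signal-to-baseline and
signal-to-noise ratios for linear-mode serum profiling and are not
revisited by any test.

What the generator deliberately does **not** model: isotope envelopes,
adducts, detector saturation, mass-dependent resolution, or correlated
biological covariation between peptides. Tests passing on these cohorts
therefore demonstrate the correctness of the pipeline's computations, not
its performance on real sera.

# Preprocessing

The cleaning cascade is fixed as Savitzky–Golay smoothing (window 21,
polynomial order 10), centered moving-median despiking (window 10), then
white top-hat baseline removal (flat structuring element, 11 points):

* The SG order of 10 is unusually high — the filter is nearly
  interpolating — but it is kept as the pipeline's standard setting and
  exposed as a parameter. Edges use the filter's polynomial-extension
  transient correction so the trace length never changes.
* The median window of 10 is even; the window is implemented as centered
  with left bias (covering $i-5,\dots,i+4$) with reflected padding, and
  the even-count median is the mean of the two central order statistics.
  This choice is frozen and regression-locked by the tests.
* Top-hat output is clipped at zero: peak areas must be non-negative, and
  the opening can exceed the signal only in noise troughs.

A practical consequence of the median window (10) exceeding the default
peak FWHM (~7 grid points at $\sigma$ = 3 Da, 1 Da grid) is that peak
apices become short plateaus. Peak detection therefore finds local maxima
on the run-length-compressed trace, taking the plateau centre as the
apex.

# Peak detection and alignment

`detectPeaks()` keeps local maxima with height ≥ 3% of the spectrum
maximum and width ≥ 5 grid points at half prominence. Peak bases are the
lowest points between the apex and the nearest higher signal on either
side; the centroid is the intensity-weighted mean m/z over the
half-prominence region (sub-grid accuracy), and the area is the
trapezoidal integral between the bases.

`greedyAlign()` builds consensus features iteratively: seed at the
unassigned peak of greatest intensity, collect each spectrum's nearest
unassigned peak within 2500 ppm of the consensus centroid (at most one
peak per spectrum per feature), recompute the centroid as the
intensity-weighted mean of members, and repeat until membership
stabilises. Three design points deserve note:

* seeding order is by peak intensity descending — the algorithm is
  specified only as "greedy", and intensity order is deterministic and
  favours genuine peptide signal;
* the tolerance is measured against the *moving* consensus centroid, not
  the seed, which is what lets a 2500 ppm window absorb ±1500 ppm
  per-spectrum drift (two drifted copies can be 3000 ppm apart yet both
  within 1500 ppm of their mean);
* matrix cells are relative areas with the sample's total *detected peak
  area* as denominator (not the raw total ion current), matching
  peak-level relative quantification; each spectrum's detected values sum
  to 1.

Peaks in the matrix-cluster window (1500–2000 Da) are **flagged, not
removed**, by default: spurious matrix adducts live there, but genuine
differential peptides are reported in that range too, so destructive
exclusion is opt-in (`flagMatrixRegion(exclude = TRUE)`).

Missing cells are imputed as zeros by default (absent = below detection
floor); linear interpolation from the same spectrum's flanking features
is available, mainly for workflows that treat the matrix as a smooth
profile. Replicates are aligned individually and collapsed afterwards by
averaging — aligning first keeps the replicate-level provenance mask
exact.

# Differential screening

Per feature, a two-sided Mann–Whitney U test compares the groups — the
rank test is the package's documented choice; the screening convention it
reproduces does not name its per-feature test, and the rank test is the
distribution-free default for skewed intensity data. The exact null
distribution is used when the smaller group has ≤ 8 samples and values
are tie-free, otherwise the tie-corrected normal approximation. Fold
changes are $\log_2((\bar x_c + \epsilon)/(\bar x_h + \epsilon))$ with
$\epsilon$ = 1e-9 of the grand mean guarding zero-imputed means. Raw
p-values are thresholded (p < 0.001, |log2FC| > 1) without multiplicity
correction, matching the screening convention; BH correction is available
via `differentialTest(adjust = "BH")`.

# Classifier benchmark

Eight classifiers run under stratified 5-fold cross-validation: k-nearest
neighbours (k = 5), RBF SVM, Gaussian naive Bayes, a CART decision tree,
a 500-tree random forest, XGBoost (100 rounds, learning rate 0.3, depth
6), discrete AdaBoost (SAMME) over 50 depth-1 stumps, and a leaf-wise
histogram gradient-boosting model (100 rounds, learning rate 0.1, 31
leaves, the LightGBM-style growth strategy, run on the xgboost backend).
Hyperparameters are the respective libraries' defaults, frozen here; no
tuning is performed. Standardisation (train-fitted, applied to held-out
folds) is applied only to the scale-sensitive models (knn, SVM). AdaBoost
probabilities come from the logistic of the ensemble margin — monotone in
the margin, so ROC/AUC are unaffected by the particular link.

Out-of-fold probabilities give per-fold one-vs-rest AUCs for both classes
(identical in the binary case, reported per class for symmetry with
multi-class reporting conventions), and the pooled confusion matrix is
taken at the 0.5 probability operating point, which is the natural
default when no operating point is specified.

# Attribution and consensus

Three attribution routes feed a majority-voting consensus:

* **Impurity importances** from the tree models, normalised to sum to 1.
* **Kernel SHAP**, written in-package: the value of a coalition is the
  model output averaged over a background sample (convention: 200
  training rows) with the coalition's features pinned to the explained
  instance; Shapley values are recovered by Shapley-kernel weighted least
  squares. For ≤ 11 features the proper coalitions are fully enumerated
  and the result is the exact Shapley value (the tests verify the linear
  closed form $\phi_j = \beta_j(x_j - \bar b_j)$ and the symmetry axiom);
  beyond that, coalitions are sampled with size frequencies proportional
  to the kernel under a frozen budget of $2^{\min(d,11)}$ capped at 2048.
  Local accuracy holds by construction in both regimes.
* **LIME-style surrogates**: per instance, 5000 Gaussian perturbations
  drawn from the training distribution, weighted by an exponential kernel
  of width $0.75\sqrt d$ on standardised Euclidean distance, fitted with
  a ridge surrogate; the 10 largest-magnitude weights are kept per
  instance and aggregated into a global signed mean with ranks by mean
  absolute weight.

`consensusTopK()` selects every feature in the top-k of ≥ 2 of the 3
methods, then fills remaining slots by ascending average rank; ties break
by the canonical ascending-m/z feature order, and the result is invariant
to the order the rankings are supplied in.
`importanceIntersection()` implements the stricter cross-validated
cross-model check: each of the four tree models is refit on the training
portion of every stratified fold, a feature enters a model's stable set
only if it ranks in the positive top-m (default m = 10; the convention
it mirrors reports only the outcome, so m is exposed) on *every* fold,
and the models' stable sets are intersected. Two details matter. A
zero-importance feature never counts as top-ranked — rank ties among
unused features are bookkeeping, not evidence. And the fold-level
intersection is what removes "lucky" noise features: a spurious
separation present in the full data set ranks high in every model (the
luck is in the data, shared by all learners), but it does not replicate
across fold resamples, whereas genuinely dominant features do.

# Clinical validation

`youdenOptimize()` scans 100 equally spaced thresholds over the score
range, computing sensitivity, specificity and $J = SEN + SPEC - 1$ from
the confusion matrix at each, and reports the J-maximising threshold
(lowest on ties). Single-feature ROC orients scores by expression
direction first (cancer mean above healthy mean → "highly expressed").

Decision-curve analysis uses the model formula
$NB(t) = TP/N - (FP/N)\,t/(1-t)$ on out-of-fold probabilities
(positive call: probability ≥ t), with fold means and normal 95% bands
($\pm 1.96\,SD/\sqrt k$), and the area of the positive-benefit region by
composite Simpson integration (a trailing trapezoid absorbs an odd
interval count). Two treat-all variants are provided: the `"as_printed"`
default divides by (TP + TN) under the classify-everyone-positive rule —
reproducing verbatim a published formula whose denominator reduces to the
positive count and inflates the curve by exactly 1/prevalence — and
`"standard"`, the textbook $\pi - (1-\pi)\,t/(1-t)$ that crosses zero at
t = prevalence. The discrepancy is documented and tested rather than
silently corrected. For single-feature decision curves the probability
axis is mapped to value cutoffs through the feature's empirical quantiles
(direction-aware), the package's own resolution of a mapping that the
convention leaves unstated.

# Unsupervised concordance

Both clustering functions accept `standardize = TRUE` to z-score the
features first; the pipeline uses it because relative-area matrices live
on a scale of ~1/number-of-peaks, far below the unit-scale radius
threshold BIRCH conventionally assumes (at the raw scale every sample
would be absorbed into a single leaf entry).

Bisecting K-means recursively 2-means-splits the cluster with the largest
within-cluster SSE (10 restarts, seeded); the split-selection rule is
frozen since only "recursive binary splitting" is conventionally
specified. BIRCH builds a clustering-feature tree (leaf-entry radius
threshold 0.5, branching factor 50) and Ward-clusters the leaf centroids
into k groups — the global stage is unnamed in the convention, and Ward
agglomeration is the deterministic standard choice. Concordance against
class labels is reported as the plain Rand index, the adjusted Rand
index, and adjusted mutual information under the permutation model
(expected MI by the exact hypergeometric sum; the tests verify it against
brute-force enumeration of label permutations). Embeddings (PCA, RBF
kernel PCA with a median-heuristic bandwidth, t-SNE, UMAP) are seeded and
intended for visualisation only.

# Numerical and scale choices

* All randomness flows from explicit integer seeds; the pipeline fans a
  single global seed out to fixed per-stage offsets.
* The reference cohort (489 samples × 3 replicates, 14,001-point grid)
  processes end to end in a few minutes on one CPU; the test suite uses
  that cohort once (cached per session) for the study-scale checks and
  much smaller cohorts (tens of samples, reduced mass ranges) for unit
  and property tests, with problem sizes chosen so the whole suite stays
  interactive.
* Kernel SHAP cost scales as coalitions × background rows × explained
  instances; the pipeline defaults (budget 256, 8 instances) keep the
  full run tractable, while exactness-critical tests use full enumeration
  at small d.
* Degenerate inputs are handled explicitly: all-zero spectra yield empty
  peak lists (not errors), constant indicators yield AUC 0.5 with a
  warning, zero-denominator metrics report 0 with a warning, and
  duplicate alignment centroids are perturbed by 1e-9 Da to keep the
  feature axis strictly increasing.

# Known limitations

The generator's independence assumptions (peaks vary independently across
samples) make the classification task easier than real serum profiles
with correlated biology; perfect cross-validated AUCs on the reference
cohort certify the pipeline plumbing, not clinical performance. The BIRCH
implementation rebuilds no tree (no rebuilding pass on threshold
overflow), matching the single-pass textbook construction. mzML ingestion
is a thin optional wrapper and assumes profile-mode single spectra per
scan.
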