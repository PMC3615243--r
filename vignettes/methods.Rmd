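---
title: "Methods: CAD and lateralization of TLE from interictal FDG-PET ROI metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAD and lateralization of TLE from interictal FDG-PET ROI metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interictal FDG-PET (iPET) images glucose metabolism between seizures.  In
temporal lobe epilepsy (TLE) the seizure-onset zone and functionally
connected regions are typically hypometabolic, and the asymmetry between
temporal lobes carries lateralizing information.  `tlecad` classifies a
patient as left TLE (LTLE), right TLE (RTLE), or non-epileptic seizures
(NES — the clinically relevant control group) from 47 region-of-interest
(ROI) mean metabolism values, each normalized by whole-brain
radioactivity, as produced by NeuroQ-style segmentation.  The package
does not touch images: its input is the per-patient ROI feature table.

# The pipeline

For a task (LTLE vs NES, RTLE vs NES, or the trinary problem) the
pipeline is, inside **every** cross-validation fold:

1. **Quantize** each candidate feature into `Q` equal-width histogram
   bins spanning the training range (the class label stays categorical).
2. **Rank** features by greedy minimum-redundancy-maximum-relevance
   (mRMR): the first feature maximizes the plug-in mutual information
   `I(f; c)` in bits; each next pick maximizes
   `I(f; c) − mean_{s ∈ S} I(f; s)` over the already-selected set `S`
   (the MID score; the MIQ quotient variant is available via
   `mrmr_config(variant = "MIQ")`).  The top `F` features are kept.
   Classification uses the *unquantized* features — the bins exist only
   for mutual-information estimation.
3. **Normalize** the selected columns linearly onto `[-1, 1]` using the
   training extrema; held-out values are scaled with the training ranges
   and clipped.
4. **Train** a sigmoid multilayer perceptron by per-instance stochastic
   gradient descent (squared error, one-hot targets) with learning rate
   0.3, momentum 0.2, and exactly 500 epochs — the study protocol
   defaults of `mlp_hyper()`.  Balanced accuracy is optimized through
   misclassification-cost instance weights: in a binary task a control
   (NES) instance is weighted by the number of epilepsy patients and an
   epilepsy instance by the number of NES patients, weights normalized to
   sum to the number of training instances, costs recomputed inside each
   training fold.  The trinary classifier is the one-against-one
   decomposition into three pairwise models (each class costed by the
   sum of the other two class sizes) combined by majority voting; a
   1-1-1 cycle is broken by the largest summed pairwise confidence and
   counted.
5. **Predict** the single held-out patient.  Cyclical leave-one-out
   cross-validation (CL1OCV) repeats 1–5 with every patient held out
   once; the feature ranking is always computed exclusive of the test
   patient.

Performance is summarized as accuracy, sensitivity, specificity,
balanced accuracy (mean of sensitivity and specificity; mean of
per-class recalls for the trinary task), the diagnostic odds ratio
(Haldane 0.5 correction when a cell is empty, flagged), exact
Clopper–Pearson intervals for every proportion, and — for the trinary
task — the lateralization accuracy among patients correctly identified
as epileptic.  The comparison baseline is the naive classifier, whose
accuracy is the largest class share.

# Choosing F and Q

`F` (features kept) and `Q` (quantal levels) must be fixed a priori, so
`accuracy_map()` evaluates a full CL1OCV at every point of an (F, Q)
grid and standardizes each cell against the naive baseline,

\[ z = \frac{\mathrm{BA} - p_0}{\sqrt{p_0 (1 - p_0) / n}}, \]

a binomial normal approximation at the evaluated sample size with
\(p_0\) the naive accuracy.  Because neighbouring grid cells share most
of their training data the z map is spatially smooth, and the search
over the grid is a multiple-comparison problem over a smooth random
field.  `select_operating_point()` therefore applies a random-field
-theory (RFT) correction:

* **Smoothness** is estimated from the map itself
  (`estimate_fwhm()`): the field is standardized and the variance `v`
  of its first differences along an axis estimates the derivative
  variance, giving `FWHM = sqrt(4 log 2 / v)` grid units, clipped below
  at one grid unit.  On unit-variance white noise `v = 2`, so the
  estimator's floor value is `sqrt(2 log 2) ≈ 1.18`; a constant field
  has no estimable roughness and is flagged infinitely smooth (the
  correction then collapses to a single effective test).
* **Threshold**: `rft_threshold()` solves
  \(E[\mathrm{EC}(u)] = R_0\rho_0(u) + R_1\rho_1(u) + R_2\rho_2(u) =
  \alpha\) with the standard 2-D Gaussian Euler-characteristic
  densities, resel counts \(R_2 = \text{area}/(f_F f_Q)\),
  \(R_1 = L_F/f_F + L_Q/f_Q\) (half-perimeter boundary terms),
  \(R_0 = 1\), by monotone root finding.  The corrected `u` never falls
  below the pointwise \(z_{1-\alpha}\).
* **Representative point**: among cells with `z > u` the cell nearest
  (Euclidean, in grid indices) to the mask centroid is chosen, ties to
  smaller `F` then smaller `Q` — a representative rather than extreme
  operating point, since the winner's-curse maximum would overstate
  performance.  An empty mask is reported as non-significant; callers
  may explicitly fall back to the pointwise maximum, with a warning.

# Likelihood-ratio fusion

For binary tasks the automated call can be combined with manual-analysis
(MA) reads of iPET and structural MRI.  For every subset of the streams,
each of the `2^k` positive/negative outcome patterns gets
`LR = (k_E / n_E) / (k_N / n_N)` — the probability of the pattern given
epilepsy over its probability given NES.  A pattern seen in no NES
patient has a flagged infinite LR; a pattern seen in nobody is flagged
undefined.  Patients missing a stream are excluded from that subset
only, so the evaluated `n` varies by subset and is reported.

Chance uncertainty is assessed with an exact-binomial construction
(`chance_lr_interval()`): conditioning on the `m` patients who actually
show the outcome, a prior-only classifier would yield
`k ~ Binomial(m, n_pos / (n_pos + n_neg))` true epileptics among them,
and the LR is encoded as the posterior odds `LR(k) = k / (m − k)`.  The
reported chance median and 95% interval are the exact binomial quantiles
of that induced distribution; `k = 0` or `k = m` gives a one-sided
unbounded bound reported as 0 or infinity.  With classes 39 and 32 and
`m = 35` the chance median is `19/16 ≈ 1.2`, the package's anchored
worked example; the encoding also converges to the prior odds
`n_pos/n_neg` as the outcome group grows.  The `k/(m−k)` encoding is a
deliberate design choice: among the natural constructions it is the one
that reproduces the worked-example median both at the binomial median
and in the prior-odds limit.  Other encodings are conceivable and the
chance-interval *bounds* should be read as construction-dependent.

# The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the pipeline assumes, so every
stage is testable end to end.  `default_table1_spec()` fixes the
generator at the reference study population: 32 NES / 39 LTLE / 34 RTLE;
female fractions (0.781, 0.538, 0.353); age means ± SD (37 ± 14,
38 ± 12, 36 ± 13) years truncated to 16–90; disease durations (12 ± 12,
22 ± 15, 20 ± 13) years and seizure frequencies (97.4, 36.5, 6.5
events/month, converted from per-day and per-week rates at 30.44 days
and 4.348 weeks per month) drawn log-normally matched to mean/SD —
log-normal because both quantities are positive and strongly
right-skewed (medians well below means); manual-read positivity
(iPET 0.188/0.769/0.879, sMRI 0.345/0.737/0.875) with report
unavailability matched to the study's missing counts.

ROI vectors are `baseline + class shift + noise` with baseline 1 (the
whole-brain-normalized scale), per-ROI Gaussian noise of SD 0.08, and an
exchangeable within-patient correlation of 0.3 (one shared patient-level
component) — the simplest noise structure that makes features mutually
redundant, which the mRMR redundancy term needs to be exercised at all.
Default class effects are hypometabolic shifts of −0.06 to −0.08
(0.75–1 noise SD) on the ipsilateral temporal ROIs and hippocampus, with
smaller (−0.02 to −0.04) distributed secondary shifts on connected
regions (midbrain, contralateral temporal structures, ipsilateral
frontal/language areas), mirroring the clinical picture of a focal
lesion with network-propagated effects.  Positive manual calls in
epilepsy classes lateralize to the true side with probability 0.9, the
remainder split between bilateral and contralateral calls; values are
floored at 0.05 to stay positive.  Generation is fully deterministic
given the spec seed.

What the generator does **not** emulate: scanner and reconstruction
effects, age- or atrophy-related metabolic gradients, heterogeneous
effect sizes across patients, non-Gaussian noise, and any dependence of
manual reads on the ROI values beyond the class label (reads are
conditionally independent given diagnosis).  Passing tests therefore
demonstrate that the *pipeline machinery* is correct and calibrated —
not that any particular accuracy level transfers to clinical data.

# Numerical and design choices

* **Histogram bins** are equal-width over the training range, right edge
  inclusive; held-out values clamp to the end bins.  A constant feature
  occupies level 0.  Mutual information is the plug-in estimator in
  bits with `0·log 0 = 0`; ranking comparisons are base-invariant.
* **mRMR ties** break to the earlier column; the ranking is invariant to
  positive affine rescaling of features (bins rescale with the range).
* **MLP details** the protocol leaves open are fixed as: logistic
  sigmoid everywhere; weight init uniform on [−0.5, 0.5] from a seeded
  Mersenne Twister; instances visited in a seed-shuffled order fixed
  across epochs.  The rule that training runs showing more than 20
  consecutive errors are excluded is implemented as a divergence guard:
  the longest run of consecutive training errors (in visiting order) of
  the trained model is measured, and a model exceeding the threshold is
  retrained from a derived seed, up to 5 retries, with counts reported.
* **Topology**: when `hidden_layout = NULL`, a single hidden layer is
  sized from {⌈(d + c)/2⌉, d, 2d} by 5-fold balanced accuracy inside
  the training data (ties to the smallest) — a bounded, reproducible
  stand-in for an unconstrained per-fold architecture search.  An
  explicit layout (possibly empty, i.e. no hidden layer) skips the
  search.
* **Seeds**: every fold, grid cell and pairwise model derives its seed
  from the master seed through a fixed integer recurrence, so runs are
  reproducible yet components independent.  Binary CL1OCV with a fixed
  topology runs each fold in compiled code; the compiled and plain-R
  fold paths share every numerical primitive and are asserted identical
  in the test suite.
* **Odds ratios** use the Haldane 0.5 correction only when a cell of the
  2×2 table is zero, and the result is flagged.  Whether the original
  analyses corrected zero cells is unknown; flagged values make the
  choice visible.
* **Cross-stream agreement** (`squared_correlation()`) is the squared
  Pearson correlation of per-patient calls, one-hot encoded and averaged
  over indicators for trinary calls, with a seeded nonparametric
  bootstrap (2000 resamples) for the interval — the original interval
  construction being unstated.

# Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run comfortably reproducible on a single CPU: cross-validation contracts
on cohorts of 20–36 patients; mutual-information and quantization
oracle checks on 1,000 random instances of up to 25 samples; planted
-effect recovery over 100 generator seeds at the reference class sizes;
cost-sensitivity over 50 seeds of a 90:10 two-Gaussian problem; and the
family-wise-error calibration of the (F, Q)/RFT procedure over 200
label-permuted null cohorts of 40 patients on a 5×5 grid.  The
calibration uses the no-hidden-layer network at 150 epochs: the
null-calibration property being tested is a property of the z-field
construction and RFT threshold, not of classifier capacity, and the
smallest network makes the 200-replicate null ensemble a few minutes of
compute.  Monte-Carlo acceptance bands are 3 binomial standard errors.

# Known limitations

* The RFT correction assumes an approximately Gaussian, stationary,
  smooth z-field; on coarse grids the discrete-difference smoothness
  estimator floors at `sqrt(2 log 2)` grid units and the correction is
  conservative rather than exact.
* Likelihood ratios are defined for binary outcomes only; the trinary
  task reports classification metrics instead.
* The chance-interval encoding is one documented choice among several
  (see above); its median is anchored, its bounds are not.
* Clinical covariates are modeled as independent within class; real
  covariate correlations (e.g. age with duration) are not emulated.
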