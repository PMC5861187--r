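---
title: "Methods: discovering and classifying psychometric-linked functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and classifying psychometric-linked functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`netpsych` implements a nine-stage analysis that links psychometric scores to
resting-state functional connectivity and then asks whether the linked
networks carry enough information to classify individuals:

1. **Morphometry (P1–P2).** At every voxel of each subject's gray-matter
   density map, the model `density ~ intercept + score + TBV` is fit; the
   score-slope t (df = n − 3, two-sided p) localizes score-linked anatomy.
   Multiple comparisons are corrected *within each atlas parcel* (small-volume
   correction): a voxel is significant iff its uncorrected p ≤ 0.001 **and**
   its |t| exceeds the (1 − 0.05) quantile of the permutation distribution of
   the within-parcel maximum |t| (scores permuted across subjects). One ROI —
   a 5-mm-diameter sphere — is placed at the peak-|t| voxel of each
   significant (parameter, parcel) mask; overlapping spheres are removed in a
   single forward pass keeping the first ROI in parameter-list order.
2. **Connectivity (P3–P4).** Per subject: nuisance regression on an
   intercept plus a 24-column motion model, zero-phase Butterworth bandpass
   to 0.01–0.1 Hz, then the R × R Pearson correlation matrix over ROI
   signals. The stage order is fixed and asserted by `build_connectivity()`.
3. **Network inference (P5–P7).** For each psychometric parameter, every
   edge (upper-triangle pair of ROIs) is regressed on the score
   (t with df = n − 2); edges with two-sided p < 0.005 form a graph whose
   connected components are candidate networks. Familywise error is
   controlled with the network-based statistic: the score vector is permuted
   (5000 times by default), the maximum supra-threshold component edge count
   is recorded each time, and a component's corrected p is
   `(1 + #[perm max ≥ observed]) / (n_perm + 1)`. A bisection over the
   primary threshold then brings the largest significant component as close
   as possible to 15 edges; components already at or below 15 edges at
   p = 0.005 are kept unchanged.
4. **Classification (P8–P9).** Scores are discretized into 8 equal-width
   classes by `clamp(ceil(8·(x − min)/(max − min)), 1, 8)`; the network's
   edge correlations are the feature matrix; one RBF-kernel binary SVM per
   class (one-against-all), prediction by maximal decision value, and C/γ
   chosen by grid search over dyadic grids (C = 2⁻⁵…2¹⁵, γ = 2⁻¹⁵…2¹⁵) to
   maximize leave-one-out accuracy. Accuracy is compared with the
   theoretical chance level (100/8 = 12.5%) and the binomial-corrected
   chance level for the sample size.

A synthetic-data module generates every input with known planted effects so
each stage can be validated against a recoverable ground truth.

## The synthetic generator: what it emulates and what it does not

`generate_scores()` draws each parameter from a Gaussian truncated to the
0–130 questionnaire scale, using per-parameter means and SDs of the kind
published in battery summary tables; missingness is block-structured (a
subject is missing a whole battery or none of it), emulating cohorts where
some instruments were administered on separate days. Parameters are
independent unless a correlation structure is injected by the caller — real
battery scores are correlated, so multivariate effects across parameters are
*not* emulated.

`generate_gm_maps()` emits already-smoothed, normalized density maps: a
constant baseline, a linear score effect `β_vbm·(score − mean)` at each
planted focus voxel (the center voxel of its parcel), and Gaussian-smoothed
noise (8-mm FWHM by default, applied to the noise field; `noise_sd` is the
pre-smoothing SD). Tissue segmentation, registration and modulation are out
of scope — the generator stands in for their *output*. TBV is the map sum
times the voxel volume.

`generate_timeseries()` samples each subject's T × R series from a
multivariate normal whose population correlation is `r0` everywhere except
planted edges, where it is `clip(r0 + β_edge·z(score), −0.95, 0.95)`;
indefinite matrices are projected to the nearest positive-definite matrix by
eigenvalue clipping at 1e-6. The 24-column nuisance matrix has the standard
motion-model layout (6 AR(1) series, their one-sample lags, and the squares
of both); by default it does not contaminate the series, so the stated
correlation contract holds exactly — callers can set `confound_loading > 0`
to inject leakage. Hemodynamics, physiological noise spectra and scanner
drift are not modeled, so passing tests demonstrate statistical correctness
of the pipeline, not robustness to those artifacts.

**Effect-size calibration.** Bandpass filtering to 0.01–0.1 Hz retains only
2·(0.1 − 0.01)·TR = 18% of the sampling bandwidth, so a per-subject
correlation estimated from T = 480 samples behaves as if estimated from
~86 independent samples (SD ≈ 0.11, not 1/√480 ≈ 0.046).
`edge_effect_for_r()` therefore computes the β that yields a desired
edge-score correlation *after* filtering:
`β = σ_eff · r_target / sqrt(1 − r_target²)` with
`σ_eff = (1 − r0²)/sqrt(T_eff − 3)`. For a target |r| of 0.4 this gives
β ≈ 0.048 per standard score unit.

## Numerical and design choices

* **Bandpass implementation.** The filter is the squared magnitude response
  of a 4th-order Butterworth bandpass — exactly the frequency response of a
  forward–backward (zero-phase) pass — applied in the frequency domain on a
  mirror-extended series. The mirror extension removes the wrap-around
  discontinuity and its spectral leakage; the FFT form is ~50× faster than
  per-column time-domain filtering, which matters because the permutation
  suites filter hundreds of synthetic cohorts. Measured on T = 480 at
  TR = 1 s: amplitude ratio 0.997 at 0.05 Hz, 0.083 at 0.005 Hz, 0.039 at
  0.2 Hz.
* **Small-volume FWE by permutation.** Parametric voxel-level corrections
  based on random-field theory assume smooth Gaussian fields; this package
  uses the within-parcel permutation max-|t| distribution instead
  (default 1000 permutations), which is distribution-free and valid under
  subject exchangeability. The two corrections are not numerically
  identical; the permutation form is the package's contract.
* **Threshold conjunction.** The voxel criterion is the *conjunction* of the
  uncorrected threshold (p ≤ 0.001) and the parcel-level FWE threshold;
  `alpha_unc = 1, alpha_fwe = 1` disables both (every parcel voxel passes),
  which the tests use as a degenerate check.
* **Peak ties** are broken by the smallest linear voxel index (x-fastest
  scan order): deterministic and stable under relabeling.
* **Overlap rule.** Two sphere ROIs "overlap" when the distance between
  centers is strictly less than the sum of their radii; spheres that exactly
  touch are both kept. Dedup is a single forward pass (first ROI in
  parameter-list order wins) and is idempotent.
* **Sign handling.** All tests are two-sided; positively and negatively
  score-linked edges are thresholded jointly on |t| and may share a network.
* **Component statistic.** Component size is the *edge count* (extent), not
  an intensity sum; the permutation null records the maximum component edge
  count per permutation, and corrected p-values use the add-one convention,
  so the smallest attainable p is 1/(n_perm + 1).
* **Permutation scheme.** Scores are permuted across subjects, which breaks
  the subject link exactly as shuffling the correlation matrices would, at a
  fraction of the cost. Subjects missing the score are dropped first, so the
  null is conditional on the observed subset. Edge columns and the score are
  centered and scaled to unit norm once; each permutation's full edge-wise
  correlation vector is then a single cross-product, and |r| thresholds are
  the exact images of the |t| thresholds
  (`r_crit = t_crit/sqrt(df + t_crit²)`).
* **Edge-count targeting** bisects the primary threshold geometrically
  (component sizes move on log-p scale), re-using one permutation stream for
  every candidate threshold so significance judgments are comparable across
  the search; ties in distance to the target resolve toward the smaller
  threshold.
* **Discretization edge cases.** `ceil` maps x = min to 0, an invalid
  class, which is clamped to 1; products that land exactly on an integer
  keep that value (there is no fractional digit to round up). A small
  rounding guard (9 decimal digits) prevents floating-point noise from
  pushing an exact product into the next class. The min/max are stored with
  the model and reused verbatim on new cohorts; out-of-range new scores are
  clamped with a warning.
* **Chance levels.** The corrected chance level uses the binomial
  inverse-CDF convention: the smallest k with `P(X ≤ k) ≥ 1 − α` for
  X ~ Binomial(n, 1/8), reported as 100·k/n. At n = 150, α = 0.05 this is
  k = 26, i.e. 17.33% ("about 17%"); at n = 57 it is 19.3%. It is the
  accuracy a random guesser exceeds with probability < α — note it corrects
  for sample size only, *not* for class imbalance (see Limitations).
* **Significance vs chance.** A single LOOCV accuracy is one number, so a
  one-sample t-test on it is ill-posed; the primary test is the exact
  binomial tail of the correct-prediction count against p₀ = 1/8. A
  one-sample t-test across *networks* (vector of accuracies) is provided as
  the secondary, group-level method.
* **OAA details.** One binary RBF SVM per observed class (LIBSVM via
  `e1071`, the same underlying library as the original MATLAB toolchain);
  decision-value orientation is calibrated on the training rows; prediction
  is the argmax of decision values with ties to the lowest class index.
  Classes absent from a training fold simply have no classifier, and
  predictions are restricted to observed classes. Features are standardized
  per column with training-set statistics (re-estimated inside every LOOCV
  fold; stored with the model for test-time reuse) because the dyadic γ
  grid assumes comparable feature scales.
* **Grid-search scheme.** By default the hyperparameters maximize the same
  LOOCV loop that is afterwards reported (`scheme = "flat"` — the historical
  design this package reproduces). That estimate carries hyperparameter
  selection bias; `scheme = "nested"` re-runs the grid search inside every
  outer fold and is selection-free but roughly n times slower. Ties in grid
  accuracy resolve toward smaller C, then smaller γ (the grid is scanned in
  ascending order and only strict improvements replace the incumbent), so
  the search is deterministic.
* **Seeds.** One global seed expands into per-stage child seeds through a
  fixed hash of the stage name (`derive_seed`), all below 2³¹, so any stage
  can be re-run in isolation and reproduce its stream.

## Study conditions used by the validation suites

The acceptance-style suites run at the cohort sizes of the design they
emulate — 150 training and 57 held-out subjects, 480 time points at
TR = 1 s — with Monte-Carlo dimensions chosen so the whole suite stays
desk-scale: 200 null replicates at R = 30 and 1000 permutations for the NBS
calibration; 50 seeds for planted-network recovery (10-edge component,
per-edge |r| ≈ 0.4); 20 seeds for the end-to-end signal check and 20 null
replicates for the end-to-end false-positive check, on a 12³ voxel grid
(3 mm voxels, 27 parcels, 16 candidate ROIs) with 200 permutations for the
small-volume correction and a 2 × 2 C/γ grid (C ∈ {1, 32},
γ ∈ {1/16, 1/2}). The full dyadic grids and 5000 permutations remain the
package defaults for real analyses; the scaled conditions are fixed
properties of the validation design, not tuned quantities.

## Known limitations

* **Class imbalance inflates "above chance".** Equal-width discretization
  of roughly Gaussian scores concentrates subjects in middle classes, so a
  majority-class predictor already beats 12.5%. The binomial-corrected
  chance level does not correct for this; a classifier can clear it without
  using the features. In this pipeline the NBS gate keeps null data from
  reaching the classifier at more than the α rate (the end-to-end null
  suite verifies this), but accuracies of *gated* classifiers should still
  be read against the empirical class priors, which the confusion matrix in
  every `classifier_report` makes visible.
* **Flat grid search** (the default, above) optimistically biases the
  reported LOOCV accuracy; use `scheme = "nested"` when an unbiased single
  estimate matters more than fidelity to the historical design.
* **NBS conservatism at small edge counts.** Correlation-valued features
  are bounded, hence slightly platykurtic, so the t-based primary threshold
  admits marginally fewer edges than its nominal rate; together with the
  discreteness of the extent statistic (a null component can only grow one
  whole edge at a time) this makes the permutation test conservative — the
  realized familywise error rate at R = 30 and p < 0.005 sits at or
  somewhat below the nominal 5%, never above it. The effect shrinks as the
  graph (and with it the supra-threshold edge count) grows.
* The corrected chance level is a step function of n and is only
  *approximately* non-increasing; tests check monotonicity across
  sample-size doublings.
* The synthetic generator treats parameters as independent and time series
  as stationary Gaussian; real batteries and BOLD data are neither.
* `nbs_fwe()` holds an n_perm × n-subject permutation matrix and processes
  the permutation × edge correlation product in chunks of 500 permutations;
  at atlas scale (R in the hundreds) memory stays modest, but runtime grows
  linearly in edges × permutations.
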