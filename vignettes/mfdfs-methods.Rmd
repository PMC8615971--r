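---
title: "Methods: manifold feature fusion and dynamical feature selection for cross-subject EEG emotion recognition"
author: "mfdfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: manifold feature fusion and dynamical feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG-based emotion recognizers are usually validated leave-one-subject-out
(LOSO): train on all subjects but one, test on the held-out individual.
Because cortical responses to identical affective stimuli differ across
people, the held-out subject's feature distribution is shifted relative to
the training pool — a domain-adaptation problem in which the target domain
has no labels. The MF-DFS pipeline attacks it in three stages: supervised
feature weighting (NCA), unsupervised manifold alignment (GFK), and a
per-subject wrapper selection (DFS). This vignette documents the models,
the tunable parameters, the numerical choices, and what the bundled
synthetic benchmark can and cannot show.

## Preprocessing and labels

Ratings on the 1–9 affective scale are trichotomized: above 5.5 is *high*,
below 3.5 is *low*, the closed interval [3.5, 5.5] is *neutral*. The outer
classes are defined by strict inequalities, so boundary ratings of exactly
3.5 or 5.5 fall in the neutral class — the only reading that partitions the
scale consistently.

Database-style profiles bundle the conventional filter chains (5th-order
4–45 Hz Butterworth bandpass for DEAP-shaped data; common-average
re-referencing plus a 7th-order 3 Hz highpass for MAHNOB-HCI-shaped data,
with trials cropped to seconds [5, 65); a 3 Hz highpass followed by a
45 Hz lowpass for SEED-shaped data). One published summary table lists the
bandpass as common to all three; the per-database prose convention is
followed here, and `preprocessProfile("custom")` lets users pick either.
All filtering is zero-phase (forward–backward): group delay would shift
features computed from short segments, at the documented cost of doubling
the effective filter order. Downsampling is an explicit anti-alias lowpass
(8th order at 80% of the target Nyquist) followed by integer decimation,
applied after the profile's filters. Trials are cut into four
non-overlapping equal segments; a non-divisible remainder is truncated from
the end, preserving equality and non-overlap.

## Feature sets

The classical (CL) set has a fixed 364-column layout for the 32-channel
montage: 160 time-domain values (variance, zero-crossing rate, 16-bin
histogram Shannon entropy, kurtosis, skewness — per channel), 128 average
band powers (theta 4–8, alpha 9–12, beta 13–30, gamma 31–45 Hz) from the
one-sided rectangular-window periodogram, 56 right-minus-left hemispheric
band-power differences over 14 electrode pairs (asymmetry bands theta 4–8,
alpha 8–14, beta 14–31, gamma 31–45 Hz), and 20 power ratios. Design
choices worth spelling out:

* **"Variation"** is implemented as the per-channel sample variance, the
  standard scale-sensitive reading.
* **Entropy binning** uses 16 equal-width bins over each channel's own
  min–max range; a fixed bin count keeps the feature comparable across
  segments. Constant channels get entropy, kurtosis and skewness of 0.
* **Kurtosis** is the raw fourth standardized moment (Gaussian reference
  value 3), not excess kurtosis.
* **Two band schemes coexist** exactly as defined for the two feature
  families — band power/entropy use the 9–12 Hz alpha convention, the
  hemispheric differences the 8–14 Hz one. They are carried side by side in
  `bandScheme()` rather than unified; which edges the differences use is
  configurable.
* **The 20 ratios** expand as: four within-band ratios
  (`Fz/(AF3+AF4)`, `Cz/Fz`, `Pz/Cz`, `Oz/Pz`) in each of the four bands
  (16), plus four theta/alpha cross-band ratios (`AFz(θ)/Pz(α)`,
  `AFz(θ)/Cz(α)`, `Cz(θ)/Pz(α)`, `Cz(θ)/Oz(α)`). `AFz` is not in the
  32-channel montage, so its power is the mean of AF3 and AF4. Zero
  denominators yield 0 with a warning.
* **Periodogram without Welch averaging**, rectangular window, inclusive
  band-edge bin membership: the simplest estimator consistent with "FFT
  band power", locked down by tests rather than left implicit.

The differential-entropy (DE) set filters each channel to each band
(5th-order zero-phase Butterworth) and returns `h = ½ ln(2πe σ̂²)` nats —
the entropy of a Gaussian with the band-limited sample variance, an
assumption that holds well for band-filtered EEG. Variances below 1e-12
are clamped there.

## NCA feature weighting

With standardized features (z-scored by training-fold statistics — the L1
base metric is scale-sensitive, so unstandardized inputs would let
high-variance features dominate), the weighted distance is
`D_w(i,j) = Σ_r w_r² |x_ir − x_jr|`. A stochastic 1-NN rule picks reference
points with probability `p_ij ∝ k(D_w)`, `k(z) = exp(−z/σ)`; `p_i` is the
probability of a same-class reference, and the objective
`F(w) = mean(p_i) − λ Σ w_r²` is maximized by batch gradient ascent with a
backtracking (Armijo) line search from `w = 1`, tolerance 1e-6 on the
objective improvement, at most 100 accepted steps. The kernel width is
fixed at σ = 1. Softmax rows are stabilized by subtracting each row's
off-diagonal distance minimum before exponentiation; the normalization is
shift-invariant, so no overflow path can error. The analytic gradient is
verified against central finite differences in the test suite and the
acceptance script.

`λ` is selected by subject-wise LOSO: for each grid value the model is
fitted on all-but-one subject and the held-out subject's labels predicted
with the expected-class rule `ŷ = Σ_c c·P(c|x)`; the loss is the MSE
against integer-coded classes, the coding chosen to make "mean squared
error" well-defined for a 3-class target. The default grid is 20 points
geometrically spaced in [1e-4, 1], wide enough to bracket optima in the
1e-3 range with margin; ties go to the smaller λ. The subject-wise fold
structure is used rather than a fixed 15-fold split: with per-subject
subsets the two descriptions coincide only when there are 15 subjects, and
the subject-wise reading is the one that measures cross-subject loss.

Selection keeps features with `w_r > 0.02 · max(w)`, clipped into
[minK, maxK] by top weight (defaults 27–38, the range the selected count
typically occupies on full-size feature sets; scaled-down benchmarks pass
explicit bounds). If every weight is zero the first `minK` columns are
kept with a warning — the gradient at the origin vanishes identically
(every component is proportional to `w_r`), so no gradient-based ordering
exists there.

## GFK manifold fusion

Source (pooled training subjects) and target (held-out subject) matrices
are each centered by their own means and reduced to d-dimensional PCA bases
`P_S`, `P_T`; the pooled data, centered by the pooled mean, gives
`P_{S+T}`. The subspace disagreement measure
`D(d) = ½(sin α_d + sin β_d)` uses the d-th principal angles of each
domain's basis against the pooled basis; `d*` is the smallest d with
`D(d) ≥ 1 − ε`, ε = 1e-3, since exact equality with 1 is numerically
unattainable. If no d qualifies, the curve's maximizer is taken, ties to
the larger d (a larger subspace keeps more of the fused features). The
candidate range is capped at `floor(D/2)` so the orthogonal complement
`R_S` can carry the flow, and at `n − 1` per domain for PCA validity.

With `P_Sᵀ P_T = U₁ Γ Vᵀ` and `R_Sᵀ P_T = −U₂ Σ Vᵀ` (Γ, Σ diagonal with
cos θᵢ, sin θᵢ of the principal angles), the geodesic is
`Φ(t) = P_S U₁ diag(cos tθ) − R_S U₂ diag(sin tθ)`. The sign convention is
arbitrated by the pole conditions — the projectors of `Φ(0)` and `Φ(1)`
must equal those of `P_S` and `P_T` — which the tests assert. The kernel
`G = ∫₀¹ Φ(t)Φ(t)ᵀ dt` is assembled from `Ω = [P_S U₁, R_S U₂]` and three
diagonal blocks derived analytically from the integral:

* `Λ₁ = ½ + sin(2θ)/(4θ)`
* `Λ₂ = (cos(2θ) − 1)/(4θ)`
* `Λ₃ = ½ − sin(2θ)/(4θ)`

For θ < 1e-6 second-order Taylor limits are used (`Λ₁ → 1 − θ²/3`,
`Λ₂ → −θ/2`, `Λ₃ → θ²/3`), and the columns of `U₂` belonging to
near-zero angles are irrelevant (their kernel weights vanish), so they are
set to zero rather than completed arbitrarily. These closed-form entries
are locked in by a quadrature oracle: on random domain pairs the kernel
must match a 2000-point trapezoid integration of `Φ(t)Φ(t)ᵀ` entrywise to
1e-6. Singular values are clamped into [0, 1] before `acos`. Both domains'
instances are mapped identically through `x ↦ Gx`.

## Dynamical feature selection

Recursive feature elimination on the transformed training data: fit the
classifier, compute non-negative importance weights (impurity decrease for
tree ensembles, vote-weighted member importance for AdaBoost, coefficient
L2 norms across classes for the multinomial-logit ranker), remove the
lowest-weight feature, refit. Ties remove the larger column index first —
deterministic and stable under column reordering. Elimination is strictly
one feature at a time; with n features that is n − 1 importance
evaluations. The ranker is the same classifier specification as the final
evaluator by default; a linear-margin ranker (`"multinom"`) can be forced.

The accuracy at each ranked prefix size is computed by *nested LOSO over
the training subjects only*. The alternative — scoring prefixes on the
held-out subject — would leak test labels into feature selection and
invalidate the LOSO protocol, so the nested reading is the only defensible
one; the held-out subject's labels are read exactly once per fold, at final
scoring, and a test asserts that access count. `k*` is the smallest prefix
attaining the maximal internal accuracy. NCA (and λ, when selected rather
than fixed) is refitted inside every fold for the same reason. Setting
`useGfk = FALSE` replaces the kernel with the identity, giving the
NCA + RFE ablation path.

## Evaluation harness

One fold per subject; accuracy is segment-level (each segment is one
instance, matching how instances are constructed), with trial-level
aggregation left to the user. Classifier hyper-parameters are frozen
across all experiments: RF 50 trees; AdaBoost 50 members of depth 24
(SAMME over rpart trees, written here because the stack ships no
multiclass AdaBoost); GBDT and XGBoost as gradient-boosted trees with 50
rounds at depths 16 and 22; decision tree of depth 10 with a 12-sample
leaf minimum (and a 24-sample split minimum — the split threshold must be
set explicitly, otherwise rpart trebles it). Paired two-sided t-tests with
df = subjects − 1 compare pipelines on the same folds; the p-value matrix
is emitted raw, with a Holm-corrected column added in the long-format file
for users who want family-wise control. Reported standard deviations are
across subjects. Per-fold classifier seeds are derived from the global
seed with a counter scheme, and random-forest prediction is seeded too
(tied votes would otherwise consume the session RNG), making a seeded run
bit-reproducible.

## The synthetic generator, and what the tests show

Each trial is a sum of four band-limited oscillations (one sinusoid per
band, center frequency jittered by up to 1 Hz per trial, random phase per
channel) plus white noise and a per-subject DC offset. Narrow-band
sinusoids are used precisely so the band-power integrators can detect the
planted structure. Class structure enters through per-band amplitude
multipliers (defaults lower alpha and raise beta/gamma for the high class,
the canonical direction of affective band-power modulation); the
cross-subject gap through a per-subject log-normal gain and per-band
scaling with spread `subjectShiftSd` (default 0.3). Labels are balanced by
construction (up to a remainder when trials are not a multiple of 3), so
chance is 1/3. Baseline amplitudes (theta 6, alpha 10, beta 5, gamma 3 µV,
noise 2 µV) are ordinary resting-EEG magnitudes. A counter-based sub-seed
per (subject, trial) makes every trial independently reproducible.

The generator does **not** emulate 1/f background spectra, ocular/muscular
artifacts, volume conduction, channel covariance structure, or
non-stationarity within trials. Passing tests therefore demonstrate that
the pipeline's machinery is correct and that it recovers planted,
cross-subject-stable structure under realistic shift magnitudes — not that
any particular accuracy level transfers to real recordings, which are
access-restricted and out of scope here.

Benchmark problem sizes, chosen once: the planted-signal suite uses 5
informative + 25 noise features, 8 subjects × 15 instances, subject shift
0.3, 20 simulation seeds, with the decision-tree ranker, a fixed λ = 0.01
and selection bounds 5–15 (a meaningful window for a 30-feature problem;
the 27–38 default targets full-size sets). Structural checks (feature
counts, segment counts for the 32×40, 24×20 and 15×45 trial layouts) use
1-s trials — the counts depend only on the layout.

## Known limitations

* The recursive elimination is O(n²) classifier fits per fold plus O(n·K)
  fits for the accuracy curve; on the full 364-feature set with slow
  learners this is expensive by design (one-at-a-time elimination is the
  specified procedure). Reduce cost via the NCA selection bounds or a
  cheaper ranker.
* The NCA objective is non-concave; gradient ascent from `w = 1` finds a
  local optimum. The ascent property (non-decreasing trace) is asserted,
  global optimality is not.
* `G` is applied as a fixed linear map; no label information from the
  target subject is ever used, which also means the adaptation cannot
  correct purely label-conditional shifts.
* Filter-based selector baselines (chi-squared, mutual information, ridge,
  extremely-randomized forests) are not implemented; the classifier
  harness is the extension point for plugging them in.
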