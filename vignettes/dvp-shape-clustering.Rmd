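---
title: "Clustering digital volume pulse shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering digital volume pulse shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvpclust)
```

## The problem

A digital volume pulse (DVP) is the single-beat segment of a
photoplethysmogram (PPG). Its shape carries vascular information: young,
compliant arteries produce a sharp systolic peak, a clearly marked dicrotic
notch and a distinct diastolic wave, while arterial stiffening flattens the
notch until the pulse becomes a single broad wave. The classic taxonomy
grades this into four notch-based morphology classes. Real recordings,
however, vary continuously, and hand-labelling beats with one of four
classes is unreliable. `dvpclust` approaches the question without labels: it
clusters beats by shape under three different representations, asks how many
shape clusters the data support, and scores whether the resulting clusters
differ in clinical covariates.

The package implements the full pipeline:

1. a synthetic-data generator that plants the four morphology classes with
   age-coupled clinical covariates, making every downstream stage testable;
2. preprocessing — resampling each beat to 100 samples, amplitude scaling to
   [0, 1], z-scoring, and a 70/30 train/test split with 30% of the training
   pool held out for validation;
3. three shape representations: fourteen handcrafted morphology features,
   pairwise derivative dynamic time warping (DDTW) dissimilarities, and the
   8-dimensional latent space of a 1-D convolutional autoencoder;
4. K-medoids (PAM) clustering in three modes — free medoids at k = 4
   ("baseline"), medoids fixed to the four canonical class shapes
   ("template"), and a cluster count selected from silhouette, inertia and
   prediction strength curves over k = 1..15 ("optimal");
5. cluster/covariate association: per-cluster normalized means,
   Kruskal–Wallis screening with Welch post-hoc tests, and a size-weighted
   quantile-function distance `d` that scores how differently a covariate is
   distributed across clusters.

## The synthetic generator

Each class template is a sum of three Gaussians on normalized time
t ∈ [0, 1] — systolic, reflected and diastolic wave — minus a narrow
Gaussian dip for the dicrotic notch, placed midway between the reflected and
diastolic centers. The four parameter sets grade notch depth
(0.24/0.16/0.10/0), diastolic amplitude (0.50/0.35/0.24/0), reflected
amplitude and systolic width from class 1 (marked notch) to class 4 (single
broad wave, no notch, no diastolic peak).

Vascular age modulates each template: over the 19–83-year span the
diastolic amplitude and notch depth shrink by 8%, the reflected amplitude by
5%, and the systolic width grows by 2.5%. These coefficients are
deliberately small relative to the between-class parameter gaps: the
generator's contract is that a beat's *class*, not its age, dominates its
shape, so that every noise-free beat is nearest (by DDTW) to its own class
template at every age and clustering-recovery tests are well posed. The
template parameters were additionally balanced so the four classes are
roughly equidistant in DDTW space (adjacent-class distances ≈ 1.5);
without that, the graded notch continuum collapses into two superclusters
and no criterion can prefer k = 4.

Waveform noise is additive, Gaussian and *band-limited* (white noise
convolved with a Gaussian kernel of ~2-sample correlation length), default
sd 0.004 in raw amplitude units (~0.4% of the systolic amplitude). Two
reasons: quality-screened beats carry smooth residual artifacts (baseline
drift, vasomotion) rather than per-sample sensor noise, and white
per-sample noise is pathological for any derivative-domain distance. Raw
beat lengths are drawn uniformly from 60–140 samples purely to exercise the
resampling path.

Covariates are drawn per subject: vascular age from a clipped normal
(mean 44.31, sd 14.34, clipped to [19.48, 83]); the reported age adds
1 year of noise. Pulse wave velocity (PWV) increases affinely in age
(correlation ≈ 0.7, mean 7.99, sd 2.91, clipped to [3.70, 26.10], with a
0.13 m/s offset compensating the clipping bias); systolic and diastolic
pressure couple to age at correlation ≈ 0.5; BMI, heart rate, height and
weight are independent clipped normals at their population moments. Transit
time is TT = 1000 / PWV ms (a 1-m finger-to-toe path) with 5%
multiplicative noise — stiffer arteries, shorter transit. Class membership
is drawn from the prior mixture tilted by a softmax in standardized age
(slope 0.6 per class step), so older subjects favour the notch-free
classes; a zero prior stays impossible. The strength of this coupling is a
free modelling choice exposed in `synthetic_config()` — no quantitative
prevalence-by-age data exists to calibrate it.

What the generator does *not* emulate: continuous multi-beat recordings,
beat segmentation, motion artifacts, sensor wavelengths, or any within-
subject beat-to-beat morphology drift beyond noise. Tests passing on this
synthetic population therefore demonstrate correctness of the pipeline's
machinery and its ability to recover planted structure — not that four
clusters (or any particular k) describe real populations.

## Preprocessing

`normalize_pulse()` resamples by linear interpolation onto 100 equally
spaced points over the beat duration, then min-max scales to [0, 1], in that
order. Linear interpolation is the simplest shape-preserving interpolant at
this grid density; the operation is idempotent. Constant or non-finite beats
are rejected rather than silently propagated. `znormalize_pulse()` uses the
population (divisor-n) standard deviation, so a two-point pulse maps to
exactly (−1, 1). Splitting is *pulse-level*, not subject-level: one subject
can contribute to train, validation and test simultaneously. This is
leakage-prone by design — it mirrors the protocol the pipeline reproduces —
and the split function documents it rather than hiding it.

## Handcrafted features

Fiducial detection on the 100-sample grid: systolic peak = global maximum;
onset = amplitude minimum at or before it; maximum downslope = most negative
first difference after the peak; dicrotic notch = first strict local minimum
of the pulse after the maximum downslope, falling back to a second
deceleration episode (the most negative local minimum of the first
derivative strictly after the maximum-downslope point); diastolic peak =
first local maximum after the notch. Absence is encoded as `NA`, never an
error: notch-free class-4 shapes are legitimate inputs.

The 14 features (fixed order): `DDR` (notch/diastolic amplitude ratio,
sentinel 1.1 when no diastolic point exists), `RDS` (area from maximum
downslope to beat end), `DDM` (mean post-systolic first derivative), `Skew`
and `log_Kurt` (moments of the amplitude distribution; kurtosis enters as
excess + 3, always positive, before the log), the amplitude and index of the
first local minimum and of the maximum of the second derivative
(`P_b_2Dev_*`, `P_a_2Dev_*`), `S_P_Onde` (total area), `nbr_peaks` (local
maxima with topographic prominence ≥ 0.02 in normalized amplitude — the
threshold is a package choice), `log_RT` (log rise time in samples, floored
at one sample), `AI_bin` (1 when an augmentation-index inflection — a local
maximum of the first derivative between systolic peak and notch — is
detectable), and `log_DDV` (log variance of the downslope derivative,
floored at 1e−8). Areas use the trapezoid rule on the unit time grid.
Skewness and kurtosis treat the 100 samples as a distribution of amplitudes;
a time-weighted alternative was considered and rejected as an unnecessary
complication. Standardization (`fit_transform_features()`) estimates
per-column mean and sd on the training partition only.

## Derivative dynamic time warping

The DTW kernel is the textbook O(nm) dynamic program with cell cost
|s[i] − t[j]|, the three standard moves, no step weights and no path-length
normalization — the raw cumulative cost is returned. A Sakoe–Chiba band
restricts alignment to |i − j| ≤ w; the default half-width is w = 20 samples
on the 100-sample grid. DDTW z-normalizes each pulse (removing affine
amplitude maps exactly), then differentiates with the slope estimator
d[i] = ((x[i] − x[i−1]) + (x[i+1] − x[i−1])/2) / 2 (endpoints copy their
neighbours), then runs banded DTW on the slope series. The order — z-score
first, differentiate second — is fixed and documented; the derivative
estimator is pluggable in principle but this is the standard form. The
dynamic program is compiled (Rcpp); the 79,800-pair matrix for 400 pulses
takes a few seconds on one core. DTW is not a metric: symmetry holds (and
is tested), the triangle inequality is not asserted.

## The convolutional autoencoder

The encoder maps 100 samples through three conv(32 channels, kernel 3, same
padding, ReLU) + halving max-pool stages (100 → 50 → 25 → 13, ceiling mode)
to a flatten width of 416 and a *linear* dense bottleneck of 8 units; the
decoder mirrors back through dense 8 → 416, reshape to (13, 32), a stride-2
transposed convolution to length 26, cropping to 25, two upsample/conv
stages to 100, a flatten to 3200 and a sigmoid dense reconstruction of 100
samples. ReLU is used inside the convolutional layers only; the bottleneck
stays linear (a ReLU there risks dead units at width 8), and the
reconstruction layer is sigmoid to match the [0, 1] pulse range.

The implementation is the package's own, on base-R matrix algebra: im2col
convolutions, pooling/upsampling with explicit masks, Adam, minibatches of
32, mean-squared reconstruction error plus an L2 weight penalty
(λ = 1e−4), early stopping on validation MSE with patience 10 and
best-weights restoration, capped at 200 epochs, learning rate 1e−3. All of
these are fixed defaults in `ae_config()` rather than searched
hyperparameters: the search procedure used to pick the bottleneck size is
tooling, not method, and 8 latent units is taken as given. Every backward
pass is pinned by finite-difference gradient checks in the test suite, and
training is a pure function of `(config seed, data)`. On 1,000 noise-free
synthetic pulses the validation MSE reaches ~1e−4 within ~25 epochs
(~40 s on one core).

## K-medoids and model selection

`kmedoids_fit()` is PAM: greedy BUILD initialization followed by
best-improvement SWAP until no single medoid exchange lowers the total
dissimilarity. Ties break to the lowest index, making the optimizer
deterministic given input order; the objective after BUILD and after each
accepted swap is stored (`objective_trace`) and is non-increasing by
construction — an invariant the tests assert. Feature-space inputs use
Euclidean distances (not squared: the objective is a sum of
dissimilarities). Template mode (`assign_fixed_medoids()`) holds the four
canonical class shapes fixed as medoids and performs one nearest-template
assignment pass; with medoids immutable there is no update step to iterate.
Inertia is reported by default as the *mean* squared distance to the
assigned medoid, which is comparable across differently scaled
representation spaces; the raw sum is available.

`scan_k()` fits k = 1..15, warm-starting each fit from the previous k's
medoids (faster, and keeps the inertia curve monotone, which a cold restart
cannot guarantee for a local optimizer). Silhouette follows
s = (b − a)/max(a, b) with a excluding the sample itself; members of
singleton clusters score 0. Prediction strength fits PAM independently on a
50/50 split, assigns the held-out half to the nearest *train* medoid, and
takes the minimum over held-out clusters of the fraction of ordered
co-assigned pairs; singleton clusters contribute 1 (the normalizer
n(n−1) is undefined below n = 2) and ps(1) = 1. Prediction strength for a
precomputed dissimilarity is implemented but off by default in the pipeline
for the DDTW representation, where its cost is disproportionate; a flag
opts in. `choose_k()` keeps the k whose prediction strength clears 0.7
(0.8 proved too restrictive in practice; k with no ps available always
qualify), maximizes the silhouette among them, and breaks ties toward the
inertia elbow (maximum perpendicular distance to the endpoint chord),
falling back to the silhouette argmax with a warning when nothing clears
the threshold. The chosen k is a recommendation; the curves are the primary
output.

## Clinical relevance

`kruskal_then_welch()` screens each covariate with a Kruskal–Wallis test
across clusters and, only where that null is rejected, runs all pairwise
Welch t tests with Holm adjustment (the adjustment choice is the package's;
any standard correction would do). `quantile_distance()` evaluates both
empirical quantile functions on the midpoint grid (q − 0.5)/Q, Q = 100, by
linear interpolation of order statistics, and averages the absolute gaps —
equal to the 1-Wasserstein distance between the empirical distributions; an
RMS variant is available and both coincide on the worked point-mass
example. Location shifts are deliberately *not* removed: a shift by c
yields distance exactly |c|, which is the behaviour wanted here (clusters
that shift a covariate's distribution should score as different).
`csm_weighted_distance()` averages the pairwise distances with cluster-size
weights w = n_cluster/N and the 1/(k(k−1)) ordered-pair normalizer:
d = 1/(k(k−1)) Σ_i w_i Σ_{j≠i} w_j dist(i, j). The denominator reading
1/(k(k−1)) is the only one that normalizes the double sum over ordered
pairs. Covariates are min-max normalized over the full dataset before
distances by default, making d comparable across covariates with different
units; an unnormalized mode preserves positive homogeneity (scaling values
by c scales d by c).

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down analogues of the
full study: 400-pulse datasets (100 subjects × 4 beats) for recovery and
model-selection checks, 1,000 noise-free pulses for autoencoder training,
160-pulse datasets with a 2-epoch autoencoder for grid bookkeeping, and
100 seeded replicates of ~180 pulses for the discrimination-rate property.
These sizes were chosen so the full suite runs in about a minute plus two
minutes of autoencoder work on a single core while leaving every property
it checks size-independent. Other numerical choices worth knowing:
swap acceptance requires an improvement above 1e−12 (guards against
floating-point cycling); the idempotence tolerance of normalization is
1e−12; DDTW affine invariance is asserted below 1e−8 (z-scoring is
exact up to rounding); silhouette agreement with the brute-force formula is
asserted at 1e−9; duplicated-cluster invariance of d holds only up to the
interpolation of empirical quantiles (≈1% at n = 25).

## Known limitations

- The synthetic population is a parametric idealization; none of the
  reported numbers transfer to real cohorts.
- Pulse-level splitting leaks subjects across partitions by design.
- DTW costs are raw cumulative sums; comparing dissimilarities across
  different grid lengths would require normalization the pipeline does not
  need (all pulses share the 100-sample grid).
- The autoencoder is CPU-scale; it is adequate for 100-sample inputs but
  makes no attempt at large-batch or GPU performance.
- `AI_bin` reduces the augmentation index to detectability of a systolic
  shoulder; it does not compute the index itself.
- t-SNE embeddings and radar plots are deliberately out of scope; the CSV
  outputs of `run_experiment()` contain everything those plots would show.
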