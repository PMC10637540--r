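# dvpclust

Unsupervised clustering of photoplethysmogram (PPG) pulse shapes, for
researchers studying pulse-wave morphology and its clinical correlates.

A digital volume pulse (DVP) — one cardiac cycle of a PPG recording —
changes shape with vascular ageing: the dicrotic notch and diastolic wave,
sharp in young compliant arteries, flatten and vanish as arteries stiffen.
The classic taxonomy grades pulses into four notch-based classes, but real
beats vary continuously and labelling them is unreliable. `dvpclust`
answers the question without labels: it clusters beats by shape, asks how
many shape clusters the data support, and quantifies whether the clusters
differ in clinical covariates.

The package provides:

- **Synthetic data**: a generator planting the four classic morphology
  classes (multi-Gaussian pulse model, age-modulated) with clinical
  covariates (age, PWV, pressures, BMI, heart rate, transit time) whose
  moments and bounds emulate a 300-subject adult cohort — so the whole
  pipeline is testable without private clinical data.
- **Preprocessing**: resampling each beat to 100 samples in [0, 1],
  z-scoring, and a 70/30 train/test split (30% of train as validation).
- **Three shape representations**: 14 handcrafted morphology features
  (notch/diastolic ratio with a 1.1 sentinel, areas, derivative and
  second-derivative landmarks, moments, peak count, rise time, ...);
  pairwise **derivative dynamic time warping** (DDTW) with a Sakoe–Chiba
  band of w = 20 samples on z-scored slope series; and the 8-dimensional
  latent space of a 1-D **convolutional autoencoder**
  (conv/pool encoder 100 → 416 → 8, mirrored decoder, trained with Adam on
  reconstruction MSE + L2, early-stopped on validation loss).
- **K-medoids (PAM)** clustering with free medoids, with medoids fixed to
  the four canonical class shapes ("template" mode), or at a cluster count
  chosen from **silhouette** s = (b − a)/max(a, b), **inertia** (mean
  squared distance to medoid) and **prediction strength** (minimum over
  test clusters of the co-assigned ordered-pair fraction) over k = 1..15.
- **Clinical relevance**: Kruskal–Wallis screening with Holm-adjusted Welch
  post-hoc tests, per-cluster normalized covariate means, and a
  size-weighted quantile-function distance
  d = 1/(k(k−1)) Σᵢ wᵢ Σⱼ≠ᵢ wⱼ dist(i, j), where dist(i, j) is the mean
  absolute gap between empirical quantile functions (the 1-Wasserstein
  distance) and wₙ = Nₙ/N penalizes small clusters. Larger d = cleaner
  clinical separation.

## Worked example

Generate 400 synthetic pulses (100 subjects × 4 beats), cluster their DDTW
dissimilarity matrix, and score the result:

```r
library(dvpclust)

ds     <- generate_dataset(synthetic_config(n_subjects = 100,
                                            pulses_per_subject = 4, seed = 1))
pulses <- normalize_pulses(ds$pulses)
D      <- pairwise_ddtw(pulses, w = 20)

fit <- kmedoids_fit(D, k = 4, diss = TRUE)
summary(fit)
#> K-medoids (baseline), k = 4 on n = 400 samples; 1 swap(s)
#>  cluster size percent medoid
#>        1  124      31     75
#>        2   72      18    151
#>        3  140      35    224
#>        4   64      16    275
#> Objective: 106.809

mclust::adjustedRandIndex(fit$labels, ds$labels)
#> [1] 1

curves <- scan_k(D, k_range = 1:8)
curves
#>  k silhouette inertia ps
#>  1         NA 3.67675 NA
#>  2     0.7524 0.68408 NA
#>  3     0.7127 0.30299 NA
#>  4     0.7882 0.07903 NA
#>  5     0.5682 0.07563 NA
#>  ...
choose_k(curves)
#> [1] 4

csm_weighted_distance(fit$labels, ds$clinical$age, variable = "age")
#> Weighted quantile-distance separation for age: d = 0.01083 (k = 4, min-max normalized)
```

The clustering recovers the planted four-class structure exactly
(adjusted Rand index 1), the silhouette curve peaks at the planted k = 4,
and the age distributions of the four shape clusters are measurably
separated (d > 0; a random relabelling of the same sizes scores lower).

`run_experiment()` / `run_experiment_grid()` orchestrate the full
3 representations × 3 modes grid end-to-end (split, representation,
clustering, selection curves, statistical tests, per-covariate d) and write
self-describing run directories of CSV/JSON artifacts.

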