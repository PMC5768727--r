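---
title: "Decoding group membership from encoded fMRI responses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding group membership from encoded fMRI responses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

musdecode classifies *participants* — not stimuli — from how their brains
track a continuous, naturalistic stimulus. The motivating application is
separating musically trained from untrained listeners using region-averaged
fMRI recorded during music listening, but the machinery is generic to any
two-group design with a shared stimulus. This vignette describes the model,
its assumptions, the tunable parameters, the synthetic-data generator used
to validate the pipeline, and the numerical choices made where the design
was open.

## The decoding model

The pipeline has four stages, applied per parcellated brain region.

**1. Participant-wise encoding.** For each participant and region the
z-scored BOLD series $\mathbf{y} \in \mathbb{R}^k$ is regressed on the
$k \times m$ standardized stimulus feature matrix $\mathbf{X}$,

$$\mathbf{y} \approx \mathbf{X}\beta,$$

with no intercept (both sides are centered, so it is identically zero).
`fit_encoding()` solves the least-squares problem by QR decomposition; a
rank-deficient design falls back to the minimum-norm SVD solution with a
warning. The encoded response $\hat{\mathbf{y}} = \mathbf{X}\hat\beta$ is
the participant's stimulus-driven activity with measurement noise projected
out; $R^2 = 1 - \|\mathbf{y}-\hat{\mathbf{y}}\|^2/\|\mathbf{y}\|^2$ equals
the squared correlation of $\mathbf{y}$ and $\hat{\mathbf{y}}$.

**2. Group models.** Within each group $G$ the encoded responses are
modelled as a multivariate normal over time points with a *diagonal*
covariance,

$$\hat{\mathbf{y}}^G \sim \mathcal{N}(\mu^G, \Sigma^G), \qquad
\Sigma^G = \mathrm{diag}(\sigma^2_1, \ldots, \sigma^2_k),$$

estimated by the time-point-wise mean and variance across the group's
training participants (`fit_group_model()`). Diagonality is a deliberate
bias–variance trade: with tens of participants and hundreds of scans a full
$k \times k$ covariance is unestimable. The cost is that serial correlation
in the encoded series is ignored; log-likelihoods are therefore somewhat
overconfident in absolute terms, which is harmless here because they are
only ever *compared* between groups.

**3. Log-likelihood-ratio features.** For any participant's encoded region
series the diagonal-Gaussian log-likelihood

$$\ln\mathcal{L}^G = -\tfrac{1}{2}\sum_{t=1}^k \left[\ln\sigma^2_t +
\frac{(\hat{y}_t - \mu^G_t)^2}{\sigma^2_t} + \ln 2\pi\right]$$

is computed under both group models, and the per-region feature is the
ratio $\Lambda = \ln\mathcal{L}^M - \ln\mathcal{L}^N$ (`llr()`): positive
when the musician model explains the series better.

**4. Region selection and classification.** Because regions outnumber
participants, regions are ranked by the summed correct-group log-likelihood
over the training set,

$$\sum_{p \in M} \ln\mathcal{L}^M_p + \sum_{p \in N} \ln\mathcal{L}^N_p,$$

(`rank_regions()`; ties break deterministically by region index) and the
top $n$ regions' $\Lambda$ values feed a Fisher linear discriminant
(`train_lda()`) with equal priors, whose within-class scatter is inverted
by SVD with singular values below $10^{-4}$ of the largest treated as zero.
Class probability is the sigmoid of the signed Euclidean distance to the
hyperplane, $P = 1/(1+e^{-d})$; whether $d$ is normalized by $\|w\|$ or
left as the raw decision value is configurable (`normalized = FALSE`), with
the normalized distance as default since the probability is defined on a
geometric distance. A sample exactly on the hyperplane is assigned to the
positive (musician) class; the tie is measure-zero but the convention is
fixed so results are deterministic.

Note what the ranking score measures: *how tightly each group's model fits
its own members*, not the separation between groups. Regions are favored
where participants within a group process the stimulus consistently;
discrimination then comes from the LLR features of those regions. The two
coincide when group-affected regions are also within-group consistent — an
assumption about the data, made explicit in the synthetic generator below.

## Cross-validated evaluation

`run_cv()` implements repeated stratified pair-holdout cross-validation:
each run draws a random bijective pairing of musicians with nonmusicians,
and each fold holds out one pair while *everything* — encoding models are
participant-local, group models, region ranking and the discriminant — is
fit on the remaining participants only. With 18 participants per group and
10 runs this yields 180 fold models. Leakage is prevented by construction
(the fold trainer receives only the training participants' encodings) and
verified by a byte-identity test: corrupting the held-out participants'
data on disk leaves the serialized fold model unchanged.

Per run, the held-out predictions cover every participant exactly once and
give accuracy, sensitivity (musician recall), specificity and AUC (rank
statistic over probabilities, ties counting one half). Significance against
chance is the exact upper-tail probability of Binomial($n$, 1/2) at the
run's correct count, summarized by the median over runs
(`binomial_significance()`). Supporting analyses:

- `sweep_regions()` traces accuracy against the number of selected regions,
  with 68%/95% confidence bands for the mean from the across-run standard
  error (bands tighten as runs are added).
- `region_consistency()` reports how often each region was selected across
  all fold models; frequencies sum to the per-fold selection count.
- `llr_group_test()` compares held-out LLRs between groups per region with
  a one-tailed pooled two-sample t-test. Each run's t is mapped to a
  standard-normal Z through its one-tailed p-quantile, Z-values are
  averaged across runs, and the p-value comes from the averaged Z. The
  reference degrees of freedom default to $n-1$ (35 for 18+18), following
  the analysis this reproduces; the conventional pooled-test value $n-2$
  is available via `df =`, and a `direct_t` variant averages the t
  statistics themselves.
- `familiarity_partial_correlation()` correlates decoder probabilities with
  the true class after residualizing both on mean stimulus familiarity — a
  control for the confound that trained listeners tend to know the stimuli
  better.
- `beta_group_tests()` contrasts the encoding coefficients themselves
  (pooled two-sample t per region/feature, plus one-sample tests per
  group), locating *which* stimulus features drive group differences.
- `lateralization_compare()` re-runs the cross-validation with fixed region
  sets (no ranking inside a set), the tool for left/right/bilateral
  comparisons of homologous regions. Fixed-region mode is used because the
  comparison is between named sets, not between selection procedures.

## Stimulus feature preparation

Raw stimulus features (e.g. musical descriptors sampled at a few Hz) are
aligned to the scan series by `prepare_features()`:

1. **HRF convolution** (`double_gamma_hrf()`): difference of two gamma
   densities with unit scale and modes at `peak_delay` (default 5 s) and
   `undershoot_delay` (default 15 s) — shape $a$ with scale 1 puts the mode
   at $a - 1$, so the modes land exactly where specified. The undershoot
   amplitude ratio defaults to the canonical 1/6 and the kernel is
   normalized to unit peak. Only the two delays are fixed by the target
   analysis; the rest is the widely used canonical parameterization and is
   configurable. Convolution is causal ("full", truncated to the input
   length).
2. **Spline detrending** (`detrend_spline()`): subtracts a natural cubic
   spline through block means at `knot_spacing_s` (default 60 s — roughly
   the slowest scanner drift worth removing; no value is prescribed by the
   target analysis). Components much faster than the knot spacing pass
   with <10% amplitude loss.
3. **Temporal smoothing** (`temporal_smooth()`): Gaussian kernel of FWHM
   `fwhm_s` (default 4 s), reading the conventional neuroimaging "width" as
   FWHM; reflective edges so constants pass unchanged.
4. **Downsampling** (`resample_to_scans()`): block means over contiguous
   windows; non-commensurate rates are first interpolated onto the smallest
   commensurate grid.
5. **z-scoring** (`zscore_columns()`): population (1/k) standard deviation
   by default, so standardized betas are exactly unit-scale regression
   weights; the sample convention is available and changes betas only by
   $\sqrt{k/(k-1)}$.

`varimax_components()` (PCA followed by orthogonal varimax rotation of the
retained loadings, via `stats::prcomp` and `stats::varimax`) covers the
generic reduction of a larger descriptor bank to a few interpretable
components; the perceptual component definitions used with real data are
external inputs, not computed here.

## The synthetic cohort generator

`make_cohort()` produces cohorts with exactly the structure the decoder
assumes, so that every downstream claim can be tested against known ground
truth:

- every region's BOLD series is a linear readout of the feature matrix
  plus i.i.d. Gaussian noise with sd `noise_sd`;
- participants' coefficient vectors scatter around their group mean with
  sd `beta_sd` (default 0.5);
- a planted subset of `n_discriminative` regions (default 9) carries a
  group separation: the group means differ by ±`effect_size`/2 (default
  total separation 0.5) on one randomly chosen feature coordinate.

Three generator choices deserve explanation, because they encode the
data assumptions the ranking stage needs:

- **Common coupling norm.** Each region's base coefficient vector has a
  random direction but a fixed norm. Without this, the random spread of
  per-region signal-to-noise (after per-region z-scoring) dominates the
  correct-group-fit ranking, and region selection measures coupling
  strength rather than group structure.
- **Orthogonalized effect coordinate.** The base component on the planted
  coordinate is zeroed (and the norm restored) before the ±δ/2 offsets, so
  the two groups are equally strongly coupled overall and differ purely in
  *direction*; `effect_size` is then a clean separation parameter.
- **Within-group tightness of planted regions** (`disc_beta_sd`, default
  `beta_sd/2`). The ranking score carries no information about a mean
  separation per se; it favors regions whose group models fit tightly.
  Regions shaped by training are therefore modelled as more consistent
  within group as well as separated between groups — the configuration
  under which ranking-based selection is informative, and, implicitly, the
  assumption under which it works on real data.

Defaults emulate the study conditions this package targets: 18+18
participants, 116 regions, $k = 720$ scans (three ~8-minute stimuli at a
2-s repetition time, concatenated), 6 features. `noise_sd = 12` was chosen
so that encoding-model prediction correlations fall in the 0.1–0.3 range
reported for region-averaged naturalistic fMRI (median ≈ 0.23 under the
defaults). Familiarity ratings are drawn per group (means 2.96 vs 2.07,
sd 1.1, clipped to the 1–5 scale) to mirror the reported group difference.
No published noise model exists for these data, so the noise defaults are
conventions — flagged as such here — not estimates.

All randomness flows from one root seed through fixed per-participant
substreams, so enlarging a cohort leaves existing records bit-identical.

What the generator does *not* emulate: spatial structure within or between
regions, hemodynamic nonlinearity, serial correlation of the noise,
head-motion artifacts, or heterogeneity of coupling strength across
regions. Passing tests on synthetic cohorts therefore demonstrate the
correctness and calibration of the machinery under the model's own
assumptions, not the accuracy attainable on real recordings.

## Numerical choices and degenerate inputs

- Group-model variances use the population (1/n) estimator by default
  (configurable to 1/(n−1)); with 17 training members per group the factor
  is immaterial and cancels between groups to first order.
- Variances are floored at $10^{-8}$ (z-scored data) so degenerate groups
  (identical members) keep finite log-likelihoods; the number of floored
  time points is recorded and is zero on realistic data.
- The discriminant's SVD rank threshold is $10^{-4}$ relative to the
  largest singular value, matching the solver convention of the analysis
  this package reproduces.
- Rounding for the binomial test uses `round(accuracy × n)` to the nearest
  integer.
- Constant columns (z-scoring), rank-deficient designs, single-class
  labels, unbalanced cohorts, mismatched dimensions and unknown region
  names are all rejected with errors naming the offender; ties in region
  ranking break by ascending region index.

## Problem sizes used by the test suite

The suite validates calibration and power on reduced cohorts chosen to
exercise the full pipeline quickly: null calibration uses 20 cohorts of
18+18 participants with 12 regions and 120 scans (so the chance band is
that of Binomial(36, 1/2)); the power grid uses 9+9 participants across
four effect sizes and ten seeds with `noise_sd = 1`. The acceptance script
runs the full-scale default cohort (36 × 116 × 720, ten cross-validation
runs). These sizes are the package's own validation design; all thresholds
(95% binomial band, ≥80% planted-region recovery at strong effects,
accuracy ≥ 0.95 at the largest effect) are stated in the tests themselves.

## Known limitations

- The diagonal-covariance group model ignores serial correlation; absolute
  log-likelihoods should not be interpreted, only ratios and ranks.
- Ranking-based selection is blind to discriminative regions that are
  *loosely* coupled within groups; such regions would be missed on real
  data too, which is a property of the method, not of this implementation.
- The familiarity control removes only the *linear* familiarity effect.
- `parcellate()` averages voxels uniformly; no weighting by tissue
  probability or signal quality is attempted.
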