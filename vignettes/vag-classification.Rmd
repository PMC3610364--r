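---
title: "Vibroarthrographic signal features and dynamic weighted classifier fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibroarthrographic signal features and dynamic weighted classifier fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagfusion)
```

## The problem

Vibroarthrography records the vibration of the knee cap with a miniature
accelerometer while the subject swings the lower leg freely (about 135° of
extension and back over 4 s). Healthy articular cartilage is smooth, so the
record is dominated by the slow swing motion with little superimposed
vibration. Degenerated cartilage (chondromalacia, meniscal and ligament
injury) produces friction and click events, so pathological records show
higher amplitude variability, more and larger transients, and more
broadband noise. The package implements a complete screening pipeline for
such signals: two dedicated waveform features plus five classical
statistical descriptors, a least-squares support vector machine (LS-SVM)
classifier, and two classifier ensembles, evaluated with ROC methodology.

The standard acquisition this package assumes is a single channel sampled
at `fs = 2` kHz for 4 s (8000 samples, 12-bit digitization), in
uncalibrated acceleration units.

## Matching pursuit over a wavelet-packet dictionary

The `Natom` feature counts how many greedy matching-pursuit (MP) iterations
a signal needs before its reconstruction reaches a fixed signal-to-noise
ratio. The dictionary is the overcomplete family of periodized orthonormal
wavelet-packet atoms built from the Daubechies `db8` filter: for each level
$l = 1, \dots, L$ (default $L = \log_2 N$) all $2^l$ frequency nodes with
all $N/2^l$ translates, i.e. $P = N L$ unit-norm atoms. At each iteration
the atom maximizing $|\langle R^m x, d_r\rangle|$ over the *whole*
dictionary is selected, its projection subtracted, and the stopping rule is

$$\mathrm{SNR}_m = 10\log_{10}\frac{\lVert x\rVert^2}{\lVert R^m x\rVert^2}
\ \ge\ 15\ \mathrm{dB}.$$

The SNR formula is the standard energy ratio with the residual treated as
noise; the stopping level of 15 dB is the protocol constant. Because each
level of the periodized transform is orthonormal, the inner products with
all atoms of a level are exactly the wavelet-packet coefficients of the
residual at that level, so one iteration costs one full analysis
($O(NFL)$ arithmetic, $F = 16$ taps) instead of $O(N^2L)$ dense products;
an explicit-matrix path (`dictionary_matrix()`) exists for inspection and
is used as an independent brute-force oracle in the test suite.

Numerical choices:

* **Padding.** 8000 is not a power of two; signals are zero-padded to 8192
  before decomposition. Padding adds no energy, so the SNR trajectory and
  hence `Natom` are unaffected by the pad itself.
* **Tie-breaking.** Exact ties in the argmax go to the lowest
  `(level, node, translate)` triple, making decompositions fully
  deterministic.
* **Boundaries.** Periodized filtering keeps every level exactly
  orthonormal at any dyadic length, so per-iteration energy conservation
  $\lVert R^m x\rVert^2 = a_m^2 + \lVert R^{m+1}x\rVert^2$ holds to
  rounding error and is asserted in the tests.
* **Iteration cap.** `max_iter = 2000` by default; hitting the cap is
  reported in `stop_reason`, not an error.
* Dirac (level-0) atoms are excluded: the dictionary covers levels
  $1,\dots,L$ only, consistent with $P = N\log_2 N$.

Intuition for the feature: a smooth, nearly noise-free record reaches
15 dB with a handful of atoms; a noisy, transient-laden record forces the
greedy pursuit to model many incoherent components, so `Natom` rises
sharply with pathology.

## Turns count with a fixed threshold

The `TCFT` feature operates on the amplitude-normalized
(`normalize_amplitude()`, range $[0,1]$) and low-pass filtered signal. The
prefilter is a 10th-order Butterworth with 50 Hz cutoff and exactly unit DC
gain; its delay is compensated by advancing the output 100 samples (0.05 s
at 2 kHz) and zero-padding the tail. The 100-sample advance is a stated
calibration constant of the protocol rather than a computed group delay —
the two differ for this filter — and it is configurable
(`filter.delay_samples`).

A sample is a significant turn when (1) the first difference changes sign
there, both neighboring differences being non-zero, and (2) it differs from
the *immediately preceding* sample by strictly more than 0.2. Condition (2)
deliberately reads the preceding sample, not the previous turning point
(Willison's original electromyographic variant). Two consequences are worth
knowing: the count is invariant to constant offsets but *not* exactly
invariant to time reversal (reversal swaps the roles of the preceding and
succeeding differences around a turn; with threshold 0 the asymmetry
vanishes); and a signal band-limited well below the sampling rate can make
large between-sample steps only if a strong component lies near the filter
cutoff — see the generator discussion below.

Constant signals are rejected by `normalize_amplitude()` rather than mapped
to zeros: silently flat records would register zero turns and corrupt a
cohort analysis undetected.

## Statistical features

Five further descriptors complete the 7-vector
`[natom, tcft, ff1, ff2, vms, mu, fd]` (`extract_feature_vector()`):

* **Form factors `ff1`, `ff2`** — the Hjorth complexity/mobility ratio
  $(\sigma_{x''}/\sigma_{x'})/(\sigma_{x'}/\sigma_x)$ on each half of the
  normalized signal (the two halves roughly correspond to extension and
  flexion). Scale-invariant; 1 for a pure sinusoid in the dense-sampling
  limit.
* **`vms`** — unbiased variance of per-segment mean squares,
  non-overlapping segments of 50 ms by default (`vms.segment_s`); measures
  how unevenly power is distributed across the swing.
* **`mu`** — mean of the Gaussian-kernel Parzen amplitude density,
  computed by quadrature over the density (with a zero-mean kernel it
  equals the sample mean, which the tests verify to 1e-6); bandwidth
  defaults to Silverman's rule of thumb.
* **`fd`** — spectral fractal dimension: least-squares slope $-\beta$ of
  log-PSD against log-frequency (Welch-averaged, Hann windows, 50%
  overlap) mapped through $FD = (5-\beta)/2$. The default fit band is
  10 Hz up to $\min(500, 0.45\,f_s)$: DC and the region near Nyquist are
  excluded because detrending, windowing and aliasing bias the power-law
  fit there. The estimate is returned unclipped.

Feature screening uses the classic pooled-variance two-sided Student
t-test (`two_sample_t_test()`, significance convention $P < 0.01$), with
limit conventions $p = 1$ (zero variance, equal means) and $p = 0$ (zero
variance, unequal means).

## Least-squares SVM

`train_lssvm()` solves the KKT linear system of the equality-constrained
regularized least-squares problem

$$\begin{pmatrix}0 & \mathbf 1^\top\\ \mathbf 1 & \Omega + I/\gamma
\end{pmatrix}\begin{pmatrix}b\\ \alpha\end{pmatrix} =
\begin{pmatrix}0\\ y\end{pmatrix},$$

with $\Omega$ the plain kernel Gram matrix and $y \in \{\pm1\}$ (abnormal
is $+1$, the clinical true-positive convention). Of the two classic
equivalent LS-SVM formulations this one keeps decision values directly
comparable to the labels, which the fusion rule below exploits. The bias
row enforces $\sum_i \alpha_i = 0$; the tests assert this and the KKT
residual to 1e-8 relative. The default configuration is the polynomial
kernel with degree 2 and intercept 1 and regularization $\gamma = 5$; the
kernel-selection sweep that produced this choice in the source study is
too loosely specified to replicate, so the winning configuration is fixed
as the default rather than re-searched.

Features are standardized to zero mean and unit variance *inside* the
model, using training-fold statistics only (leave-one-out and bootstrap
retrainings each re-estimate them). Kernel methods on features with wildly
different units — an atom count against a variance of squares — are not
meaningful without this; a zero-variance feature gets scale 1. The system
is solved densely with partial pivoting ($n$ is at most a few hundred);
singularity raises an error carrying the reciprocal condition number.

`loo_evaluate()` implements leave-one-out validation: $n$ retrainings,
each scored on its held-out sample.

## Ensembles: Bagging and dynamic weighted fusion

`bagging_train()` draws $K = 5$ bootstrap resamples of the full training
size (single-class resamples are redrawn, at most 100 attempts) and trains
one component LS-SVM (CSVM) per resample; `bagging_predict()` averages the
component decision values. `dwf_predict()` fuses the same components with
per-sample weights

$$w_k = \frac{\sum_j e_k^{-1}e_j^{-1}}{\sum_i\sum_j e_i^{-1}e_j^{-1}}
      = \frac{e_k^{-1}}{\sum_j e_j^{-1}}, \qquad
g_{\mathrm{DWF}} = \sum_k w_k g_k,$$

where $e_k = l - g_k$ is the component error. Three design points:

* **Error transform.** Applied to signed errors the closed form can
  produce negative weights or a vanishing denominator (e.g.
  $e = (1, -1)$), violating the nonnegativity/normalization constraints it
  is meant to satisfy. The default mode therefore uses $|e_k|$; a
  `"signed"` mode implements the literal formula for study. Components
  with $|e_k| \le \varepsilon$ ($\varepsilon = 10^{-12}$) take the natural
  $w \propto 1/e$ limit: all weight split equally among them.
* **Oracle versus estimated weights.** The published evaluation computes
  test-time errors from the *true* label, which cannot be deployed
  prospectively. `dwf_mode = "oracle"` reproduces that protocol (and is
  what the pipeline's headline "DWF" row reports); `"estimated"`
  substitutes one constant per component — its mean absolute validation
  error — giving a deployable but weaker rule. Results from oracle mode
  should be read as an upper bound, not an expected field performance.
* **An algebraic inconsistency, implemented as printed.** The closed-form
  weights are *not* the stationary point of the constrained quadratic
  program they are derived from (for distinct positive errors the
  stationarity conditions cannot hold), and substituting them into the
  quadratic form $\sum_{kj}w_k w_j e_k e_j$ yields
  $K^2/(\sum e^{-1})^2$ — $K^2$ times the printed closed-form ensemble
  error $1/(\sum e^{-1})^2$. The package implements both printed
  expressions literally — `dwf_ensemble_error()` returns the closed form,
  `dwf_weighted_squared_error()` the quadratic form — and documents the
  discrepancy instead of guessing an intended correction. The bound
  $e_k^2 / e^2_{\mathrm{DWF}} \ge 1$ holds for the closed form on strictly
  positive errors and is verified over random draws in the tests.

`active_select_fixed_size()` adds the small-training-set variant: working
subsets of fixed size 15 are refined by random swap proposals against the
candidate pool, accepting a swap only when the quadratic Rényi entropy
$H_2 = -\log\big(n^{-2}\sum_{ij}\kappa(x_i - x_j)\big)$ (Gaussian
convolution kernel, variance $2h^2$ per dimension) strictly increases.
Features are standardized first and the bandwidth defaults to Silverman's
multivariate rule, both undocumented in the source protocol and therefore
package choices; termination is `max_steps = 500` proposals or 100
consecutive rejections, a concrete stand-in for "entropy becomes stable".

## Evaluation

`roc_auc()` builds the empirical ROC curve over all distinct thresholds
(ties step diagonally) and integrates by trapezoid, which equals the
rank-sum estimator with half-credit for ties; the tests verify the
equivalence by brute force over all positive–negative pairs and
cross-check against an independent ROC implementation. The standard error
is Hanley–McNeil with $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$ — the SE
estimator behind reported tables of this kind is conventionally unnamed,
so the choice is stated here. The empirical (assumption-free) area is used
rather than a binormal fit.

## The synthetic cohort generator

No public VAG corpus exists, so `generate_synthetic_cohort()` defines the
study conditions for every cohort-level claim the package tests. Both
classes share a smooth swing baseline (two sweep cycles with a slow
envelope inside `base_band`, unit amplitude). On top of that:

* **Normal**: rare small raised-cosine transients (Poisson rate 4,
  amplitudes 0.2–0.6) and white noise with sd 0.03.
* **Abnormal**: frequent larger transients (rate 25, amplitudes 0.8–2.0,
  mostly one-sided), *crepitus bursts* — Hann-enveloped 30–48 Hz carriers,
  50–150 ms long, Poisson rate 6, amplitude about 3 relative to the unit
  swing — white noise with sd 0.15, and a 0.05-amplitude 50 Hz powerline
  component. Optional 12-bit quantization mimics the acquisition chain and
  is off by default so floating-point identities in tests stay exact.

The crepitus component deserves explanation. After the 50 Hz low-pass, a
turn needs an adjacent-sample step exceeding 0.2 of the full normalized
range; at 2 kHz a band-limited signal cannot produce such steps (the
per-sample increment of even a full-range 50 Hz component is an order of
magnitude too small), and broadband noise is removed by the filter. The
only physically sensible source of supra-threshold turns is a strong
oscillation just under the cutoff — which is exactly what pathological
friction vibration is. Amplitudes were chosen once, from a feasibility
study of the filter's step-response geometry, so that abnormal records
show a clear but not saturated turn count; they were not tuned against
test outcomes afterwards.

Cohort-level tests run at a reduced rate: 1024 samples over the same 4 s
swing (256 Hz) instead of 8000. This keeps a full 51 normal / 38 abnormal
cohort's matching-pursuit pass near ten seconds while preserving the class
structure; at 256 Hz the 0.2-range steps are also attainable, making the
turns-count separation observable at all. The generator is the same code
at every rate — only `fs` changes.

What the generator does *not* emulate: muscle-contraction interference
with realistic spectra, baseline wander from electrode movement,
inter-subject variability in swing speed, or any calibrated physical
units. Passing cohort tests therefore demonstrates that the pipeline
recovers the intended qualitative class structure — abnormal records need
more MP atoms, show more significant turns, and the oracle-weighted fusion
dominates its components — not that clinical accuracy figures would be
reproduced on real patients.

## Problem sizes used by the test suite

Matching-pursuit oracle equivalence runs at $N = 64$ against the explicit
matrix; cohort-level properties use 51/38 cohorts of 1024-sample signals
over 20 seeds (feature screening) and 10 seeds (ensemble ordering);
fusion-algebra properties use 1,000 random error vectors with $K = 5$.
These sizes are the package's reference configuration for desk-scale
verification.

## Known limitations

* Oracle-mode DWF needs true labels at prediction time; it is an
  evaluation protocol, not a deployable classifier. Use
  `dwf_mode = "estimated"` (or Bagging) prospectively.
* `Natom` from zero-padded 8192-sample decompositions is not numerically
  comparable to counts obtained with other padding or boundary
  conventions; printed atom counts from other implementations cannot be
  replicated exactly, only their ordering.
* The fixed 100-sample delay compensation is exact only for the protocol
  rate; at other sampling rates it is a convention carried over, and the
  trailing zero-pad can contribute one spurious turn at the record tail.
* The turns count at the native 2 kHz rate is near zero for any
  band-limited signal, as discussed; its discriminative value lives at
  reduced rates or with threshold recalibration.
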