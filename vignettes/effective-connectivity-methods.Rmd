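---
title: "Methods: simulation-backed effective-connectivity analysis for MEG"
author: "megnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed effective-connectivity analysis for MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnet)
```

## The analysis model

`megnet` estimates *effective connectivity* — directed statistical
influence between neural sources — from sensor-level MEG recordings, and
wraps the estimation chain in a synthetic-cohort generator so that every
stage can be checked against a known ground truth.

The chain is:

1. **Preprocessing.** Per-channel DC removal, a 50 Hz zero-phase notch
   filter, and a zero-phase Butterworth band-pass into one of the five
   canonical bands (delta 1–4, theta 4–8, alpha 8–12, beta 13–30,
   gamma 30–90 Hz). Trials are cut around the stimulus trigger and the
   90–180 ms post-trigger window is retained; trials whose peak amplitude
   exceeds a rejection threshold are dropped before averaging.
2. **Source reconstruction.** A unit-gain scalar LCMV beamformer,
   $w = (C+\lambda I)^{-1} g \,/\, g^\top (C+\lambda I)^{-1} g$, with
   diagonal loading $\lambda$ equal to a fraction (`reg`, default 0.05) of
   the mean sensor variance, scanned over a volumetric grid (6 mm default
   spacing). Grid voxels closer than 10 mm are greedily merged in
   descending output-power order — strictly *less than* 10 mm merges;
   exactly 10 mm keeps both.
3. **Connectivity.** Pearson correlation
   $R(X_a, X_b) = C(X_a, X_b)/(S_{X_a} S_{X_b})$ between every retained
   virtual-sensor pair, thresholded through its t value
   $T_p = R\sqrt{(K-2)/(1-R^2)}$ with $K$ data points per connection; a
   pair is kept when the two-sided p-value under $t_{K-2}$ is below 0.01.
   Surviving pairs are directed by multivariate Granger causality: an MVAR
   model fitted by least squares (order by BIC up to a cap), with
   $GC(a \to b) = \ln(\hat\sigma^2_{b|\text{reduced}} /
   \hat\sigma^2_{b|\text{full}})$ and an F-test per direction. Positive-R
   edges are excitatory, negative inhibitory; nodes are labelled driver,
   driven, mixed or isolated by their directed degree balance.
4. **Graph metrics.** Degree D, strength S (sum of $|R|$), characteristic
   path length L (mean shortest-path hops over connected pairs, undefined
   when no path exists) and clustering coefficient C, all on the
   undirected binarized skeleton.
5. **Group statistics.** Fisher's exact test on the per-group prevalence
   of a directed region pattern (PFC→TL by default); pooled two-sample
   t-tests on the four metrics with both Bonferroni families
   (0.05/5 = 0.01 per band; 0.05/20 = 0.0025 per band × parameter) and
   Benjamini–Hochberg step-up flags, reported side by side and never
   merged; Spearman correlations (midranks, t-approximation p) between
   clinical covariates and metrics within the patient group.

### Reading of the correlation formula

The correlation is implemented as the Pearson coefficient — covariance
over the product of standard deviations. The accompanying prose
description of the numerator as a "mean" is not adopted: only the
covariance reading yields a correlation coefficient bounded by 1 and
compatible with the $T_p$ formula, which assumes $|R| \le 1$.

### Direction significance on band-limited data

Parametric Granger F-tests assume the fitted VAR whitens the residuals.
Band-limited signals violate this at any practical model order when the
band occupies a small fraction of the spectrum, making the tests
anti-conservative; zero-phase (non-causal) filtering makes this worse.
Three choices in the package's validation configuration respond to this:

* the smoke-scale studies run at 250 Hz, where the 30–90 Hz gamma band
  spans roughly half of the spectrum and a short VAR can whiten it;
* the MVAR order is capped at 3 (12 ms of lags at 250 Hz — still "a few
  milliseconds" of prediction horizon); at 1000 Hz the default cap is
  20 ms of lags;
* `example_pipeline_config()` uses a direction threshold of 0.005 instead
  of the `granger_direction()` default of 0.05. The stricter level was
  chosen, before the acceptance studies were frozen, to bring the
  false-directed-edge rate on correlated-but-uncoupled pairs down to a few
  percent while leaving planted-edge sensitivity near 1.

On white (VAR-representable) signals the F-test is well calibrated — the
measured per-direction null rejection rate at $\alpha = 0.05$ is ≈0.05 —
so the default threshold is kept for that regime.

## The synthetic cohort generator

Sources are stable MVAR processes: stability is enforced by a companion
spectral-radius check (< 1) at construction. The generative design
separates the two measurable aspects of a connection:

* **Correlation** is planted through the innovation covariance
  (instantaneous), because a lagged coupling between band-limited
  oscillations produces near-orthogonal signals when the lag approaches a
  quarter cycle — at 250 Hz a one-sample lag in the gamma band is ~90° of
  phase, which would leave nothing for the $R/T_p$ stage to find.
* **Direction** is planted through lag-1 MVAR coefficients, which is what
  Granger causality measures.

Innovations are shaped into the analysis band with a *causal* (forward
only) Butterworth filter. A zero-phase filter here would make the source
process depend on future innovations and corrupt the planted directed
structure — this is measurable: with zero-phase shaping, independent
sources show spurious Granger direction at rates above 40%.

The forward model is a distance-kernel gain matrix: gain magnitude decays
with the inverse square of the channel–source distance, modulated by a
seeded orientation factor whose sign may flip across the array, as real
neuromagnetic field topographies do. The orientation diversity is what
keeps nearby sources separable for the beamformer; with strictly positive
smooth gains, gain columns become nearly collinear and no spatial filter
can unmix them.

The reference study conditions (`example_network()`,
`example_cohort_spec()`) are: 8 sources (one PFC, one TL, one OCC, five
OTHER), planted PFC→TL lag-1 coupling 0.5 with innovation correlation
0.5, three background pairs (excitatory 0.35/0.4, inhibitory −0.3/−0.4,
and one purely instantaneous 0.45), diagonal AR terms 0.3 and 0.1,
gamma band, 32 trials × 80 samples at 250 Hz, 32 channels, 10 dB sensor
SNR. Desk-scale runtime motivated the 250 Hz/32-channel scale; the
sampling rate is configurable up to real-hardware rates (the
`cohort_spec()` default is 1000 Hz, and 6000 Hz is honoured).

Per subject, a Bernoulli draw at the group prevalence decides whether the
planted PFC→TL coupling is present, and a background-network gain factor
$u \sim U(0.4, 1.6)$ scales every coupling and instantaneous correlation
*except* the planted pair. Clinical covariates follow marginals typical of
a migraine clinic population; the tied covariate (HAM-A by default) is
drawn through a Gaussian copula against $u$ at the requested Spearman
correlation. Anchoring on the background gain, not the planted edge, keeps
pattern detectability independent of the clinical anchor while measured
strength S still tracks $u$ strongly (rank correlation ≈ 0.85 under the
reference conditions).

### What the generator does not emulate

Realistic forward physics (no boundary-element head model), head movement,
ocular/cardiac artifacts, phase-locked evoked components, 1/f background
spectra, and within-subject stimulus-condition structure (conditions are
modelled as independent cohort runs). Passing the simulation studies
therefore demonstrates the correctness of the estimation chain under its
own generative assumptions, not robustness to every property of real MEG.

## Numerical choices

* **Filters** are designed directly in second-order sections from the
  analog Butterworth prototype (prewarp → band transform → bilinear per
  conjugate pole pair). The flat order-8 transfer-function polynomial is
  numerically ill-conditioned at narrow normalized bands (delta at
  1 kHz); the biquad cascade keeps linearity errors near machine
  precision. Zero-phase application uses reflection padding.
* **Connectivity signals**: the `signal_mode` flag chooses the
  trial-averaged evoked window (`"averaged"`, the default, $K$ = window
  samples) or concatenated per-trial windows (`"concatenated"`,
  $K$ = total samples, with MVAR lags never crossing trial boundaries).
  The validation studies use `"concatenated"`: the generator's sources
  are stochastic rather than phase-locked, so trial averaging would
  cancel them.
* **Voxel-merge tie-breaks**: output power descending, then lowest voxel
  index.
* **Degenerate inputs**: zero-variance sources are excluded from the
  correlation with a warning; rank-deficient MVAR regressions flag the
  pair undirected; an all-rejected trial set is an error, not an empty
  average; a zero margin in the Fisher table returns p = 1 with a warning.
* **Head-movement rule**: strictly "beyond" — exactly 5 mm is kept.
* **Path length**: disconnected pairs are excluded from the mean
  (`NA` when no pair is connected); isolated and degree-1 nodes
  contribute clustering 0 so group means compare fixed node sets.
* **Conditional vs pairwise GC**: conditional (full multivariate model)
  up to `gc_max_system` sources (default 20), pairwise above, with a
  message. The two agree exactly on 2-node systems.

## Validation studies

The package's claims are established by the test suite and by
`scripts/acceptance.R` at these problem sizes: brute-force agreement of
the four graph metrics on 500 random graphs of up to 8 nodes; Fisher p
against exhaustive table enumeration; BH-FDR against the explicit step-up
rule on 10⁴ random p-vectors; t-threshold equivalence on 10⁴ random
(R, K) pairs; direction recovery on 200 planted bivariate VAR(1) seeds
with 500-pair null calibration; beamformer recovery over 100 two-source
runs at 10 dB SNR; and 200 end-to-end cohort replicates (24 + 24 subjects,
prevalences 19/24 vs 8/24, clinical Spearman −0.5) checking the Fisher
decision at α = 0.01 and the recovered correlation sign. A useful
calibration fact for the last study: with the planted prevalences the
Bernoulli draws alone cap the probability of a Fisher p below 0.01 at
about 0.70 even with perfect subject-level detection, so a majority — not
near-certainty — is the correct expectation.

## Known limitations

* The Granger stage's parametric significance is trustworthy only when
  the VAR can whiten the signals; for narrow bands at high sampling rates
  prefer resampling so the band occupies a large spectral fraction, and
  treat direction p-values as indices rather than calibrated error rates.
* Correlation-then-direction inherits the usual beamformer-leakage
  caveats; source pairs closer than a few centimetres at moderate channel
  counts will show inflated connectivity regardless of thresholding.
* The 2×2 prevalence pattern is a single-edge criterion
  (`min_edges = 1`); with many same-labelled regions the family of
  qualifying pairs grows and the detection false-positive rate with it.
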