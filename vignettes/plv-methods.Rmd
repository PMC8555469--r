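---
title: "Methods: phase-locking networks for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking networks for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## Overview

`plvnet` implements a complete functional-connectivity analysis for
two-class (left/right hand) motor-imagery EEG, together with a synthetic
cohort generator whose phase-coupling strength has a closed-form expected
connectivity value. The pipeline is:

1. common average reference (CAR),
2. zero-phase 8–30 Hz band-pass,
3. spherical-spline surface Laplacian (current source density),
4. instantaneous phase by complex Morlet wavelet convolution,
5. inter-trial phase-locking value (PLV) per electrode pair, computed in a
   rest window and a motor-imagery (MI) window, plus their difference
   (ΔPLV = MI − rest),
6. averaging of pair PLVs at several network scales,
7. a median split of subjects into High/Low performance groups by online
   BCI accuracy, and
8. a permutation two-way factorial ANOVA (group × imagery hand) per
   (scale, window, band) cell with Bonferroni control across activity
   types and bands.

## The connectivity measure

For electrodes $i, j$ and trial $n$ with instantaneous phases
$\varphi_{i,n}(t)$, the inter-trial PLV at time $t$ is the mean resultant
length across $N$ trials,

$$R_{ij}(t) = \frac{1}{N}\left|\sum_{n=1}^{N}
  e^{\,\mathrm{i}\,(\varphi_{i,n}(t) - \varphi_{j,n}(t))}\right|,$$

and the reported PLV of a window is the time average of $R_{ij}(t)$ over
the window's samples (the default `agg = "samplewise"` in `plv_pair()`;
`agg = "pooled"` instead pools all (trial, sample) phase differences into
one resultant, which is smoother but mixes temporal and trial variability).

Anchors used throughout the tests: identical phase sequences give
PLV = 1; phase differences alternating $0, \pi$ over an even number of
trials give PLV = 0; i.i.d. uniform phase differences give the Rayleigh
floor $\mathbb{E}[R] \approx \sqrt{\pi/(4N)}$ (0.0886 at $N = 100$), which
is why PLV comparisons are always made at matched trial counts.

## Phase extraction

Phases come from convolution with a complex Morlet wavelet
$\psi(t) = (\pi f_b)^{-1/2} e^{\,\mathrm{j} 2\pi f_c t} e^{-t^2/f_b}$ with
band presets alpha ($f_c = 10.5$ Hz, $f_b = 0.3$ s²) and beta
($f_c = 21.5$ Hz, $f_b = 0.13$ s²). The kernel is truncated where its
Gaussian envelope falls below $10^{-6}$ of the peak; at 250 Hz the alpha
half-kernel is 509 samples (≈ 2.04 s). Convolution is FFT-based and
batched over trials and channels (`stats::mvfft`).

**Valid mask.** Samples within one half-kernel of a trial edge are edge
contaminated and excluded via the tensor's `valid_mask`. Window averaging
in `plv_pair()` intersects the requested window with this mask, so the
rest window [0, 3) s effectively starts ≈ 2.04 s in, and the MI window
[4, 7.5) s effectively ends ≈ 5.96 s. Windows are half-open $[t_0, t_1)$.

## Preprocessing choices

- **CAR** subtracts the instantaneous mean across channels; it is linear,
  idempotent, and maps constant fields to zero (all unit-tested).
- **Band-pass**: the default is a 4th-order Butterworth applied forward
  and backward (`signal::filtfilt`, zero phase). An equivalent linear-phase
  FIR design (`method = "fir"`) is provided; it is not the default because
  the ~800-tap kernel needed at 250 Hz produces edge transients comparable
  to the 8 s trial length.
- **Surface Laplacian**: Perrin-style spherical splines with stiffness
  $m = 4$, 50 Legendre terms, and ridge regularization
  $\lambda = 10^{-5}$ added to the diagonal of the G matrix. Validated by
  physical invariants: a spatially constant field maps to (numerically)
  zero, a focal Gaussian source stays localized at its electrode, and the
  solution responds measurably to $\lambda$.

The stage order is CAR → band-pass → Laplacian (`preprocess_epochs()`);
all three stages are linear, so their composition is too, which the suite
checks directly on random mixtures.

## The synthetic generator

`generate_subject()` produces trials on a 16-channel idealized 10-20
montage (unit sphere, algorithmically constructed) at 250 Hz, 8 s per
trial, with a cue at 3 s. Each channel carries an oscillator at the band
center frequency with per-trial uniform starting phase and ±0.5 Hz
frequency jitter. Coupling is specified as directed rows
(`source_spec()`): on each trial the destination's phase is set to the
source's phase plus a von Mises offset with concentration $\kappa$
(drawn per trial; separate $\kappa$ for rest and for MI under each hand,
blended over a 0.25 s ramp at the cue). Rows apply in order; a later row
overrides a destination set earlier. Pink ($1/f$) noise is added at a
chosen SNR (`Inf` = noiseless).

Because a von Mises offset with concentration $\kappa$ has mean resultant
length $I_1(\kappa)/I_0(\kappa)$, the expected PLV of a coupled pair is
known in closed form: 0.2425, 0.4464, 0.6978, 0.8635 for
$\kappa = 0.5, 1, 2, 4$. `plv_recovery()` regenerates such data and pushes
it through band-pass + Morlet phase + PLV, recovering these values to
within 0.05 with 200 trials. That harness deliberately skips CAR and the
Laplacian: spatial filters remix sources across channels, so including
them would test a different property than estimator correctness.

**What the generator does not emulate:** volume conduction and realistic
forward-model mixing, amplitude dynamics (ERD/ERS), artifacts (EMG, EOG,
line noise), non-stationary coupling within a segment, or any demographic
structure. Group differences enter only through the coupling
concentrations and the accuracy distributions.

## Windows, scales, groups

- Default windows: rest [0, 3) s, MI [4, 7.5) s; ΔPLV is the pairwise
  MI − rest difference matched on (subject, condition, band, pair).
- Scales (`default_scales()`): **global** = all 120 pairs of the montage;
  **large** = the 25 inter-hemispheric pairs between the left hub
  {FC5, FC1, C3, CP5, CP1} and the right hub {FC6, FC2, C4, CP6, CP2};
  **local_left / local_right** = in the default `"center"` mode, the 4
  pairs from C3 (resp. C4) to its hub neighbors; a `"within_hub"` mode
  uses all 10 within-hub pairs instead. Scale averages are unweighted
  means and error if a required pair is missing (naming it).
- Groups: `median_split()` assigns subjects strictly above the median
  accuracy to High, strictly below to Low, and excludes ties with the
  median — a 55-subject cohort with distinct accuracies yields 27/27/1.

## Permutation inference

`perm_anova_2x2()` computes classical two-way F statistics (Type-II sums
of squares, via differences of fitted sums of squares between nested QR
fits, vectorized so all permutations are one matrix operation) and
permutation p-values $p = (b+1)/(B+1)$ with $B = 999$ by default.

Two schemes are available:

- `"manly"` (default): the response is permuted freely; appropriate for
  the omnibus null and calibrated in the test suite (1000 null datasets of
  27 + 27 subjects × 2 hands, 199 permutations each: rejection rates at
  $\alpha = 0.05$ fall in [0.035, 0.065] for all three effects).
- `"subject"`: restricted permutations honoring the repeated measure —
  whole-subject blocks are permuted for the group effect, hand labels are
  flipped within subjects for the hand effect, and the interaction uses
  free permutation.

Six activity-type × band families (rest, MI, Δ × alpha, beta) give the
Bonferroni threshold $0.05/6 = 0.00833$, conventionally displayed as
0.008 (`bonferroni()`).

## Problem sizes used in validation

- PLV estimator vs. a naive double loop: 10 random phase tensors,
  agreement to $10^{-10}$.
- Bessel-ratio recovery: 200 trials per $\kappa \in \{0.5, 1, 2, 4\}$,
  max error < 0.05, monotone in $\kappa$.
- Type-I calibration: 1000 null replicates × 199 permutations.
- End-to-end replication (`run_group_replication()`): 17 synthetic
  subjects (8 High / 8 Low / 1 excluded), 24 trials, planted MI coupling
  ($\kappa = 1.2$) from C4 into its hub neighborhood in the High class
  only, per-subject nuisance ring coupling elsewhere, SNR 3, 999
  permutations. Across independent seeds the group effect is detected at
  the local right scale below 0.05/6 in the majority of runs while the
  global, inter-hemispheric, and local left scales stay null.

## Limitations

PLV is sensitive to volume conduction and reference choice; the surface
Laplacian mitigates but does not eliminate this, and zero-lag spurious
coupling is not explicitly suppressed (no imaginary-coherence variant is
implemented). Inter-trial PLV requires consistent phase relationships
relative to trial timing and is not an amplitude measure. The Manly
permutation scheme assumes exchangeability under the null; for strongly
heteroscedastic groups, prefer `scheme = "subject"`. Synthetic results
validate the estimator and inference machinery, not any empirical claim
about human EEG.
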