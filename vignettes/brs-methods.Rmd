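---
title: "Between-run spectral-power similarity: model, parameters, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-run spectral-power similarity: model, parameters, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brseeg)
```

## The measurement model

`brseeg` treats a participant's resting-state EEG as a stationary
multichannel process whose spectral content may shift between two recording
runs. The quantity of interest is not the spectrum itself but its
*within-person stability across runs*: participants whose post-task resting
spectrum fails to return to its pre-task shape show low between-run
similarity (BRS).

The statistic is built in five stages:

1. **Epoching.** Each 90-s run is band-pass filtered (0.5–50 Hz, zero-phase
   FIR) and cut into 6-s epochs with 60% overlap. With the step rounded in
   samples (1,200 at 500 Hz) the count is
   `floor((T − L)/step) + 1`, giving exactly 36 epochs per run; a trailing
   partial epoch is discarded. Epochs containing any sample above 100 µV in
   magnitude are rejected, a deterministic surrogate for visual artifact
   screening (so a run with one contaminated epoch keeps 35).
2. **Band powers.** Per epoch and electrode, the demeaned, Hann-tapered
   one-sided periodogram is summed over half-open bands [low, high):
   delta 1–4, theta 4–8, low alpha 8–10, high alpha 10–13, low beta 13–20,
   high beta 20–30, gamma 30–45 Hz. Half-open intervals count shared edges
   exactly once, and the normalization makes band powers over a partition
   sum to the signal power (a unit on-bin sinusoid contributes ≈ 0.5 µV²).
3. **Region vectors.** Band powers are averaged (unweighted) over each scalp
   region's electrodes — frontal(7), central(6), parietal(6), occipital(3),
   left/right temporal(4) — and the 7 band means of epoch *i*, run *r* are
   concatenated into p<sub>i</sub><sup>r</sup>.
4. **Similarity.** Every cross-run epoch pair contributes
   s<sub>ij</sub> = 1/‖p<sub>j</sub>² − p<sub>i</sub>¹‖; the region's raw
   BRS is the mean over all n × m pairs. Distances are floored at 10⁻¹²:
   the reciprocal is undefined at zero distance, which is unreachable for
   noisy data but must be well-defined for degenerate inputs. Reciprocal
   Euclidean distance makes S homogeneous of degree −1 in overall power
   scale — a deliberate property check in the tests, and the reason the
   standardization step matters.
5. **Standardization.** Raw similarities are small and scale-dependent, so
   each region's values are z-scored against the healthy-control group
   (sample n−1 standard deviation): HC mean 0, HC sd 1 by construction,
   patient values in healthy-sd units.

### Montage note

The default montage assigns Oz as the third occipital electrode, giving 30
unique electrodes; a variant (`defaultMontage(occipitalThird = "Cz")`)
places Cz in both the central and occipital regions for compatibility with
listings that describe the occipital region that way.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| band edges (Hz) | 7 bands, 1–45 | canonical clinical bands; order fixes vector components |
| epoch length / overlap | 6 s / 60% | 36 epochs from 90 s; 6 s gives 1/6 Hz resolution, enough for the 1 Hz delta edge |
| FIR band-pass | 0.5–50 Hz, Hamming windowed-sinc, order = rate | ≤ 0.5 s single-pass group delay; applied forward–backward (zero phase) |
| rejection threshold | 100 µV | conventional EEG artifact amplitude bound |
| distance floor ε | 10⁻¹² | defines the degenerate zero-distance case deterministically |
| standardization sd | sample (n−1) | clinical z-scoring convention; population sd available |
| SVM grid | odd powers of two, 2⁻²⁹…2²⁹ (30 × 30) | exhaustive default; `smallParamGrid()` (3 × 3, C ∈ 2^{−3,1,5}, γ ∈ 2^{−5,−1,3}) for desk-scale runs |
| libsvm tolerance | 10⁻⁶ | decision values then match an exact dual solution to ~10⁻⁵ |

## Classification and evaluation design

Binary tasks (MCI–HC, AD–HC, AD–MCI) are evaluated by leave-one-participant-
out cross-validation; accuracy is correct participants over total, so its
granularity is 1/N (one flip in a 50-participant task moves the error rate
by exactly 2 points). LDA uses the pooled-covariance linear discriminant
with configurable class penalties and priors; a scalar shrinkage toward the
identity engages only when the pooled covariance's condition number exceeds
10⁸ (relevant for 21-dimensional coherence features on ~45 training rows).
The RBF-SVM is the standard soft-margin dual; sequential forward selection
of the six regional features is carried out jointly with the grid search:
a full SFS chain is grown per grid point and the global argmax over
(grid point, chain prefix) is reported, with deterministic tie-breaks
(earlier region in montage order, then smaller C, then smaller γ).

**Caveat — validation, not test, accuracy.** The held-out participant in
each fold participates in the feature-selection and hyperparameter argmax,
so the reported best accuracy is a *validation* accuracy with an optimistic
selection bias. Under a pure null (no group difference, N = 40) the argmax
over a 3 × 3 grid × 6 chain prefixes of Binomial(40, ½)/40 draws has
expectation ≈ 0.70–0.75 — far above chance. The package therefore also
provides a leakage-safe mode: `brsFoldStandardizer()` re-standardizes BRS
features from the training fold's healthy controls only, and the
`std-mode = fold-train` path recomputes everything per fold. Both modes are
first-class; side-by-side reporting is recommended.

## The synthetic cohort generator

Because clinical two-run EEG datasets are rarely shareable, the generator is
first-class, tested code. It emulates exactly the structure the BRS
analysis assumes:

- per-region per-band **log-normal band powers**: subject-level profile
  (log-sd 0.2 around an alpha-dominant clean-resting profile of
  8, 8, 10, 10, 8, 6, 4 µV² for delta…gamma), epoch-level jitter
  (log-sd 0.15);
- a **group-dependent run-2 perturbation**: a per-participant, per-band
  log-power shift drawn with group-specific scale — HC 0.05 in all bands,
  MCI 0.6 in low/high beta and gamma, AD 0.5 in delta and theta (0.1
  elsewhere for patients) — so patient groups drift between runs in
  band-specific ways while controls barely move;
- default cohort sizes 27 HC / 24 MCI / 23 AD.

These are *testability* conditions, not clinical claims: magnitudes were
chosen analytically (before any test was frozen) so that the documented
"strong effect" (MCI log-sd 0.8 in beta/gamma vs HC 0.05) exceeds the
generator's nuisance variability — with a delta-dominated profile or large
subject-scale noise, a beta/gamma shift would be geometrically invisible to
a Euclidean distance on raw powers, which is itself an instructive property
of the statistic.

Two fidelity levels exist. `simulatePowerVectors()` draws region power
vectors directly (fast; used for statistical property tests at scale).
`simulateCohort()` synthesizes raw signals: each channel is a sum of seven
band-limited Gaussian noise components (white noise through the same FIR
design used in preprocessing, rescaled to the target variance), sharing the
region's power profile but with independent noise per electrode. Epoch
jitter at the signal level is a piecewise-constant per-band amplitude
envelope over epoch-step-length (2.4 s) blocks, since overlapping epochs
preclude independent per-epoch scaling; periodogram estimation noise adds
on top. A single global seed drives per-participant substreams, so adding
participants never changes existing ones.

What the generator does *not* emulate: 1/f background shape, ocular/EMG
artifacts (beyond what the rejection threshold needs for testing),
inter-electrode correlation within a region beyond the shared power
profile, and non-stationarity within a run. Passing tests on synthetic
cohorts therefore demonstrate correctness of the pipeline's computations
and its statistical behavior under the stated model — not clinical
performance on real EEG.

## Numerical choices

- **Periodogram scaling** satisfies Parseval over band partitions; the
  sinusoid and white-noise calibrations cannot hold simultaneously for a
  single bin, but both hold to stated tolerance when summing a band that
  captures the taper's main lobe.
- **Pairwise distances** are computed by direct differencing rather than
  the expanded-square identity: reciprocal distances amplify cancellation
  error on close epoch pairs, and the double-loop oracle agreement is
  asserted to 12 significant digits.
- **Zero-phase filtering** applies the symmetric FIR twice (response |H|²)
  via FFT convolution with reflection padding, equivalent to
  forward–backward filtering.
- **Exact vs approximate rank-sum**: exact null distribution up to combined
  n = 20 without ties, normal approximation with tie and continuity
  correction otherwise; the branches agree within 0.01 at the cutover.
- **EDF support** is a minimal reader/writer for the fixed-layout 16-bit
  format (one tool-independent cross-check against a Python reader lives in
  the tests); the package's own array format (CSV + YAML sidecar) is
  lossless at 17 significant digits and preferred for fixtures.

## Problem sizes used in the shipped checks

The automated checks run the pipeline at desk scale: parameter-recovery
cohorts of 20 participants per group at the power-vector level (10 seeds
per condition), signal-level cohorts of 4–12 participants with 2–6 channels
and 18–30 s runs, and 20–50-seed Monte-Carlo replicates for test-level
properties. The acceptance script uses 5-seed recovery runs and a 20-seed
null stack. These sizes are the package's choice of a fast, reproducible
default; all generators accept larger cohorts and full 30-channel, 90-s
runs.

## Known limitations

- Reciprocal Euclidean distance on raw powers is dominated by the
  highest-power bands; band-specific effects in low-power bands are best
  probed with the per-band mode (`bandNames = "low_beta"` etc.).
- Global HC standardization leaks benchmark information into LOPO folds
  (see the evaluation caveat above); use `fold-train` for honest error
  estimates.
- The KS normality screen uses estimated parameters without a Lilliefors
  correction, so its p-values are conservative; it documents the choice of
  nonparametric tests and never switches the pipeline automatically.
- Only binary tasks are provided; the three pre-planned pairwise
  comparisons are the supported design.
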