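---
title: "Models and methods behind ferrotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ferrotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ferrotrace)
```

ferrotrace analyses optical-transmission time traces from double-nanohole
(DNH) nanotweezer experiments on single ferritin molecules, and ships a
generator that synthesizes such traces with known ground truth. This
vignette explains the signal model, the estimators, the parameters that
matter and why their defaults are what they are, and what passing tests do
and do not demonstrate about real data.

## The signal model

A synthetic trace is built as

$$T(t) \;=\; T_0\,(1 + \delta\,o(t)) \;+\;
  o(t)\,\bigl[c\,x(t) + A(t)\,\zeta(t)\bigr] \;+\; n(t),$$

where

* $o(t)\in\{0,1\}$ is trap occupancy (0 before trapping and after
  release);
* $\delta$ is the dielectric-loading step contrast $\Delta T/T_0$. Apo
  ships with $\delta = 0.05$ — a free scale choice, since only ratios of
  contrasts are meaningful — and holo with $\delta = 0.0705$, i.e. a 41 %
  excess, matching the reported average contrast between the isoforms.
  The `polarizability()` / `delta_from_polarizability()` pair exposes the
  physics behind that excess: a Clausius–Mossotti sphere with a
  Drude-type conductive core term, linear in the real polarizability;
* $x(t)$ is the trapped particle's overdamped Brownian position in the
  harmonic trap, an Ornstein–Uhlenbeck (OU) process with stiffness
  $\kappa$, Stokes drag $\gamma = 6\pi\eta r$ and stationary variance
  $k_BT/\kappa$, coupled to the detector by a linear responsivity $c$
  (V/m). The OU path is simulated with the *exact* discrete update
  $x_{k+1} = a\,x_k + \xi_k\sqrt{(k_BT/\kappa)(1-a^2)}$,
  $a = e^{-\kappa\Delta t/\gamma}$, so the stationary variance and lag-one
  autocorrelation are correct at any step size — Euler integration would
  carry a step-size bias and could not be tested against the closed
  forms;
* $\zeta(t)$ is unit-RMS conformational noise, a Gaussian process with a
  flat spectrum confined to 3–150 Hz (spectral synthesis). Only the band
  is reported for the real system; the flat shape is a declared
  convention, not an inference;
* $A(t)$ is the conformational envelope: the preset amplitude, times the
  gating-state multiplier (`amp_on` = 1, `amp_off` = 0.25), times an
  exponential mineralization decay
  $e^{-\max(0,\,t-t_\text{load})/\tau_\text{min}}$ with
  $\tau_\text{min} = 600$ s. The paper-scale observation is a fluctuation
  reduction visible ~22 minutes into loading; the exponential form and the
  600 s constant are the package's own choices that make the reduction
  essentially complete by that time. `amp_off` is likewise a free choice:
  the off (folded-channel) state is modelled as retaining a quarter of the
  conformational amplitude, so the off-state window RMS is dominated by
  the hydrodynamic + instrument floor, which is what the reported 5.4 mV
  late-loading level implies;
* gating itself is an alternating Markov renewal process with i.i.d.
  exponential dwells (defaults $\tau_\text{on} = \tau_\text{off} = 3.5$ s,
  the midpoint of the reported 2–5 s range). Exponentiality is a modelling
  assumption of the generator, not a claim about ferritin kinetics;
* $n(t)$ is white instrument noise, 3 mV RMS per sample at 10 kHz.

### Detector scale and calibration

No absolute transmission voltage is reported for the real instrument, so
the package fixes $T_0 = 1$ V and interprets all mV figures at that scale.
Four amplitudes are then *calibrated through the package's own analysis
chain* (1 kHz Gaussian filter, 0.1 s sliding-RMS window, median over the
trapped span), by iterating the amplitude until the chain reports the
target on a long seeded trace:

| constant | value | calibration target |
|---|---|---|
| `position_responsivity` | 131 083 V/m | fluctuation floor (conformational term off) → median sliding RMS 5.4 mV |
| apo `conf_amp_trapped` | 4.217 mV | trapped apo median → 6.8 mV |
| control `conf_amp_trapped` | 13.25 mV | ferric-control pre-exposure median → 14 mV |
| control post/pre factor | 1.0835 | post-exposure median → 15 mV |

The holo conformational amplitude is 0.79 × apo, the ratio of the reported
late/early loading medians (5.4/6.8), which also reproduces the reported
ordering of NRMS and interquartile ranges between the isoforms. The
default sampling rate for shipped experiments is 10 kHz rather than the
instrument's native 1 MHz: it keeps hour-scale traces desk-sized while
leaving the 1 kHz analysis filter far below Nyquist. Note that the
calibration is rate-specific — the OU position noise has a Lorentzian
spectrum whose in-band share grows as the rate drops — so the calibrated
medians are guaranteed only at 10 kHz.

## Preprocessing

`gaussian_lowpass()` convolves with a symmetric (zero-phase) Gaussian
kernel. "Cutoff" is declared to mean the −3 dB point:
$\sigma_f = f_c/\sqrt{\ln 2}$, response $2^{-1/2}$ at $f_c$; edges are
handled by reflection. Zero-phase filtering matters because segment
boundaries must not shift. `decimate_trace()` applies the conventional
Chebyshev-I anti-alias filter at $0.4\,(f_s/\text{factor})$ with
forward–backward filtering, in stages of at most 10× (IIR designs get
numerically fragile at very low normalized cutoffs), with
mirror-padding so start-up transients never touch the data, and the
filter rescaled to exactly unit DC gain (an even-order Chebyshev-I
otherwise sits 0.05 dB low at DC). `mode_normalize()` divides a trace by
the argmax of its Gaussian KDE (Silverman bandwidth, 4096-point grid —
deterministic and shared with `estimate_pdf()`), the normalisation used to
overlay PDFs from different nanostructures.

## Step detection and the ΔT/T₀ estimator

`detect_steps()` is binary segmentation on the cumulative-sum
least-squares statistic with a BIC-like penalty $2\hat\sigma^2\log n$,
$\hat\sigma$ from the MAD of first differences. That noise estimate
assumes roughly independent samples, so `detect_trap_event()` first
decimates to ~200 Hz, where the 3–150 Hz conformational noise is close to
white; detection there is also ~50× cheaper. `characterize_trap()` uses
*medians* for the baseline and trapped levels (robust to the asymmetric
conformational fluctuations), excludes a configurable 0.5 s settling
window after the step, and declares a release when a later change point
returns the level to within 3 pre-trap SDs of the baseline. The ratio
estimator is scale-invariant by construction.

## Fluctuation metrics

* `sliding_rms()`: per-window RMS of per-window mean-subtracted samples
  (0.1 s window, 0.05 s hop by default — ≥ 20 points per 2–5 s dwell).
  The local mean subtraction makes it a fluctuation amplitude, immune to
  steps and drifts.
* `nrms()`: sd/median of the filtered trapped segment. The normalisation
  is what lets fluctuation magnitudes be compared across DNH structures
  with different transmission levels. Populations are built from 1 s
  sub-segments, matching how distributions of NRMS are presented.
* `estimate_pdf()` / `quartile_summary()`: Gaussian KDE (as above) and
  linear-interpolation quartiles.
* `psd_band_fraction()`: Welch estimate (Hann, 50 % overlap, segment
  length the power of two nearest $4/f_{lo}$ seconds) of the in-band
  power over the total above $f_{lo}/2$; the region below $f_{lo}/2$ is
  excluded because window leakage of the residual mean dominates there.
  The Welch estimator is implemented in the package because no installed
  R package provides one.

## On/off segmentation and dwell statistics

`segment_states()` idealizes the log sliding-RMS series into two levels:
exact 1-D two-means (exhaustive split of the sorted values), threshold at
the midpoint of the cluster means, hysteresis band of ±0.25 × the level
separation, and runs shorter than `min_dwell` (0.5 s, well below the
reported 2 s minimum dwell) merged into their neighbours, shortest first.
The higher-RMS cluster is "on", following the interpretation that the
unfolded 3-fold channels fluctuate more. A hidden-Markov alternative was
deliberately left out of scope: the clustering scheme is deterministic and
directly testable against brute-force ground truth.

Whether two states exist at all is decided by the ratio of cluster
separation to pooled within-cluster SD. Exact two-means applied to a
*single* Gaussian level splits it into halves separated by
$1.596\sigma$ with within-half SD $0.603\sigma$ — a ratio of 2.65 — so
any criterion accepting ratios below that would declare every unimodal
series two-state. The package requires the ratio to exceed 3.5; the
calibrated gating levels give ≈ 4–5, a constant-amplitude control ≈ 2.7.
This margin also absorbs the ferric-control case, where a small (14 →
15 mV) exposure step exists but involves so few pre-exposure windows that
the split stays noise-dominated. Segmentation is run on the trapped span
only: baseline windows sit far below any trapped level and would
otherwise register as a spurious state.

`dwell_statistics()` drops the first and last segments (censored — their
true start or end was not observed, standard renewal-process practice) and
reports arithmetic means, the exponential-model MLE. Two biases are worth
knowing about: dwells shorter than `min_dwell` are unresolvable and each
missed one concatenates its two neighbours (for exponential dwells with a
3.5 s mean, ~13 % fall under 0.5 s, inflating recovered means by roughly
+0.6 s), and window smearing (~one window width per boundary) shaves the
apparent run length of short dwells. On a 120 s trace only ~10 uncensored
dwells per state survive, so recovered means carry ~±1 s sampling scatter
on top of the bias. `mineralization_trend()` and `control_check()` report
interval medians of the sliding RMS, which are insensitive to both
effects.

## Population comparison and classification

`permutation_test()` tests the difference of group means, exhaustively
enumerating all assignments when their number fits the permutation budget
(always the case for the invariant-checked n ≤ 10) and sampling seeded
random reassignments otherwise, with the add-one estimate
$(1 + \#\text{extreme})/(B+1)$. A permutation test was chosen over a
t-test because per-segment NRMS populations are visibly non-Gaussian and
only significance bounds are reported for the real data; the
difference-of-means statistic keeps the result interpretable.
`classify_isoform()` applies the two-feature rule (holo ⇔ NRMS below
threshold *and* ratio above threshold), with default thresholds at the
midpoints of the preset population means (NRMS 0.0063, ratio 0.06025) and
ties mapping to "undetermined".

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on generated data at
10 kHz: twenty 60 s paired traces for the step-contrast comparison, one
~24 min loading trace for the mineralization medians, one 120 s gating
trace for dwell recovery, 50 + 50 one-second segments (100 000
permutations) for the NRMS test, and one ~21 min ferric-control trace.
These sizes were chosen so each check completes in roughly a minute on a
single core while leaving the estimators' sampling error well inside the
tolerances being asserted.

## What the synthetic tests do and do not show

The generator reproduces the *statistical structure the analysis assumes*:
a step with band-limited, state-modulated Gaussian fluctuations on an OU
baseline. Passing tests therefore demonstrate that the estimators recover
known ground truth under that model — they do not validate the model
against real ferritin data. Known idealisations: flat in-band
conformational spectrum; exponential dwells (other proteins/structures
reportedly show ~20 s dwells, and the true dwell distribution is
unestablished); a single exponential mineralization time constant; no
laser-heating drift, no fluidic artefacts, no multi-protein co-trapping
(events are assumed single-occupancy); and an instrument-free absolute
scale ($T_0 = 1$ V convention). File I/O is plain CSV with a JSON
metadata sidecar; 64-bit binary containers are intentionally not required
by any part of the chain.
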