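---
title: "Methods: prosodic and electroglottographic modelling of perceptual voice quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prosodic and electroglottographic modelling of perceptual voice quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voqual)
```

## Overview

`voqual` models perceptual Roughness–Breathiness–Hoarseness (RBH) ratings
of connected speech from two independent measurement systems: a prosodic
analysis of the acoustic channel and cycle-irregularity measures from an
electroglottographic (EGG) channel. This vignette documents the method in
enough detail to reproduce or audit every step: the signal processing, the
feature definitions, the statistical layer, the numerical choices, and the
places where the design was genuinely open and a decision had to be made.

The pipeline is:

1. condition the speech channel (resample to 16 kHz);
2. frame-level analysis: energy, voiced/unvoiced decision, F0;
3. 33 word-level and 15 global prosodic features, averaged into one
   48-dimensional vector per recording;
4. EGG cycle detection and the irregularity summaries CFx and CQx;
5. per criterion: correlation-based feature selection in cross-validation,
   a linear ε-SVR trained by sequential minimal optimization, and
   evaluation against the item-averaged ratings;
6. interrater-agreement statistics for the rating panel.

## Signal conditioning and frame analysis

Speech is analysed at exactly 16 kHz; input at other rates is resampled
with `signal::resample` (polyphase, anti-aliased; a 440 Hz tone survives
resampling from 44.1 kHz with < 1 Hz peak error, tested). Amplitudes are
floating point in [−1, 1] regardless of source bit depth. Times are
seconds, 0-based; intervals are half-open `[start, end)`.

Frames are 16 ms long with a 10 ms shift (256/160 samples). The frame
shift is not dictated by the framing convention itself; 10 ms is the
common default in prosodic analysis and is exposed in `voq_config()`.
Per-frame short-time RMS energy is the energy measure everywhere.

**Voiced/unvoiced decision.** A frame is voiced iff (a) the maximum of its
normalized cross-correlation over candidate F0 lags reaches `v_thresh`
(default 0.45) and (b) its energy reaches `e_thresh` (default 0.1) times
the recording's *median* frame energy. Both thresholds are dimensionless;
the energy gate is relative, so voicing is invariant under overall gain
(tested as a property). The defaults were chosen once on the synthetic
generator's output — periodic pulse trains must come out voiced, white
noise and silence unvoiced — and are configurable.

**F0 estimation.** The search range is 50–500 Hz, wide enough for
pathological adult voices of either sex. Per voiced frame the normalized
cross-correlation is evaluated on all integer lags in the range, with the
window contents compared against their lag-shifted continuation. A
perfectly periodic frame correlates equally well at every integer multiple
of its period, so "take the global maximum" systematically halves or
thirds F0; instead the estimator takes the *shortest lag among local
maxima within 93% of the global maximum* (exact ties break toward the
longer lag). The winning lag is refined by parabolic interpolation of the
correlation around the peak, clamped to ±0.5 lag.

Two octave-control passes follow inside each voiced run: (1) a frame whose
F0 lies within 4% (relative) of 2×, 3×, ½× or ⅓× of the consensus of both
neighbours is folded back to the consensus octave — by construction the
only possible changes are factors {1/3, 1/2, 2, 3}, which the test suite
asserts on randomized contours; (2) a running median of window 5 smooths
residual spikes. On a synthetic 120→180 Hz linear ramp the per-frame error
stays below 5% (measured: < 1%).

**Sections.** Maximal runs of constant voicing flag form the
voiced/unvoiced section list; lengths are frames × shift. The run-length
encoding is tested against an independent oracle on random flag sequences.

## Word-level features (33)

Features are computed per word of the alignment, in two contexts: the
current word (W) and the word-pause-word interval (WPW) spanning the two
words *preceding* the current word together with the pause between them.
For the first two words of a recording no WPW context exists; their WPW
features are imputed with the recording mean of that feature so the design
matrix stays complete.

Definitions and conventions, where the underlying literature leaves the
normalization open (each such choice is a declared stand-in, made once):

* **Pauses** — `PauseBefore`/`PauseAfter` are the silent parts of the gaps
  to the neighbouring words; `PauseFill*` is time occupied by
  filler-labelled alignment entries (default filler set
  {"äh", "ähm", "hm"}, configurable). Fillers are not feature words
  themselves. Words at the recording edges get 0 (no pause is attributable
  to a missing neighbour).
* **Energy** — regression slope and mean squared residual of the RMS
  contour over time; `EnAbs` = sum of frame energies; `EnMean` = mean;
  `EnNorm` = `EnMean` divided by the recording's mean frame energy
  (removes gain dependence); `EnMax` and its relative position.
* **Duration** — `DurAbs` = interval length; `DurNorm` = `DurAbs` /
  (character count × recording-level mean duration per character).
  Intrinsic word-duration norms would need a lexicon; character count is
  the declared proxy.
* **F0** — all F0 features are computed on the semitone scale relative to
  the recording's median voiced F0 (`12·log2(f0/median)`), making them
  speaker-register-free: regression slope and residual, mean, max/min,
  onset/offset values (first/last voiced frame in the word) and the
  relative positions of all four, clipped to [0, 1].

A word without voiced frames gets missing-coded F0 features, which the
aggregation skips.

## Global features (15)

Words are grouped into consecutive windows of 15; a trailing remainder of
at least 8 words forms its own window, a smaller one merges into the
previous window (a recording with fewer than 15 words is one window).
Whether such windows should overlap and how a partial window is handled
was not constrained by prior art; non-overlapping windows with the 8-word
rule is the package's choice.

**Jitter and shimmer** are computed pitch-synchronously per voiced
section: waveform peaks are located cycle by cycle, seeded by the frame F0
and steered by the running median of the last 5 measured periods (the
frame contour alone is too noisy right at voiced-run edges), with
parabolic refinement of peak position and height; the first two and last
cycles of each section are dropped as onset/offset transients. For the
period sequence T and peak-amplitude sequence A of one section

    jitter  = mean|T_{i+1} − T_i| / mean(T)
    shimmer = mean|A_{i+1} − A_i| / mean(A)

(the *local* relative forms). `MeanJitter`/`StandDevJitter` (in percent)
are the mean/sd over the sections of a window, likewise for shimmer. The
terms jitter and shimmer cover many algorithmic variants in the
literature; this one is fixed, documented, and validated by parameter
recovery: injected perturbations of 2–3% are recovered within ±20%
relative, zero perturbation measures as exactly zero, and estimates are
monotone in the injected level across {0, 1, 2, 4}% (all tested).

**Section statistics** restrict the voiced/unvoiced section list to the
window's time span: counts (`NumVoiced`, `NumUnvoiced`), max and mean
lengths, the count ratio `RelNumVoicedUnvoiced`, the length shares
`RelLenVoicedSignal`/`RelLenUnvoicedSignal` of the window, and the length
ratio `RelLenVoicedUnvoiced`. `StandDevF0` is the standard deviation of
the semitone contour over voiced frames. An enumeration of "means and
standard deviations of jitter and shimmer, section counts, lengths and
ratios" yields 14 natural names; the fifteenth implemented feature is the
voiced/unvoiced *length* ratio, and "length" is realized as both mean and
maximum per section type. This disambiguation is the package's own; the
canonical name registry (`global_feature_names()`) freezes it.

Recording-level aggregation is the mean over words/windows per feature,
skipping missing-coded entries.

## EGG measures

Cycle detection works on the differentiated EGG (dEGG): closure instants
are positive dEGG peaks above an adaptive threshold — 0.3 × the rolling
95th percentile of the positive dEGG (1 s window, 0.25 s hop) — with a
minimum separation of 1/500 s and parabolic sub-sample refinement. Cycles
whose implied Fx leaves 50–500 Hz are discarded; the analysis is
period-synchronous and uses full cycles only, so partial cycles at signal
edges vanish (prepending/appending 100 ms of silence moves CFx/CQx by
< 0.1, tested).

Per cycle, the contact quotient Qx normalizes the EGG between the cycle's
min and max and measures the time spent above the contact level 0.3
(a common contact-quotient convention; configurable) as a percentage of
the period. The summaries are

    CFx = 100 · mean|Fx_{i+1} − Fx_i| / mean(Fx)   [percent]
    CQx = mean|Qx_{i+1} − Qx_i|                    [percentage points]

The vendor's exact definitions behind the commercial CFx/CQx displays are
proprietary; the mean-absolute successive-difference form above matches
their verbal description (cycle-to-cycle variation, given in percent) and
is fully testable: CFx is amplitude-invariant, exactly zero for constant
periods, strictly increasing over injected perturbation levels
{0, 1, 2, 5}%, and recovers a 2% injected perturbation within [1.6, 2.4]
over ≥ 200 cycles (all tested). Whether the commercial quantity is instead
a distribution-width statistic cannot be settled from published
descriptions; this is a known representational caveat, not an
implementation uncertainty.

## Statistical layer

**Krippendorff's α** uses the coincidence-matrix formulation: every item
with m ≥ 2 ratings contributes its ordered rating pairs with weight
1/(m−1); α = 1 − D_o/D_e with the interval metric (squared score
difference) by default and the ordinal (cumulative-margin) metric by flag.
Ratings are treated numerically on the 0–3 scale because item averages are
used as the modelling reference elsewhere; the metric used in prior
studies is typically unreported, so interval is the default, not a claim.
The implementation is verified against a brute-force pairwise-enumeration
oracle to 10⁻¹² on hundreds of random panels, including missing cells.

**Correlations.** Pearson and Spearman (mid-ranks) with two-sided
p-values: t approximation for n ≥ 10, exact permutation for n < 10.
Rater-versus-rest correlates each rater with the item-wise mean of the
others and averages; zero-variance raters are skipped with a warning.

**CFS.** Subset merit `M_S = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with
absolute Pearson correlations; best-first forward search with a stall
limit of 5 non-improving expansions, verified against exhaustive
enumeration on 8-feature problems. Selection runs per fold of a seeded
10-fold cross-validation (shuffled contiguous blocks); features are
ranked by cross-fold selection frequency (ties: mean merit, then name),
and those with frequency ≥ 0.5 (at least one) enter the regression.
"Rank" is thus realized as selection frequency — the natural frequentist
reading of fold-wise subset selection.

**SVR.** Linear ε-SVR on standardized (zero mean, unit variance)
features, trained by an SMO solver on the 2n-variable dual with
maximal-violating-pair working-set selection; convergence when the KKT
violation gap falls below `tol` (default 10⁻³; the oracle tests use
10⁻⁶). Defaults C = 1, ε = 0.001; none of these hyperparameters carry
empirical claims and all are exposed. The returned optimum matches a
generic QP solver (`kernlab::ipop`) on the identical standardized dual to
10⁻⁴ in objective (tested on random problems, n ≤ 30, p ≤ 5). Degenerate
fits are exact: a constant target yields zero weights and the constant as
intercept.

**Presets.** The published weight sets for the best R/B/H models ship as
a JSON resource, interpreted as standardized-space weights (the training
tool behind them normalizes inputs by default). Their intercepts were
never published, so preset predictions are *relative* scores — valid for
correlation-based evaluation, not for absolute 0–3 prediction. This is a
documented limitation, not recoverable from the published material.

**Evaluation.** Model outputs are compared against item-averaged ratings
(mean over available raters per item) with Pearson r and Spearman ρ. The
study runner accepts either a full rater panel or an already-averaged
continuous reference table; the latter is what a noiseless validation
target requires, since integer 0–3 panels cannot represent one.

## Synthetic study conditions

The generators are pure functions of their specs (seed included) and
produce bit-identical output for equal seeds.

* `synth_voice`: glottal pulse train with per-period multiplicative
  Gaussian perturbation of period (sd = jitter%) and amplitude
  (sd = shimmer%), sub-sample impulse placement, filtered by a fixed
  two-formant resonator (500/1500 Hz, bandwidths 80/120 Hz — enough
  spectral realism for the voicing logic without a full synthesizer);
  pauses carry noise 30 dB below the voiced RMS by default. Gaussian
  multiplicative perturbation makes the expected measurement analytic:
  the mean absolute successive difference of an i.i.d. perturbed series
  is √2·√(2/π) ≈ 1.13 × the injected sd, which the recovery tolerances
  accommodate.
* `synth_egg`: per cycle a smoothed rectangular contact pulse (raised-
  cosine edges, 5% of the period each) occupying the contact quotient's
  share of the period; period and per-cycle quotient perturbed per spec.
* `synth_panel`: rating = clamp(round(true + N(0, sd))) per rater and
  criterion.
* `synth_feature_table`: standard-normal features, target = weighted sum
  + noise.

What passing the recovery tests shows — and what it does not: the
generators emulate periodicity, amplitude structure, pauses, contact
dynamics and rater noise, but not vocal-tract articulation, aperiodic
(breathy) noise excitation, diplophonia, or the acoustic diversity of real
pathological voices. Green parameter-recovery tests therefore validate the
*measurement chain*, not clinical performance. The published clinical
correlations (human–machine r ≈ 0.7 for roughness on a 58-speaker panel
study) depend on an undeposited clinical dataset and are deliberately not
reproduced or asserted here.

Problem sizes in the shipped tests and acceptance script — single
recordings of 5–16 words, EGG stretches of ~300 cycles, studies of 12 and
30 synthetic recordings with 6–8 simulated raters — were chosen as the
smallest sizes at which the statistical checks are stable (e.g. ≥ 200
cycles for CFx recovery, ≥ 30 items for selection stability).

## Numerical choices and degenerate inputs

* Regression on fewer than two distinct points yields slope 0, mse 0
  (a flat contour is genuinely flat, not missing).
* Position features clip to [0, 1]; argmax-based positions are inherently
  tie-unstable on flat contours and are treated as such in the tests.
* `RelNumVoicedUnvoiced` and `RelLenVoicedUnvoiced` guard the denominator
  with one section/frame-shift to stay finite in all-voiced windows.
* Signals shorter than one frame, empty word lists, overlapping
  intervals, out-of-range ratings, < 2 EGG cycles, constant correlation
  inputs and missing feature columns all raise classed conditions
  (`voq_*_error`, `voq_undefined`, `voq_empty_*`) rather than NA
  propagation.
* All report writers format numbers deterministically; identical studies
  produce byte-identical report directories (tested).

## Known limitations

* The word alignment is an *input*; no speech recognizer or forced
  aligner is included.
* DurNorm/EnNorm/F0 normalizations are declared proxies for prior-art
  normalizations whose exact definitions are not public.
* Preset models lack intercepts (not published) and give relative scores.
* Jitter/shimmer estimates assume the waveform peak structure of voiced
  speech; heavily aperiodic signals yield few valid sections and
  missing-coded values rather than numbers.
* The EGG channel is analysed independently of the speech channel; no
  cross-channel fusion or inverse filtering.
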