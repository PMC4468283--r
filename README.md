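# voqual — automatic voice-quality assessment from connected speech

Perceptual grading of pathological voices — in German-speaking clinics the
RBH scheme: **R**oughness, **B**reathiness, **H**oarseness, each scored 0–3
by listeners — is the clinical gold standard but suffers from poor intra-
and interrater reliability. `voqual` implements an objective counterpart
for *connected speech* (a read standard text, not sustained vowels): it
extracts prosodic and electroglottographic measurements from a recording
and models the averaged listener ratings with a linear support-vector
regression, so that a single automatic score can support, and be compared
against, a rater panel.

The package is aimed at voice/speech researchers and clinical phoneticians
who have speech recordings with word-level time alignments (Praat TextGrid
or CTM), optionally a synchronous electroglottographic (EGG) channel, and
perceptual rating tables.

## What it computes

**Prosodic features.** The speech channel is analysed at 16 kHz in 16 ms
frames (10 ms shift). After a voiced/unvoiced decision (normalized
autocorrelation peak + relative energy gate) and F0 estimation with octave-
error control, the package computes

* 33 **word-level features** per word — silent/filled pause durations;
  energy regression slope, residual, mean, max and positions; absolute and
  normalized duration; F0 regression, extremes, onset/offset values and
  positions — each in the current-word (W) and, where defined, the
  word-pause-word (WPW) context;
* 15 **global features** per 15-word window — means and standard
  deviations of jitter and shimmer (pitch-synchronous, per voiced
  section), counts, lengths and ratios of voiced/unvoiced sections, and
  the F0 standard deviation in semitones.

The per-recording feature vector is the average over words and windows
(48 values).

**EGG measures.** From the electroglottogram the package detects vocal-fold
cycles on the differentiated signal and computes, per cycle, the period
frequency Fx and the contact quotient Qx (closed phase / period). Their
cycle-to-cycle irregularities are summarized as

    CFx = 100 · mean|Fx_{i+1} − Fx_i| / mean(Fx)      (percent)
    CQx = mean|Qx_{i+1} − Qx_i|                       (percentage points)

**Modelling.** Per criterion, features are selected by correlation-based
feature selection (CFS; subset merit
`k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)`, best-first search) in 10-fold
cross-validation, and a linear ε-SVR is trained by sequential minimal
optimization on standardized features. Model outputs are compared to the
item-averaged ratings with Pearson's r and Spearman's ρ. The published
weight sets for the best R/B/H models (including the CFx/CQx-only
variants) ship as presets.

**Agreement statistics.** Krippendorff's α (coincidence matrix, interval
or ordinal metric, missing ratings supported), rater-versus-rest
correlations, and panel summary/cross-correlation tables.

**Synthetic generators.** Seeded, bit-reproducible generators for
speech-like pulse-train audio (controllable F0 contour, jitter, shimmer,
pauses), EGG signals (controllable contact quotient and cycle
perturbation), rating panels and feature tables provide ground truth for
the test-suite's parameter-recovery checks.

## Worked example

A synthetic 12-recording study across a severity gradient (increasing
jitter, shimmer and EGG cycle perturbation), rated by 8 simulated
listeners:

```r
library(voqual)

manifest <- lapply(1:12, function(i) {
  sev <- (i - 1) / 11
  sv <- synth_voice(f0 = 100 + 8 * i,
                    word_plan = default_word_plan(6, 0.3, 0.1),
                    jitter_pct = 3 * sev, shimmer_pct = 8 * sev,
                    seed = 100 + i, id = sprintf("rec%02d", i))
  egg <- synth_egg(f0 = 100 + 8 * i, contact_quotient_pct = 45 + 10 * sev,
                   cycle_perturb_pct = 4 * sev, duration_s = 2,
                   seed = 200 + i)
  sv$recording$egg <- as.numeric(egg)
  sv$recording$egg_rate <- attr(egg, "sample_rate")
  list(id = sv$recording$id, recording = sv$recording,
       alignment = sv$alignment)
})
severity <- seq(0, 2.5, length.out = 12)
panel <- synth_panel(severity, n_raters = 8, rater_noise_sd = 0.5, seed = 42)
rownames(panel) <- sapply(manifest, function(m) m$id)

study <- run_study(manifest, panel, config = voq_config(cfs_folds = 6), seed = 7)
print(study)
```

```
Voice-quality study: 12 recordings
  R: r = 0.987 (p = 2.67e-09), rho = 0.974; features: CFx, CQx
  B: r = 0.985 (p = 5.96e-09), rho = 0.988; features: CFx
  H: r = 0.988 (p = 2.32e-09), rho = 0.995; features: CFx, MeanJitter, CQx
Interrater alpha: R = 0.64, B = 0.64, H = 0.72
```

The selection picks the irregularity measures that actually drive the
simulated severity (CFx, CQx, MeanJitter), and the fitted scores correlate
with the averaged panel ratings at r ≈ 0.99; the simulated panel's own
agreement (α ≈ 0.6–0.7) reflects the injected rater noise. A single
recording can be analysed directly:

```r
res <- analyze_recording(manifest[[12]]$recording, manifest[[12]]$alignment)
round(res$features[c("MeanJitter", "MeanShimmer", "CFx", "CQx", "NumVoiced")], 3)
#>  MeanJitter MeanShimmer         CFx         CQx   NumVoiced
#>       3.974      12.957       4.264       0.617       6.000
```

`write_study_report(study, "report_dir")` writes the feature table, the
agreement report, the per-criterion models and the feature-correlation
matrix (Pearson r upper triangle, Spearman ρ lower) as deterministic
plain-text files. A thin command-line front end with `analyze`, `study`,
`synth` and `agreement` subcommands is installed at
`system.file("cli", "voqual", package = "voqual")`.

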