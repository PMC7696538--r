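---
title: "Hippocampal LFP analysis around low-frequency amygdala stimulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal LFP analysis around low-frequency amygdala stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Low-frequency deep brain stimulation (DBS) of the amygdala is a candidate
therapy for temporal-lobe epilepsy. In the rodent chronic-epilepsy setting
its electrophysiological footprint on the hippocampus is quantified through
three markers derived from the local field potential (LFP):

1. the rate of **interictal epileptiform discharges** (IEDs: spikes,
   polyspikes, sharp waves), counted on both hippocampi and averaged;
2. **relative theta power** (4–12 Hz as a fraction of 1–600 Hz), compared
   between the 30 s immediately before the first and after the last
   stimulation train;
3. **phase-amplitude coupling (PAC)** between the delta phase (1–4 Hz) and
   the amplitude of four fast bands — gamma 30–100, HFO 100–150, ripple
   150–250, fast ripple 250–600 Hz — estimated with a time-resolved method
   (tPAC) and summarized by the MaxPAC of each 5-min epoch.

These markers are then linked, across animals, to the behavioral seizure
outcome (rate and duration before vs during the 10-day stimulation period).
`lfpac` implements the full chain — session model, epoching, detection,
spectra, coupling, statistics — plus a ground-truth-annotated synthetic
generator so that every stage is testable without animal recordings.

## Session and epoch model

A daily session follows the stimulation protocol: recording starts
`pre_s` (300 s) before the first train; `n_trains` (4) trains of `train_s`
(50 s) at 4 Hz are separated by `pause_s` (300 s) pauses; recording ends
`post_s` (300 s) after the last train — 1700 s in total. Epochs are derived
purely from the schedule:

* `pre5` — `[first onset − pre_s, first onset)`, `post5` — `[last offset,
  last offset + post_s)`;
* `pre30` / `post30` — the 30-s windows flanking the train block;
* `train_k` — the train intervals themselves, excluded from every analysis.

Intervals are half-open `[start, end)` with sample index `floor(t * fs)`,
which makes adjacent epochs concatenate without overlap. Sessions without a
schedule (SHAM animals) receive first/last windows of the same nominal
length. The acquisition hardware's filter chain is carried as metadata only
and never applied; the corner frequencies printed for the recording chain
are internally inconsistent (a 0.16 Hz "low-pass" against an 8 kHz
"high-pass" is almost certainly transposed), which is a further reason to
treat traces as analysis-ready rather than to emulate the chain.

On-disk format is plain EDF (16-bit, µV) with a JSON sidecar for metadata
and schedule; a float64 raw format is provided where 16-bit quantization
would matter (bit-exact fixtures).

## IED detection

The published criterion — amplitude above 2 SD of background — was applied
by a human scorer; alone it fires constantly on noise. The automated
detector keeps the printed threshold as the amplitude floor and adds two
morphology gates, all stated explicitly:

* **Background SD** is `1.4826 × MAD` of the demeaned trace, computed on the
  full epoch *including* events: the MAD is insensitive to sparse large
  transients, so no circular event-masking pass is needed. Baseline-to-peak
  amplitude is used (the printed criterion does not say which convention;
  this is flagged as a convention, not an inference).
* **Detection signal**: the trace band-passed to 2.5–80 Hz. Events of
  20–200 ms live in roughly this range; removing slower content stabilizes
  the baseline under delta rhythm and 1/f drift (otherwise the duration
  measurement fails on displaced baselines), and the 80 Hz top acts as the
  smoothing stage.
* **Gates**: principal-deflection duration 20–200 ms (width between the
  baseline crossings flanking the peak); the supra-threshold run must last
  ≥ 10 ms (rejects grazing threshold crossings, which is where nearly all
  noise false positives live); and sharpness — the largest amplitude change
  over a lag of a quarter of the measured duration — must exceed 3× the
  background SD of same-lag changes. Measuring sharpness at a lag matched
  to the event's own time scale is what lets a single rule accept both a
  25-ms spike and a 180-ms sharp wave; at the raw sampling interval no
  physiological transient outruns broadband noise differences.
* **Counting**: peaks closer than 500 ms merge into one event (a polyspike
  is one discharge, not 2–4), and events whose peak falls inside a
  stimulation train are dropped. Subtypes follow conventional durations —
  spike 20–70 ms, sharp wave 70–200 ms, polyspike ≥ 2 same-sign
  supra-threshold deflections within 500 ms (sign-matching avoids counting
  the band-pass rebound of a wide wave as a second deflection).
  Out-of-range durations are `unclassified`: excluded from subtype
  proportions, still counted in total rates.

`k = 2` remains configurable. Left/right rates are averaged
(`bilateral_mean_rate`) and the asymmetry is expressed as
`(L − R) / (L + R)`, zero by convention when no events occur.

## Spectral analysis

`compute_psd()` is a Welch averaged periodogram: 10-s windows, 50% overlap,
Hann taper, per-window demeaning, one-sided scaling that satisfies Parseval
(the published analysis names only FFT, window length and overlap; taper
and averaging are conventions here). Band powers integrate the PSD over
half-open bands, the shared 4 Hz edge belonging to theta so assignment is
deterministic. Relative power divides by the total over [1, 600) Hz — the
union support of the named bands — since no denominator is published; this
makes the four bands near-exhaustive while excluding DC and line-frequency
remnants, and renders relative powers invariant under amplitude scaling.
`theta_change()` reports `100 × (post − pre)/pre` per side and for the
left/right mean.

## Time-resolved PAC

For each sliding window (18 s, 50% overlap — 18 delta cycles at the 1 Hz
edge; a 300-s epoch yields 32 windows):

1. band-pass to the fA band; the **dominant fast frequency** is the peak of
   the band-limited power spectrum of the window;
2. band-pass around that frequency with bandwidth `2 × fP_high` (retaining
   the modulation sidebands) and take the Hilbert envelope `A(t)`;
3. band-pass to the delta band and take the instantaneous phase `φ(t)`;
4. the coupling is the normalized mean vector
   `|⟨A e^{iφ}⟩| / sqrt(⟨A²⟩)` — unitless, in [0, 1], exactly invariant
   under amplitude scaling; its argument is the preferred phase.

Band-pass filtering is done in the frequency domain with raised-cosine
transition edges. This is exactly zero-phase (no phase bias between the
slow and fast components, which would bias the preferred phase) and gives
precise band control at `O(n log n)`; an FIR with a 1-Hz transition band at
5 kHz sampling would need thousands of taps for the same response. Two
seconds are trimmed from each end of every window's envelope and phase
before averaging, absorbing Hilbert/filter edge artifacts at delta
frequencies.

**MaxPAC** is defined as the maximum over the fA grid of the across-window
mean coupling, ties broken toward the lowest frequency. Whether the
published "maximum PAC" is this or the mean of per-window peaks is not
documented; the adopted definition is deterministic and reduces to the
plain across-window mean when the dominant frequency is stable.

Two independent controls accompany the estimator:

* `tort_mi()` — the Kullback–Leibler modulation index (phase-binned mean
  envelope against uniformity, normalized to [0, 1]) as a cross-validation
  oracle: over a modulation-depth sweep the two measures must agree in rank.
* `surrogate_threshold()` — circular shifts of the envelope against the
  phase by at least one slow cycle; the observed coupling is compared with
  the `1 − α` surrogate quantile. The published analysis reports raw
  coupling without surrogate control, so surrogates are an extension, off
  the main path.

A practical calibration note: the mean-vector statistic has a positive
small-sample bias (a random-walk resultant), so couplings measured on
finite windows have a noise floor — about 0.03 on 60-s epochs with
realistic background. Modulation depths whose true coupling sits below this
floor are indistinguishable from zero by magnitude alone; the surrogate
threshold is the instrument for that regime.

## Study-level statistics

Percent changes are `100 × (before − after)/before`; seizure-rate change is
`rate_before − rate_dbs` so positive values mean improvement, matching the
outcome-axis convention of the study design. Group contrasts use paired t,
Welch t (unequal group sizes; pooled variance available) or one-way ANOVA;
identical paired samples return `t = 0, p = 1` rather than an error. Pearson
correlations populate the epoch × side × band grid against the seizure-rate
change. No multiplicity correction is applied across bands or sides —
matching the per-band reporting of the study — and none is silently added.

## The synthetic generator

`synthetic_spec()` describes one session: 1/f^β background synthesized in
the frequency domain (direct spectral control, β defaults to 1), a delta
rhythm whose instantaneous frequency drifts as an Ornstein–Uhlenbeck
process (SD 0.3 Hz, 2 s correlation time), fast carriers amplitude-modulated
by the delta phase with the normalized envelope
`(1 + κ cos φ)/(1 + κ)` (peak amplitude independent of κ, isolating
coupling strength from power), a theta sinusoid, and injected discharges
with half-sine morphology (spike 20–70 ms, sharp wave 70–200 ms, polyspike
bursts of 2–4 deflections within 500 ms counted once), at Poisson times
with a short refractory spacing so every injected event remains
individually countable, with amplitude parameterized in background-SD units
(default 6) so detector tests are SNR-controlled.

The delta-phase drift deserves emphasis: with a strictly sinusoidal delta,
a circular shift of a modulated envelope merely *rotates* the coupling
vector without shrinking it, so surrogate control would be impossible by
construction. In vivo delta is narrowband, not periodic; the drift models
that and restores the surrogate logic.

Defaults are the emulated study condition, chosen once: background
50 µV RMS, delta 2.5 Hz / 60 µV, theta 7 Hz / 38 µV (relative theta near
26%), one gamma carrier at 80 Hz / 8 µV with κ = 0.25 — weak modulation of
a prominent fast rhythm, which is the regime whose measured MaxPAC falls in
the 10⁻² decade — total discharge rate 3.61/min split ≈ 72/11/17% across
spikes/polyspikes/sharp waves, and post-train multipliers ×1.11 on theta
amplitude (≈ +17% relative theta) and ×0.8 on κ. The cohort generator
defaults to 10 animals, baseline 1 seizure/day, rate multiplier 0.77
(a 23% decrease), durations lognormal with mean 60.84 s falling by ×0.734,
and a negative latent PAC–outcome slope; `generate_cohort_sessions()`
scales each animal's κ by its latent PAC level so the *measured* coupling
inherits the cohort's PAC–outcome link.

What the generator does **not** emulate: ictal waveforms, stimulation
artifacts, non-stationary background beyond the imposed step changes,
inter-channel volume conduction, electrode drift, and the acquisition
filter chain. Passing tests therefore demonstrate correctness of the
analysis chain under the stated generative assumptions, not performance on
arbitrary in-vivo data.

## Numerical choices and degenerate inputs

* Robust scale is `1.4826 × MAD` throughout; a constant trace yields SD 0
  with a warning and no detections.
* Ties in MaxPAC go to the lowest frequency; the 4 Hz band edge belongs to
  theta; intervals are half-open everywhere.
* Zero pre-stimulation theta makes the percent change undefined (error,
  not `Inf`); zero-variance inputs make correlations undefined (error).
* `percent_change` requires a positive baseline; lateralization of two
  silent channels is 0 by convention.
* All generators are deterministic given their seed, restore the caller's
  RNG state, and derive per-channel sub-seeds so channels are independent
  but reproducible.

## Problem sizes used by the test-suite and acceptance script

The in-vivo protocol (1700 s at 5 kHz) is larger than unit tests need. The
suite exercises the identical code paths on scaled-down sessions — tens of
seconds to ~10 min at 1–2 kHz sampling, keeping the Nyquist frequency above
the 600 Hz fast-ripple edge wherever the full band set is analyzed — with
reduced schedules (2 × 10 s trains, 60–90 s windows). Detector performance
is measured on 10-min traces; statistical calibration uses 1000 simulated
null replicates; the end-to-end cohort uses 10 animals at 170 s per
session. These sizes are the package's chosen test conditions; nothing in
the implementation depends on them.

## Known limitations

* The detector's subtype boundary at 70 ms smears under band-pass
  distortion for events near the boundary; proportions are reported over
  classified events only.
* MaxPAC from few windows is positively biased for bands with no true
  coupling (maximum over noisy cell means); pre/post contrasts are
  unaffected because the bias is common to both epochs, but absolute
  values for uncoupled bands should be read with the surrogate threshold.
* The EDF writer targets the subset of EDF this pipeline needs (equal
  sampling rates, one session per file); it is not a general-purpose EDF
  implementation.
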