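# lfpac

Analysis of hippocampal local field potentials (LFP) recorded around
low-frequency deep brain stimulation (DBS) of the amygdala in rodent models
of temporal-lobe epilepsy.

Chronic epilepsy leaves three measurable footprints in the hippocampal LFP,
and all three respond to amygdala low-frequency stimulation: the rate of
interictal epileptiform discharges (IEDs — spikes, polyspikes, sharp
waves), the relative theta power (4–12 Hz), and the phase-amplitude
coupling (PAC) between the delta phase and fast oscillations. `lfpac`
implements the complete quantitative chain linking these markers to seizure
outcome:

* **Session model** — the daily stimulation protocol (trains, pauses,
  pre/post recording windows) and the analysis epochs derived from it;
  minimal EDF (16-bit, µV) reading/writing plus a bit-exact raw format.
* **IED detection** — automated version of the "amplitude > k·SD of
  background" criterion (robust MAD scale, default k = 2) with duration
  (20–200 ms) and sharpness gates, 500-ms merge so a polyspike counts once,
  subtype classification, bilateral rate averaging and a lateralization
  index `(L−R)/(L+R)`.
* **Spectral power** — Welch PSD (10-s windows, 50% overlap, Hann),
  band powers over delta 1–4, theta 4–12, beta 15–30 and gamma–fast-ripple
  30–600 Hz, relative power against the [1, 600) Hz total, and the
  pre/post-stimulation 30-s theta comparison.
* **Time-resolved PAC (tPAC)** — per 18-s window: dominant fast frequency
  from the band-limited spectrum, Hilbert envelope around it, delta phase,
  and the normalized mean-vector coupling

  `PAC = |⟨A(t) e^{iφ(t)}⟩| / √⟨A(t)²⟩ ∈ [0, 1]`

  over four fA bands (gamma 30–100, HFO 100–150, ripple 150–250, fast
  ripple 250–600 Hz), with MaxPAC per epoch, comodulograms, a
  Kullback–Leibler modulation-index oracle and circular-shift surrogate
  thresholds.
* **Study statistics** — percent changes, paired/unpaired/ANOVA contrasts,
  PAC–outcome correlation grids, day-course summaries, and a per-animal
  outcome table joining seizure logs with the electrophysiological
  predictors.
* **Synthetic data** — a ground-truth-annotated generator (1/f background,
  drifting delta, κ-controlled cross-frequency coupling, injected IEDs,
  cohort seizure logs with an imposed PAC–outcome link) so the whole
  pipeline is testable end to end without animal recordings.

## Worked example

A reduced-scale synthetic session (2 × 10 s trains, 60 s windows, 1250 Hz)
with a post-train theta increase (amplitude ×1.3) and coupling-depth drop
(κ ×0.5), analyzed with the same code paths used for full-scale recordings:

```r
library(lfpac)

sched <- build_schedule(n_trains = 2, train_s = 10, pause_s = 30,
                        pre_s = 60, post_s = 60)
spec  <- synthetic_spec(duration_s = 170, fs = 1250,
                        post_theta_mult = 1.3, post_kappa_mult = 0.5,
                        seed = 42)
sess <- generate_session(spec, sched)$session
ep   <- extract_epochs(sess)

session_ied_rates(sess)
#> <ied_rate_summary> bilateral 2.40 events/min (L 2.40, R 2.40), lateralization +0.00
#>   subtypes: spike 50%, polyspike 17%, sharp wave 33%

epoch_pac(sess, ep, pac_config(fa_bands = data.frame(
  name = "gamma", f_low = 30, f_high = 100)))[,
  c("epoch", "channel", "max_pac", "max_pac_fa")]
#>   epoch    channel    max_pac max_pac_fa
#> 1  pre5  left_hipp 0.06828705         80
#> 2  pre5 right_hipp 0.07932121         80
#> 3 post5  left_hipp 0.03504535         80
#> 4 post5 right_hipp 0.05054433         80

theta_change(
  list(left_hipp  = epoch_trace(sess, ep, "pre30", "left_hipp"),
       right_hipp = epoch_trace(sess, ep, "pre30", "right_hipp")),
  list(left_hipp  = epoch_trace(sess, ep, "post30", "left_hipp"),
       right_hipp = epoch_trace(sess, ep, "post30", "right_hipp")))
#> <theta_change> relative theta 25.4% -> 34.6% (+35.9%)
```

Reading the output: the detector recovers the injected discharges at
2.4 events/min with the expected subtype mix; the tPAC estimator locates
the imposed 80 Hz carrier in every epoch and MaxPAC drops after the trains
on both sides (κ was halved post-train); relative theta rises from ~25% to
~35% (the theta amplitude was raised ×1.3, i.e. ×1.69 in power). Percent
changes use the study conventions, e.g.
`percent_change(5.17, 3.37)` → `34.81625` (an IED-rate reduction of 34.8%).

## Documentation

The methods vignette (`vignettes/lfp-dbs-pipeline.Rmd`) documents the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator emulates and what it deliberately does not,
the numerical choices (zero-phase frequency-domain filters, edge trims,
robust scales, tie-breaks, degenerate inputs), and known limitations.
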