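Package: lfpac
Title: Hippocampal LFP Analysis for Low-Frequency Deep Brain Stimulation
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal local field potential (LFP)
    recordings acquired around amygdala low-frequency deep brain stimulation
    in rodent models of temporal lobe epilepsy. Provides detection and rating
    of interictal epileptiform discharges (spikes, polyspikes, sharp waves),
    windowed spectral band-power estimation with relative theta power,
    time-resolved delta-to-fast-oscillation phase-amplitude coupling (tPAC)
    with comodulograms, MaxPAC extraction and surrogate control, a stimulation
    schedule and epoch model, minimal European Data Format (EDF) input and
    output, study-level statistics linking electrophysiological markers to
    seizure outcome, and a ground-truth-annotated synthetic LFP and seizure-log
    generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
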