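Package: apseize
Title: Seizure-Like Event Detection and Intrinsic Optical Signal Analysis
    for the 4-Aminopyridine Slice Model
Version: 0.1.0
Authors@R:
    person("apseize", "developers", email = "apseize@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of 4-aminopyridine-induced seizure-like
    events (SLEs) in combined hippocampal-entorhinal cortex slices.
    Detects SLEs in local field potential recordings using the three
    electrographic criteria (negative DC shift of at least 0.5 mV,
    duration of at least 10 s, superimposed ripple-like discharges),
    quantifies intrinsic optical signals as per-pixel transmittance
    changes (dT/T) with a threshold-persistence involvement rule and
    per-region SLE areas, and aggregates baseline/intervention/wash-out
    phase summaries into antiepileptic drug effect measures (frequency
    ratios, responder rates, repeated-measures and between-group
    statistics). Includes a calibrated synthetic generator for paired
    LFP traces and trigger-aligned 8-bit image stacks with known ground
    truth, and a command-line pipeline for reproducible simulated
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
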