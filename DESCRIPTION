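Package: burstlapse
Title: Cycle-by-Cycle EEG Burst Detection and Behavioural Lapse Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking oscillatory theta and alpha bursts in multichannel
    EEG to behavioural lapses in a sustained visual attention task.
    Implements cycle-by-cycle burst detection (narrow filter bank,
    zero-crossings, per-cycle rhythmicity criteria), event-locked burst
    occupancy time courses and window topographies, pre-stimulus
    burst-amplitude quantile analysis, Morlet time-frequency control
    analyses, pupil-confidence eye-closure masking, and the supporting
    statistics layer (one-sample and paired t-tests, Benjamini-Hochberg
    FDR, Hedge's g, minimal detectable effect size via the noncentral t
    distribution). A synthetic-data generator produces 1/f background EEG
    with ground-truth bursts, eye closures, and behaviourally coupled
    trial outcomes so every pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
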