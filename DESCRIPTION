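Package: lfpmon
Title: Session Tooling and Seizure Detection for Chronic Multianimal Video-LFP Monitoring
Version: 0.1.0
Authors@R: person("Ewell Lab", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Reads and writes the packet-blocked binary session files produced by
    low-cost multianimal chronic video-LFP acquisition rigs, reconstructs the
    alignment between 256-sample voltage packets and video frame indices
    (including offline linear frame interpolation and segment continuity
    checks), implements two seizure detectors (amplitude threshold on a
    bandpassed trace and sliding-window FFT band power), quantifies
    cross-animal signal independence (pairwise Pearson correlations, one-way
    ANOVA, Tukey post hoc), and models the Racine-scale scoring questionnaire.
    A seeded synthetic session generator emulates multianimal LFP with
    interictal spikes, seizures and movement artifacts so the whole pipeline
    runs without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
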