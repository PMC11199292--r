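Package: microstability
Title: Resting-State EEG Microstate Segmentation and Trait-Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: preprocessing of
    multichannel recordings (zero-phase band-pass and notch filtering, channel
    interpolation, epoching, amplitude-based artifact rejection, average
    referencing), extraction of topographic maps at global field power peaks,
    atomize-agglomerate hierarchical clustering (AAHC) into K microstate
    classes, grand-mean clustering across subjects, template-based map sorting,
    backfitting to continuous data, and per-subject temporal stability metrics
    (duration, occurrence, coverage, global explained variance). A statistical
    layer relates microstate stability to questionnaire-based trait aggression
    via intraclass correlations, random-intercept model comparison, standardized
    regression, and gender-moderated regression with simple slopes. Includes a
    synthetic-data generator that plants known microstate structure and known
    trait effects so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
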