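Package: sleeparch
Title: Hyperarousal Features of Sleep Architecture from Polysomnography
Version: 0.1.0
Authors@R:
    person("sleeparch", "maintainers", email = "maintainers@sleeparch.org",
           role = c("aut", "cre"))
Description: Computes polysomnography-derived markers of hyperarousal for
    insomnia research: sleep-stage transition count matrices and
    probabilities, multitaper relative band-power features per sleep stage,
    sleep-spindle and slow-oscillation microarchitecture (density,
    dispersion, spindle-peak phase within slow oscillations), and the Wake
    EEG Similarity Index (WESI), an L1-regularized robust logistic score of
    how wake-like a 3-s EEG segment is. Includes a synthetic PSG cohort
    generator (Markov hypnograms, stage-shaped EEG spectra, planted spindle
    and slow-oscillation events, artifact injection) providing ground truth
    for every detector, plus mixed-effects group comparison machinery with
    likelihood-ratio tests, family-wise FDR adjustment and hurdle models for
    sparse transition counts. Signal primitives (Kaiser-window FIR filters,
    polyphase resampling, DPSS multitaper spectra, minimal EDF read/write)
    are implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
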