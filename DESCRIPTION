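Package: bhi
Title: Brain-Heart Interaction Analysis for Continuous Emotional Arousal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved analysis of brain-heart interplay during naturalistic
    emotional arousal. Provides a synthetic generator of coupled ECG/EEG/rating
    sessions with known ground truth (integral pulse frequency modulation heart
    model, adaptive Markov EEG band amplitudes, heartbeat-locked potentials),
    wavelet-based 1-Hz low/high-frequency heart-rate-variability and EEG band
    power series, per-participant tertile binning of continuous arousal ratings,
    heartbeat-evoked potentials with spatio-temporal cluster-based permutation
    testing, directional brain-to-heart and heart-to-brain coupling estimation
    from a synthetic-data-generation model, and condition-level inference with
    linear mixed models, Tukey-corrected marginal-mean contrasts and
    Benjamini-Yekutieli corrected electrode-wise tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
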