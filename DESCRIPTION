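Package: edgesalience
Title: Edge Salience in Auditory Pattern Matching: Stimuli, Synthetic
    Observers and Signal-Detection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a melody-detection paradigm probing the salience of
    spectral edges in auditory scenes. Generates constrained random
    pure-tone melodies in ERB-spaced frequency bands (log-uniform
    frequencies over half-octave ranges, rejection-sampled tone durations,
    cosine-ramped synthesis, A-weighted level alignment), builds fully
    counterbalanced yes/no detection designs with constant-density muting
    rules, simulates cohorts of equal-variance signal-detection observers
    with programmable sensitivity per presentation-order and edge-position
    cell, and fits the complete analysis chain: hit and false-alarm rates,
    d-prime with extreme-rate correction, per-participant edge- and
    order-effect contrasts with percentile bootstrap confidence intervals
    over participants, linear mixed-effects models with participant random
    intercepts, and a within-band relative-edge hit-rate analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    lmerTest,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
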