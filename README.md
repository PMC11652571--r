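# edgesalience

Tools for studying the salience of spectral edges in auditory scene
analysis with a yes/no melody-detection paradigm.

In the paradigm this package implements, a listener hears an isolated 2-s
"target" pure-tone melody and a 2-s mixture of several such melodies, each
confined to its own frequency band, and reports whether the target was in
the mixture. Presenting the target cue *before* the mixture
(Target-Mixture, TM) lets the listener direct attention to the target band;
presenting it *after* (Mixture-Target, MT) forces holistic listening.
Detection is scored with equal-variance signal-detection sensitivity,

    d' = z(hit rate) − z(false-alarm rate),

and the phenomenon of interest is the **edge effect**: targets in the
lowest or highest band of the scene are detected better than targets in the
bands between, an advantage that does not depend on absolute frequency.

The package provides the full pipeline:

* **Stimuli** — six frequency bands equally spaced on the ERB-number scale
  E(f) = 21.4·log10(0.00437·f + 1) between 65 and 2080 Hz (centers 65, 215,
  441, 783, 1300, 2080 Hz); eight-tone melodies with log-uniform
  frequencies over each band's half-octave range and rejection-sampled tone
  durations (> 50 ms, summing to 2 s); sinusoidal synthesis with 10-ms
  cosine ramps; A-weighted level alignment to a common 40 dB SPL(A) target;
  WAV output.
* **Designs** — fully counterbalanced trial lists for the six-band
  experiment (120 TM + 240 MT trials; constant mixture density of five via
  random muting of one nontarget band) and the split-range experiment
  (low range bands 1–4, high range bands 3–6; 160 TM + 320 MT trials;
  density three), with per-trial seeds and edge-position bookkeeping
  (absolute edge / relative edge / center).
* **Synthetic observers** — an equal-variance SDT cohort simulator with
  programmable sensitivity per (order × edge-position) cell, Gaussian
  between-participant variability, response criterion and optional
  musical-sophistication covariates; plus a diagnostic spectrogram
  template-matching observer for rendered audio.
* **Analysis** — `edge_salience()` fits the whole chain: rates → d' (with
  log-linear extreme-rate correction) → per-participant edge- and
  order-effect contrasts → percentile bootstrap CIs over participants →
  linear mixed-effects models with participant random intercepts → the
  within-band relative-edge hit-rate GLMM → covariate R².

## Worked example

```r
library(edgesalience)

lay <- band_layout(65, 2080, 6)
lay
#> Band layout: 6 bands, ERB-spaced
#>   centers (Hz): 65, 215, 441, 783, 1300, 2080
#>   melody ranges (Hz): [65, 92] [215, 304] [441, 624] [783, 1108] [1300, 1838] [2080, 2942]

des  <- build_experiment1(lay, seed = 1)          # 120 TM + 240 MT trials
resp <- simulate_responses(observer_params(), des,
                           n_participants = 25, seed = 2)
fit  <- edge_salience(resp, B = 10000, seed = 3)
fit
#> Edge-salience fit: experiment 1, 25 participants
#>   order effect (TM - MT): +0.82 d'  [0.70, 0.93]
#>   edge effect (edge - mid): +0.57 d'  [0.45, 0.68]
#>     MT: +0.79 d'
#>     TM: +0.34 d'
```

The order effect says the cohort gains about 0.8 d' units when the target
cue precedes the mixture; the edge effect says targets in the outermost
bands are detected about 0.6 d' units better than targets in between, with
the advantage larger in the uncued (MT) order — the same qualitative
structure that the default observer is programmed with (cell means
TM edge 2.95, TM mid 2.55, MT edge 2.12, MT mid 1.31). `summary(fit)`
additionally prints the cohort d' for every order × band cell with its
bootstrap CI and the mixed-model coefficient table; `plot(fit)` draws the
band-wise detection profile; `coef(fit)` returns the fixed effects.

A complete reproducible run (design → simulation → analysis → tidy output
directory with manifest, response table and JSON summary):

```r
cfg <- run_config(experiment = 1, seed = 1)
fit <- run_pipeline(cfg, "my_run")
```

or from a shell via the thin CLI in `inst/cli/`:

```sh
Rscript inst/cli/edge-salience run --experiment 1 --seed 1 --out my_run
```

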