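---
title: "Methods: stimulus generation, synthetic observers and the edge-salience analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus generation, synthetic observers and the edge-salience analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgesalience)
```

This vignette documents the modelling and numerical choices behind the
package: how the stimuli are constructed, what the synthetic observer does
and does not emulate, and how the statistical chain is defined. It states
no empirical result beyond what the package's own tests compute.

## The paradigm

A trial presents an isolated 2-s pure-tone melody (the target cue) and a
2-s mixture of melodies in separate frequency bands, in one of two orders:
cue first (Target-Mixture, TM) or mixture first (Mixture-Target, MT), with
a 1-s pause between. The task is a yes/no judgement of whether the cued
melody — identical in frequencies and timing when present — was in the
mixture. Sensitivity is the equal-variance signal-detection statistic
d' = z(hit) − z(false alarm). The quantity of scientific interest is the
*edge effect*: the difference between mean d' for targets in the outermost
bands of the scene and mean d' for targets in the bands between.

## Band layout

Bands are placed on the ERB-number scale of Glasberg & Moore (1990),

  E(f) = 21.4 log10(0.00437 f + 1),  ERB(f) = 24.7 (0.00437 f + 1),

with `n_bands` centers equally spaced between E(65) and E(2080) and
inverted back to Hz. Rounded to integer Hz this yields the published
centers 65, 215, 441, 783, 1300, 2080; centers are stored at full floating
precision and rounded only for display, so downstream draws never compound
rounding error. The builder also accepts explicit centers, because the
interpolate-then-round construction is one of two readings of how a
printed center list may have been produced; both yield the same integers
here.

Each band's melody range is the half octave *anchored at the center*:
[c, c·2^(1/2)]. The worked mapping 1300 → [1300, 1838] fixes this reading
(the center is the lower bound, not the midpoint). The constructor enforces
the separation invariant that the gap between one band's upper melody
bound and the next band's center is at least one ERB bandwidth evaluated
at the gap's lower edge; with tones inside their half-octave ranges this
guarantees neighbouring-band tones are always at least one ERB apart, the
design's defence against energetic masking. Layouts violating the
invariant are rejected with an error rather than silently accepted.

## Melody generation

* **Frequencies.** Uniform on a log2 scale over the band's half octave; no
  semitone or interval constraints.
* **Timing.** Seven interior timepoints uniform on (0, 2) s, sorted; with
  the fixed boundaries 0 and 2 they partition the melody into eight
  contiguous tones. Draws with any tone ≤ 50 ms are discarded *wholesale*
  and redrawn. The acceptance probability has the closed form
  (1 − 8·0.05/2)^7 = 0.8^7 ≈ 0.21, so the expected number of attempts per
  melody is about 4.8; the iteration cap (10^6) is unreachable in
  practice. Partial repair of a rejected draw would distort the spacing
  distribution, which is why rejection is all-or-nothing.
* **Synthesis.** Each tone is a sinusoid gated by 10-ms raised-cosine
  onset and offset ramps lying *inside* the tone's interval. The source
  description of "separated by" ramps is ambiguous between embedded ramps
  and ramps extending the tone; embedded ramps preserve the exact
  timepoint partition (no overlap, no gap) and are what the package
  implements. The 50-ms duration floor guarantees both ramps fit.

## Level alignment

Levels are measured as A-weighted RMS, with the IEC 61672 analytic
magnitude curve applied in the frequency domain to the whole 2-s waveform
(silence between tones included in the RMS window — the simplest fixed
window, stated so results are reproducible). The curve is normalised to
exactly 0 dB at 1 kHz; the familiar checkpoints follow (−19.1 dB at
100 Hz). A frequency-domain implementation avoids filter-design dialects;
the contract is 0.05 dB agreement for narrowband signals, not bit
exactness against any particular time-domain filter.

Digital level maps to SPL through a single calibration constant,
0 dBFS = 100 dB SPL by default, so the 40 dB SPL(A) presentation target
sits at −60 dBFS(A). In a headless pipeline the absolute SPL figure only
matters as a common target across bands. Alignment is per melody (not a
fixed per-band gain), the stricter reading of level equalisation;
idempotence and cross-band agreement to 0.01 dB are tested. Gains that
would clip raise an error instead of limiting.

## Experiment designs

Both designs counterbalance target presence exactly within every
(order × band × range) condition — hence per-condition trial counts must
be even — and shuffle trial order uniformly within block (the source
states randomisation without further detail).

* **Six-band design** (TM 20/condition = 120 trials, then MT 40/condition
  = 240). Version 2 mutes one uniformly random nontarget band on present
  trials so the mixture always holds five melodies; version 1 has no
  muting (6 present / 5 absent). On absent trials the cue melody is drawn
  for the target band but withheld, and the target band is silent — the
  only reading consistent with both the stated densities and the muting
  fix. Whether the original absent-trial cue was freshly drawn or recycled
  is unstated; fresh per-trial draws are implemented.
* **Split-range design** (ranges bands 1–4 and 3–6; TM 2 × 80 = 160, MT
  2 × 160 = 320; range order counterbalanced by `start_range`). Density is
  three everywhere: present trials drop one of the three nontargets at
  random; absent trials play all three nontargets — the unique way to
  reach density three without the target.

Each trial records a derived integer seed, so any trial's melodies can be
regenerated in isolation; a single master seed determines the entire run.

Edge bookkeeping classifies the *designed* position of the target band:
absolute edge (outermost band of the range), relative edge (an inner band
left extreme among the active bands by muting), or center (active bands on
both sides). Classification ignores the response and applies equally to
absent trials.

## The synthetic observer

The cohort stand-in is an equal-variance Gaussian SDT observer because the
analysis reports d'; with that choice, programmed cell sensitivities are
exactly the asymptotic d' values and parameter recovery is well-posed.
Present trials draw evidence from N(d, 1), absent trials from N(0, 1), and
the decision threshold is d/2 + c, so c = 0 is unbiased and the recovered
d' equals the programmed one in expectation regardless of c.

Defaults are the study conditions: the six-band cell means
(TM edge 2.95, TM mid 2.55, MT edge 2.12, MT mid 1.31) and cohort size 25.
For the split-range variant the printed values give TM edge 2.93 and MT
edge (2.42 + 2.36)/2 = 2.39; the unprinted mid cells are solved from the
printed order means (TM 2.75, MT 2.07) under equal edge/mid weighting
(each range has two edge and two mid bands): TM mid 2.57, MT mid 1.75. The
split-range default also grants relative-edge trials the edge
sensitivity, which is what generates a within-band hit-rate difference.
Between-participant spread is Gaussian on the d' scale with SD 0.5 — the
source reports individual spread graphically but no numeric SD, so 0.5 is
a fixed, documented choice of plausible magnitude, configurable. Optional
Gold-MSI-like covariate scores (perception ~ N(50, 9), training
~ N(26, 11), rounded) act through per-point slopes on sensitivity.

What the simulator does **not** emulate: memory decay in the MT order,
learning or fatigue, criterion drift, lapses, and any acoustic limitation
— its responses are generated from trial metadata, not audio. Passing
recovery tests therefore validate the *analysis chain*, not any claim
about human hearing. The spectrogram template-matching observer closes
that gap at the acoustic level only diagnostically: it verifies that
rendered present/absent trials are separable (embedded templates correlate
near 1, silent bands near 0) and has no order or edge effects by
construction.

## The analysis chain

* **Rates and d'.** Counts per cell; d' with the log-linear correction
  (add 0.5 to each count, 1 to each total) by default so perfect rates
  stay finite; a 1/(2N) clamp and an uncorrected variant are available.
  The source does not state its extreme-rate handling; log-linear is the
  standard documented default here.
* **Aggregation.** Reported cohort means are means of participant-level
  d' (not pooled-trial d'); the alternative is noted as an open dialect
  question and the participant-mean choice is applied consistently.
* **Edge and order effects.** Per participant: mean d' over edge bands
  minus mean over mid bands (positive = edge advantage), and mean TM minus
  mean MT. Both are invariant to participant-wise additive shifts, so
  participant intercepts cancel by construction. In the split-range
  analysis, mid-band cells use only center-classified present trials —
  relative-edge trials are excluded from the mid cells, mirroring the
  design-based exclusion in the source analysis.
* **Bootstrap.** Percentile intervals from B = 10000 resamples drawn over
  participants (the exchangeable units), seeded. The percentile method
  at cohort sizes of 25–30 undercovers mildly (≈93% empirical coverage at
  nominal 95%), a known property checked explicitly in the tests.
* **Mixed models.** Participant-cell d' on order (MT reference), edge,
  their interaction, numeric band, covariate scores, plus a binary range
  term for the split-range variant, with participant random intercepts
  (lme4, Satterthwaite p values via lmerTest). A trial-level binomial
  GLMM variant is provided; the cell-level linear model is the default
  because the reported statistic is d'. Rank-deficient or degenerate
  inputs surface as errors from the fitting engine rather than silent
  drops.
* **Within-band hit rates.** Present trials of the inner bands, hit
  modelled by a logit GLMM on relative-edge class, order, band and range
  with participant intercepts. The link function is not stated in the
  source; logit is assumed. Class-wise cohort hit rates are means of
  participant rates with percentile bootstrap CIs.
* **Muting contrast.** Participant-cell hit rates for adjacent- versus
  non-adjacent-muted present trials, with an order interaction, as a
  linear mixed model.

## Problem sizes and numerical tolerances

The test suite exercises the generator invariants on 10^4 seeded melodies,
checks level alignment to 0.01 dB on synthesized audio at 44.1 kHz,
verifies parameter recovery over 100 replicate cohorts of 25 participants
at the full design sizes, and measures bootstrap coverage over 500 cohorts
of 30 participants with B = 2000 — sizes chosen to keep Monte-Carlo error
well below the assertion margins while the whole suite runs in about a
minute. Audio-dependent tests use reduced sampling rates (8–16 kHz) where
the checked property is rate-invariant; all band frequencies remain far
below Nyquist.

## Known limitations

* Participant-level d' from a few dozen trials per cell is biased toward
  zero by the z-transform (about −0.1 to −0.15 d' units at the highest
  programmed cell with 20 present trials); cohort CIs around the highest
  cell consequently undercover the programmed value relative to the other
  cells. This is a property of the estimator at these trial counts, not of
  the simulator; it is visible in the recovery tests and documented rather
  than corrected, since the correction choice is part of the analysis
  dialect being reproduced.
* The A-weighting contract is the analytic magnitude curve; comparisons
  against hardware sound-level meters or IIR implementations hold to
  ~0.05 dB for narrowband signals only.
* Human coefficient values (β, t, p, F, R² of the original cohorts) depend
  on the human sample and are out of scope; the pipeline recovers signs,
  magnitudes of programmed effects, and coefficient structure.
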