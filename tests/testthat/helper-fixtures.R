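# Shared fixtures: everything is generated in code at test time.

paper_layout <- function() band_layout(65, 2080, 6)

# A small but structurally complete six-band design (even counts).
small_design1 <- function(seed = 101, n_tm = 4, n_mt = 4, version = 2)
  build_experiment1(paper_layout(), n_tm, n_mt, version = version,
                    seed = seed)

small_design2 <- function(seed = 202, n_tm = 4, n_mt = 4)
  build_experiment2(paper_layout(), n_tm, n_mt, seed = seed)

# Deterministic response table: the observer answers "present" with the
# given accuracy on every trial (used for arithmetic checks).
rigged_responses <- function(design, accuracy = 1, n_participants = 1) {
  trials <- design$trials
  do.call(rbind, lapply(seq_len(n_participants), function(p) {
    correct <- rep_len(c(TRUE, FALSE), nrow(trials))[
      sample.int(nrow(trials))] | accuracy >= 1
    resp <- ifelse(correct | stats::runif(nrow(trials)) < accuracy,
                   trials$present, !trials$present)
    cbind(data.frame(participant = p, msi_perception = 50,
                     msi_training = 25), trials, response = resp,
          evidence = NA_real_)
  }))
}

# Single-tone melody covering the full 2 s (for synthesis oracles).
one_tone_melody <- function(freq = 1000, band = 1) {
  structure(list(band_index = band,
                 tones = data.frame(freq = freq, onset = 0, offset = 2),
                 seed = NULL),
            class = "tone_melody")
}

pure_sine <- function(freq, rate = 44100, dur = 1, amp = 0.5)
  waveform(amp * sin(2 * pi * freq * (seq_len(rate * dur) - 1) / rate), rate)
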