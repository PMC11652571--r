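#' Draw melody tone frequencies for one band
#'
#' Frequencies are uniform on a log2 scale over the band's half-octave range
#' [center, center * 2^(1/2)]: log2(f) ~ U(log2(low), log2(low) + 1/2). No
#' musical-interval or semitone constraints are applied.
#'
#' @param layout A [band_layout()].
#' @param k Band index.
#' @param n_tones Number of frequencies to draw (default 8).
#' @return Numeric vector of frequencies in Hz.
#' @export
draw_melody_frequencies <- function(layout, k, n_tones = 8) {
  rng <- band_range(layout, k)
  2^stats::runif(n_tones, log2(rng[1]), log2(rng[2]))
}

#' Draw the tone onset/offset partition of a 2-s melody
#'
#' Seven interior timepoints are drawn uniformly on (0, 2) and sorted;
#' together with the fixed boundaries 0 and 2 they partition the melody into
#' eight tone intervals. Draws containing any interval of 50 ms or shorter
#' are discarded wholesale and redrawn (rejection sampling), so all eight
#' durations exceed 50 ms and sum to exactly 2 s.
#'
#' @param total_s Total melody duration in seconds (default 2).
#' @param n_tones Number of tones (default 8; `n_tones - 1` interior points).
#' @param min_dur_s Minimum tone duration in seconds, exclusive (default 0.05).
#' @param max_attempts Rejection-sampling cap (default 1e6).
#' @return Data frame with columns `onset`, `offset` (seconds), one row per
#'   tone, plus attribute `attempts` recording the number of draws used.
#' @export
draw_timepoints <- function(total_s = 2, n_tones = 8, min_dur_s = 0.05,
                            max_attempts = 1e6) {
  for (attempt in seq_len(max_attempts)) {
    pts <- sort(stats::runif(n_tones - 1, 0, total_s))
    bounds <- c(0, pts, total_s)
    if (all(diff(bounds) > min_dur_s)) {
      out <- data.frame(onset = bounds[-length(bounds)], offset = bounds[-1])
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop("rejection sampling failed to find a valid timepoint partition")
}

#' Generate one constrained random pure-tone melody
#'
#' Combines [draw_timepoints()] and [draw_melody_frequencies()]: eight
#' contiguous tones spanning exactly 2 s, each with a frequency drawn
#' log-uniformly within the band's half-octave range.
#'
#' @inheritParams draw_melody_frequencies
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and independent of the caller's RNG state.
#' @return Object of class `tone_melody`: list with `band_index`, `tones`
#'   (data frame `freq`, `onset`, `offset`), `seed`.
#' @export
make_melody <- function(layout, k, seed = NULL) {
  draw <- function() {
    tp <- draw_timepoints()
    data.frame(freq = draw_melody_frequencies(layout, k, nrow(tp)),
               onset = tp$onset, offset = tp$offset)
  }
  tones <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(band_index = k, tones = tones, seed = seed),
            class = "tone_melody")
}

#' @export
print.tone_melody <- function(x, ...) {
  cat(sprintf("Pure-tone melody, band %d, %d tones over %.3f s\n",
              x$band_index, nrow(x$tones), max(x$tones$offset)))
  print(round(x$tones, 3))
  invisible(x)
}

#' Synthesize a melody to a waveform
#'
#' Each tone is a pure sinusoid at its frequency, gated by a 10-ms raised
#' cosine onset ramp and a 10-ms offset ramp, both lying inside the tone's
#' interval so consecutive tones neither overlap nor leave gaps.
#'
#' @param melody A `tone_melody`.
#' @param rate_hz Sampling rate in Hz (default 44100).
#' @param amplitude Peak amplitude in full-scale units (default 0.1).
#' @param ramp_s Ramp duration in seconds (default 0.010).
#' @return Object of class `waveform`: list with `samples` (numeric in
#'   [-1, 1]) and `rate_hz`.
#' @export
synthesize_melody <- function(melody, rate_hz = 44100, amplitude = 0.1,
                              ramp_s = 0.010) {
  tones <- melody$tones
  if (any(tones$offset - tones$onset <= 2 * ramp_s))
    stop("tone shorter than twice the ramp duration; cannot fit ramps")
  total <- max(tones$offset)
  n <- round(total * rate_hz)
  x <- numeric(n)
  t_all <- (seq_len(n) - 1) / rate_hz
  for (i in seq_len(nrow(tones))) {
    i0 <- floor(tones$onset[i] * rate_hz) + 1
    i1 <- min(n, ceiling(tones$offset[i] * rate_hz))
    idx <- i0:i1
    tt <- t_all[idx] - tones$onset[i]
    dur <- tones$offset[i] - tones$onset[i]
    env <- rep(1, length(idx))
    env[tt < ramp_s] <- 0.5 * (1 - cos(pi * tt[tt < ramp_s] / ramp_s))
    tail_t <- dur - tt
    sel <- tail_t < ramp_s
    env[sel] <- pmin(env[sel], 0.5 * (1 - cos(pi * pmax(tail_t[sel], 0) / ramp_s)))
    x[idx] <- x[idx] + amplitude * env * sin(2 * pi * tones$freq[i] * tt)
  }
  waveform(x, rate_hz)
}

#' Construct a waveform object
#'
#' @param samples Numeric amplitude sequence in full-scale units [-1, 1].
#' @param rate_hz Sampling rate in Hz.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz = 44100) {
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, max(abs(x$samples))))
  invisible(x)
}
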