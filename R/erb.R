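#' ERB-number scale conversions
#'
#' The equivalent-rectangular-bandwidth (ERB) scale of Glasberg & Moore (1990)
#' maps frequency in Hz onto a perceptually even scale of auditory-filter
#' widths. `erb_number()` gives the cumulative ERB-number E(f) =
#' 21.4 log10(0.00437 f + 1); `erb_to_hz()` inverts it; `erb_bandwidth()`
#' gives the filter bandwidth ERB(f) = 24.7 (0.00437 f + 1) in Hz.
#'
#' @param f Frequency in Hz (vectorised, must be > 0; `erb_to_hz` accepts
#'   ERB-numbers >= 0).
#' @return Numeric vector: ERB-numbers (dimensionless), Hz, or bandwidth Hz.
#' @examples
#' erb_number(1000)        # ~15.62
#' erb_bandwidth(1000)     # ~132.6 Hz
#' erb_to_hz(erb_number(440))
#' @export
erb_number <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  21.4 * log10(0.00437 * f + 1)
}

#' @rdname erb_number
#' @param e ERB-number (>= 0).
#' @export
erb_to_hz <- function(e) {
  if (any(!is.finite(e)) || any(e < 0))
    stop("ERB-numbers must be non-negative and finite", call. = FALSE)
  (10^(e / 21.4) - 1) / 0.00437
}

#' @rdname erb_number
#' @export
erb_bandwidth <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  24.7 * (0.00437 * f + 1)
}

#' Construct a band layout for melody stimuli
#'
#' Places `n_bands` band centers equally spaced on the ERB-number scale
#' between `f_low` and `f_high` (both inclusive), or accepts an explicit
#' vector of centers. Each band carries a half-octave melody range anchored
#' at its center: melodies in band k draw frequencies from
#' [center_k, center_k * 2^(1/2)]. The constructor validates that the gap
#' between each band's upper melody bound and the next band's center is at
#' least one ERB bandwidth (evaluated at the gap's lower edge), so that
#' tones in neighbouring bands are always separated by at least one ERB.
#'
#' Six bands between 65 and 2080 Hz reproduce the centers
#' 65, 215, 441, 783, 1300, 2080 Hz after rounding to integer Hz. Centers
#' are stored at full floating precision; rounding happens only on display.
#'
#' @param f_low,f_high Lowest and highest band center in Hz.
#' @param n_bands Number of bands (>= 2).
#' @param centers Optional explicit centers in Hz (overrides interpolation).
#' @return An object of class `band_layout`: list with `centers_hz`,
#'   `n_bands`, `half_octave_ratio`.
#' @examples
#' lay <- band_layout()
#' round(lay$centers_hz)
#' band_range(lay, 5)   # c(1300, 1838) approximately
#' @export
band_layout <- function(f_low = 65, f_high = 2080, n_bands = 6,
                        centers = NULL) {
  if (is.null(centers)) {
    if (!(f_low > 0 && f_high > f_low)) stop("need 0 < f_low < f_high")
    if (n_bands < 2) stop("n_bands must be >= 2")
    centers <- erb_to_hz(seq(erb_number(f_low), erb_number(f_high),
                             length.out = n_bands))
  } else {
    if (any(centers <= 0) || is.unsorted(centers, strictly = TRUE))
      stop("explicit centers must be positive and strictly increasing")
    n_bands <- length(centers)
  }
  ratio <- 2^(1 / 2)
  upper <- centers * ratio
  if (n_bands >= 2) {
    gap <- centers[-1] - upper[-n_bands]
    need <- erb_bandwidth(upper[-n_bands])
    bad <- which(gap < need)
    if (length(bad))
      stop(sprintf(
        "layout violates band separation: gap above band %d is %.1f Hz but one ERB there is %.1f Hz",
        bad[1], gap[bad[1]], need[bad[1]]), call. = FALSE)
  }
  structure(list(centers_hz = centers, n_bands = n_bands,
                 half_octave_ratio = ratio),
            class = "band_layout")
}

#' @export
print.band_layout <- function(x, ...) {
  cat(sprintf("Band layout: %d bands, ERB-spaced\n", x$n_bands))
  cat("  centers (Hz):", paste(round(x$centers_hz), collapse = ", "), "\n")
  rng <- vapply(seq_len(x$n_bands), function(k) band_range(x, k), numeric(2))
  cat("  melody ranges (Hz):",
      paste(sprintf("[%d, %d]", round(rng[1, ]), round(rng[2, ])),
            collapse = " "), "\n")
  invisible(x)
}

#' Melody frequency range of one band
#'
#' The half-octave range anchored at the band center: low = center,
#' high = center * 2^(1/2).
#'
#' @param layout A `band_layout`.
#' @param k Band index (1-based).
#' @return Numeric length-2 vector `c(low, high)` in Hz.
#' @export
band_range <- function(layout, k) {
  stopifnot(inherits(layout, "band_layout"))
  if (any(k < 1 | k > layout$n_bands)) stop("band index out of range")
  c(layout$centers_hz[k], layout$centers_hz[k] * layout$half_octave_ratio)
}
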