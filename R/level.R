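#' A-weighted level of a waveform
#'
#' Applies the IEC 61672 analytic A-weighting magnitude response in the
#' frequency domain (via the FFT of the whole waveform, normalised so the
#' weight at 1 kHz is exactly 0 dB) and returns the weighted RMS level in
#' dB relative to digital full scale (a full-scale sinusoid at 1 kHz reads
#' about -3.01 dBFS). The RMS window is the full waveform, silence included.
#'
#' @param w A [waveform()].
#' @return A-weighted level in dB re full scale (scalar).
#' @export
a_weight_level <- function(w) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (all(x == 0)) stop("level of an all-zero waveform is undefined")
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * w$rate_hz / n   # fold to [0, rate/2]
  wgt <- a_weight_gain(f)
  rms_w <- sqrt(sum((Mod(X) * wgt)^2)) / n
  20 * log10(rms_w)
}

# Linear-magnitude A-weighting gain, exactly unity at 1 kHz; gain(0) = 0.
a_weight_gain <- function(f) {
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  out <- numeric(length(f))
  pos <- f > 0
  out[pos] <- ra(f[pos]) / ra(1000)
  out
}

#' A-weighting attenuation in dB at given frequencies
#'
#' Convenience accessor for the analytic A-curve (0 dB at 1 kHz, about
#' -19.1 dB at 100 Hz).
#'
#' @param f Frequency in Hz.
#' @return Weight in dB (negative = attenuated).
#' @export
a_weight_db <- function(f) {
  if (any(f <= 0)) stop("frequencies must be positive")
  20 * log10(a_weight_gain(f))
}

#' Align waveforms to a common A-weighted presentation level
#'
#' Rescales each waveform by a single gain so its A-weighted level equals
#' `target_dba` dB SPL(A) under the digital-to-SPL calibration convention
#' that 0 dBFS corresponds to `cal_dbfs_spl` dB SPL. Shapes are unchanged
#' up to the scalar gain. Errors if any required gain would clip.
#'
#' @param waves A list of [waveform()]s (a single waveform is accepted).
#' @param target_dba Target level in dB SPL(A) (default 40, the presentation
#'   level used for every band).
#' @param cal_dbfs_spl Calibration constant: SPL at digital full scale
#'   (default 100, so the 40 dB SPL(A) target sits at -60 dBFS(A)).
#' @return List of aligned waveforms (or a single waveform if one was given),
#'   with the applied gains attached as attribute `gains`.
#' @export
align_levels <- function(waves, target_dba = 40, cal_dbfs_spl = 100) {
  single <- inherits(waves, "waveform")
  if (single) waves <- list(waves)
  target_dbfs <- target_dba - cal_dbfs_spl
  gains <- vapply(waves, function(w)
    10^((target_dbfs - a_weight_level(w)) / 20), numeric(1))
  out <- Map(function(w, g) {
    y <- w$samples * g
    if (any(abs(y) > 1))
      stop(sprintf(
        "alignment gain %.2f would clip (peak %.3f); lower the target or add headroom",
        g, max(abs(y))), call. = FALSE)
    waveform(y, w$rate_hz)
  }, waves, gains)
  attr(out, "gains") <- gains
  if (single) out[[1]] else out
}

#' Mix waveforms sample-wise
#'
#' Sums equal-length, equal-rate waveforms and checks for clipping.
#'
#' @param waves List of [waveform()]s.
#' @return A single mixed [waveform()].
#' @export
mix_waveforms <- function(waves) {
  stopifnot(length(waves) >= 1)
  n <- unique(vapply(waves, function(w) length(w$samples), integer(1)))
  r <- unique(vapply(waves, function(w) w$rate_hz, numeric(1)))
  if (length(n) != 1 || length(r) != 1)
    stop("waveforms must share length and sampling rate")
  x <- Reduce(`+`, lapply(waves, `[[`, "samples"))
  pk <- max(abs(x))
  if (pk > 1)
    stop(sprintf("mix clips: peak %.3f exceeds full scale", pk), call. = FALSE)
  waveform(x, r)
}

#' Write and read RIFF/WAVE audio
#'
#' Minimal WAV I/O: mono, 16-bit integer PCM or 32-bit IEEE float.
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `write_wav`: `path`, invisibly. `read_wav`: a [waveform()].
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  x <- w$samples
  n <- length(x)
  bytes <- bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  writeChar("RIFF", con, eos = NULL); wi(36 + n * bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wi(16, 4)
  wi(if (bits == 16) 1 else 3, 2); wi(1, 2)          # format, channels
  wi(w$rate_hz, 4); wi(w$rate_hz * bytes, 4)         # rate, byte rate
  wi(bytes, 2); wi(bits, 2)                          # block align, bits
  writeChar("data", con, eos = NULL); wi(n * bytes, 4)
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(size, signed = TRUE)
    readBin(con, "integer", n = 1, size = size, endian = "little",
            signed = signed)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  ri(4)
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- ri(4)
    if (id == "fmt ") {
      fmt <- ri(2); ch <- ri(2); rate <- ri(4); ri(4); ri(2); bits <- ri(2)
      if (ch != 1) stop("only mono WAV supported")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      nsamp <- sz / (bits / 8)
      x <- if (fmt == 1 && bits == 16) {
        readBin(con, "integer", n = nsamp, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else if (fmt == 3 && bits == 32) {
        readBin(con, "numeric", n = nsamp, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      return(waveform(x, rate))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
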