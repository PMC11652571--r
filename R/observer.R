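#' Parameters of the synthetic signal-detection observer
#'
#' An equal-variance Gaussian yes/no observer that stands in for the human
#' cohort. Sensitivity is programmed per (order, edge-position) cell on the
#' d-prime scale; each simulated participant receives a Gaussian intercept
#' (SD `participant_sd`) added to every cell, and optional musical-
#' sophistication covariates add `msi_slope` d-prime units per score point
#' (scores centred before applying the slope).
#'
#' The default `dprime_map` programs the four six-band-experiment cell
#' means: Target-Mixture edge 2.95, Target-Mixture mid 2.55, Mixture-Target
#' edge 2.12, Mixture-Target mid 1.31. `exp2_observer_params()` programs the
#' split-range experiment's cells (edges 2.93 / 2.39, mids 2.57 / 1.75,
#' solved from the printed order means under equal edge/mid weighting) and
#' by default grants relative-edge trials the edge sensitivity, which is
#' what produces a within-band edge effect in hit rates.
#'
#' @param dprime_map Named numeric: names are `order.position` cells
#'   (`TM.edge`, `TM.mid`, `MT.edge`, `MT.mid`); an optional `*.relative`
#'   entry gives relative-edge trials their own sensitivity (defaults to the
#'   cell implied by `relative_edge` below).
#' @param participant_sd Between-participant SD of sensitivity (d' units).
#' @param criterion_c Response criterion c (0 = unbiased).
#' @param msi_slope_perception,msi_slope_training d' change per point of the
#'   Gold-MSI perceptual-abilities / musical-training subscale.
#' @param relative_edge How relative-edge trials map onto the sensitivity
#'   cells: "center" (treated as mid-position, the six-band default) or
#'   "edge" (granted edge sensitivity, the split-range default).
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(dprime_map = c(TM.edge = 2.95, TM.mid = 2.55,
                                           MT.edge = 2.12, MT.mid = 1.31),
                            participant_sd = 0.5, criterion_c = 0,
                            msi_slope_perception = 0, msi_slope_training = 0,
                            relative_edge = c("center", "edge")) {
  if (any(!is.finite(dprime_map))) stop("sensitivities must be finite")
  if (participant_sd < 0) stop("participant_sd must be >= 0")
  structure(list(dprime_map = dprime_map, participant_sd = participant_sd,
                 criterion_c = criterion_c,
                 msi_slope_perception = msi_slope_perception,
                 msi_slope_training = msi_slope_training,
                 relative_edge = match.arg(relative_edge)),
            class = "observer_params")
}

#' @rdname observer_params
#' @param ... Overrides passed to [observer_params()].
#' @export
exp2_observer_params <- function(...) {
  defaults <- list(dprime_map = c(TM.edge = 2.93, TM.mid = 2.57,
                                  MT.edge = 2.39, MT.mid = 1.75),
                   relative_edge = "edge")
  args <- utils::modifyList(defaults, list(...))
  do.call(observer_params, args)
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Synthetic SDT observer\n  programmed d' cells:\n")
  print(round(x$dprime_map, 2))
  cat(sprintf("  participant SD %.2f, criterion c %.2f, relative edge -> %s\n",
              x$participant_sd, x$criterion_c, x$relative_edge))
  invisible(x)
}

# Map each trial to its programmed sensitivity cell.
trial_cells <- function(params, trials) {
  pos <- ifelse(trials$edge_class == "absolute_edge", "edge",
         ifelse(trials$edge_class == "relative_edge",
                if (params$relative_edge == "edge") "edge" else "mid", "mid"))
  key <- paste(trials$order, pos, sep = ".")
  rel_key <- paste(trials$order, "relative", sep = ".")
  use_rel <- trials$edge_class == "relative_edge" &
    rel_key %in% names(params$dprime_map)
  key[use_rel] <- rel_key[use_rel]
  missing <- setdiff(unique(key), names(params$dprime_map))
  if (length(missing))
    stop("no programmed sensitivity for cell(s): ",
         paste(missing, collapse = ", "))
  key
}

#' Simulate yes/no responses of a synthetic cohort
#'
#' Each trial draws latent evidence from a unit-variance Gaussian centred at
#' the participant-and-cell sensitivity (target present) or 0 (absent); the
#' response is "yes" when evidence exceeds the decision threshold
#' d_cell/2 + c. Cohort-level d-prime estimates therefore converge to the
#' programmed cell values as trial counts grow.
#'
#' @param params An [observer_params()].
#' @param design An `edge_design` (or its `$trials` manifest).
#' @param n_participants Cohort size.
#' @param seed Optional integer seed.
#' @return A `response_table` data frame: one row per (participant, trial)
#'   with all manifest columns plus `participant`, `response` (logical yes),
#'   `evidence`, `msi_perception`, `msi_training`.
#' @examples
#' des <- build_experiment1(band_layout(), 2, 2, seed = 1)
#' head(simulate_responses(observer_params(), des, 3, seed = 1))
#' @export
simulate_responses <- function(params, design, n_participants, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  trials <- if (inherits(design, "edge_design")) design$trials else design
  run <- function() {
    key <- trial_cells(params, trials)
    base_d <- params$dprime_map[key]
    nt <- nrow(trials)
    msi_p <- round(stats::rnorm(n_participants, 50, 9))
    msi_t <- round(stats::rnorm(n_participants, 26, 11))
    intercept <- stats::rnorm(n_participants, 0, params$participant_sd) +
      params$msi_slope_perception * (msi_p - mean(msi_p)) +
      params$msi_slope_training * (msi_t - mean(msi_t))
    out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      d <- base_d + intercept[p]
      mu <- ifelse(trials$present, d, 0)
      ev <- stats::rnorm(nt, mu, 1)
      resp <- ev > d / 2 + params$criterion_c
      cbind(data.frame(participant = p, msi_perception = msi_p[p],
                       msi_training = msi_t[p]),
            trials, response = resp, evidence = ev)
    }))
    rownames(out) <- NULL
    out
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  class(res) <- c("response_table", "data.frame")
  res
}

#' Simulate a cohort from a design object
#'
#' `simulate()` method wrapping [simulate_responses()].
#'
#' @param object An `edge_design`.
#' @param nsim Number of cohorts (a list is returned when `nsim > 1`).
#' @param seed Optional integer seed.
#' @param params An [observer_params()] (default: the six-band cells for
#'   experiment 1, the split-range cells for experiment 2).
#' @param n_participants Cohort size (defaults to the paper cohorts: 25 for
#'   experiment 1, 30 for experiment 2).
#' @param ... Unused.
#' @return A `response_table`, or a list of them when `nsim > 1`.
#' @export
simulate.edge_design <- function(object, nsim = 1, seed = NULL,
                                 params = NULL, n_participants = NULL, ...) {
  if (is.null(params))
    params <- if (object$experiment == 2) exp2_observer_params()
              else observer_params()
  if (is.null(n_participants))
    n_participants <- if (object$experiment == 2) 30 else 25
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_responses(params, object, n_participants,
                       seed = derive_seed(seed, i)))
  if (nsim == 1) sims[[1]] else sims
}

#' Template-matching ideal observer for rendered trials
#'
#' A diagnostic bottom-up observer: responds "yes" when the normalised
#' correlation between the cue's magnitude spectrogram and the mixture's
#' spectrogram, both restricted to the target band's frequency rows, exceeds
#' `threshold`. It verifies that rendered present/absent trials are
#' acoustically distinguishable; it has no order or edge effects by
#' construction.
#'
#' @param cue,mixture [waveform()]s of equal rate and length.
#' @param band_low,band_high Frequency range (Hz) of the target band.
#' @param threshold Correlation threshold for a "yes" (default 0.5).
#' @param nfft STFT window length (default 1024).
#' @return List with `response` (logical) and `score` (the correlation).
#' @export
matched_filter_observer <- function(cue, mixture, band_low, band_high,
                                    threshold = 0.5, nfft = 1024) {
  stopifnot(cue$rate_hz == mixture$rate_hz,
            length(cue$samples) == length(mixture$samples))
  sgram <- function(w) {
    s <- signal::specgram(w$samples, n = nfft, Fs = w$rate_hz,
                          overlap = nfft / 2)
    list(mag = Mod(s$S), f = s$f)
  }
  sc <- sgram(cue); sm <- sgram(mixture)
  rows <- sc$f >= band_low * 0.95 & sc$f <= band_high * 1.05
  a <- as.vector(sc$mag[rows, ]); b <- as.vector(sm$mag[rows, ])
  score <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else
    stats::cor(a, b)
  list(response = score > threshold, score = score)
}
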