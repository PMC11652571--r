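#' Build the trial list for the six-band experiment
#'
#' Two blocks, Target-Mixture first, then Mixture-Target. Each block crosses
#' six frequency conditions (one per band) with exact present/absent
#' counterbalancing, and trial order is a seeded uniform shuffle within the
#' block. Version 2 applies the constant-density muting rule: on target-present
#' trials one random nontarget band is muted, so the mixture always contains
#' five melodies whether or not the target is present. Version 1 applies no
#' muting (six melodies when present, five when absent). On target-absent
#' trials the cued band is silent in the mixture and all other bands play.
#'
#' @param layout A [band_layout()].
#' @param n_tm_per_cond Target-Mixture trials per frequency condition
#'   (default 20; must be even).
#' @param n_mt_per_cond Mixture-Target trials per frequency condition
#'   (default 40; must be even).
#' @param version 1 (no muting) or 2 (constant density, default).
#' @param seed Master seed for trial order and per-trial melody streams.
#' @return An object of class `edge_design`; its `$trials` data frame is the
#'   trial manifest (one row per trial) with columns `experiment`, `block`,
#'   `trial`, `order`, `range`, `target_band`, `present`, `muted_band`,
#'   `active_bands` (comma-separated), `edge_class`, `seed`.
#' @examples
#' des <- build_experiment1(band_layout(), seed = 1)
#' table(des$trials$order)
#' @export
build_experiment1 <- function(layout, n_tm_per_cond = 20, n_mt_per_cond = 40,
                              version = 2, seed = NULL) {
  stopifnot(inherits(layout, "band_layout"), version %in% 1:2)
  if (n_tm_per_cond %% 2 || n_mt_per_cond %% 2)
    stop("per-condition trial counts must be even for presence counterbalancing")
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  bands <- seq_len(layout$n_bands)
  blocks <- list(
    list(name = "TM1", order = "TM", n = n_tm_per_cond),
    list(name = "MT1", order = "MT", n = n_mt_per_cond))
  trials <- with_seed(seed, do.call(rbind, lapply(blocks, function(b) {
    df <- expand.grid(target_band = bands,
                      rep = seq_len(b$n), KEEP.OUT.ATTRS = FALSE)
    df$present <- df$rep <= b$n / 2
    df$muted_band <- NA_integer_
    if (version == 2) {
      for (i in which(df$present))
        df$muted_band[i] <- sample(setdiff(bands, df$target_band[i]), 1)
    }
    df <- df[sample.int(nrow(df)), ]
    df$block <- b$name
    df$order <- b$order
    df
  })))
  finalize_design(trials, layout, experiment = 1L, version = version,
                  range_map = list(TM1 = bands, MT1 = bands), seed = seed)
}

#' Build the trial list for the split-range experiment
#'
#' Four blocks: two Target-Mixture then two Mixture-Target, one block per
#' frequency range within each order. The low range spans bands 1-4 and the
#' high range bands 3-6; `start_range` sets which range comes first within
#' each order (counterbalanced across participants). Mixture density is
#' three bands in every trial: present trials play the target plus two of
#' its three range neighbours (one nontarget dropped at random, recorded as
#' `muted_band`); absent trials play the three nontarget bands.
#'
#' @inheritParams build_experiment1
#' @param start_range "low" or "high": the range presented first in each
#'   order condition.
#' @return An `edge_design` (see [build_experiment1()]); `range` is "low" or
#'   "high" and `target_band` is the absolute band index (1-6).
#' @export
build_experiment2 <- function(layout, n_tm_per_cond = 20, n_mt_per_cond = 40,
                              start_range = c("low", "high"), seed = NULL) {
  stopifnot(inherits(layout, "band_layout"), layout$n_bands == 6)
  start_range <- match.arg(start_range)
  if (n_tm_per_cond %% 2 || n_mt_per_cond %% 2)
    stop("per-condition trial counts must be even for presence counterbalancing")
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  ranges <- list(low = 1:4, high = 3:6)
  rorder <- if (start_range == "low") c("low", "high") else c("high", "low")
  blocks <- list(
    list(name = "TM1", order = "TM", range = rorder[1], n = n_tm_per_cond),
    list(name = "TM2", order = "TM", range = rorder[2], n = n_tm_per_cond),
    list(name = "MT1", order = "MT", range = rorder[1], n = n_mt_per_cond),
    list(name = "MT2", order = "MT", range = rorder[2], n = n_mt_per_cond))
  trials <- with_seed(seed, do.call(rbind, lapply(blocks, function(b) {
    bands <- ranges[[b$range]]
    df <- expand.grid(target_band = bands,
                      rep = seq_len(b$n), KEEP.OUT.ATTRS = FALSE)
    df$present <- df$rep <= b$n / 2
    df$muted_band <- NA_integer_
    for (i in which(df$present))
      df$muted_band[i] <- sample(setdiff(bands, df$target_band[i]), 1)
    df <- df[sample.int(nrow(df)), ]
    df$block <- b$name
    df$order <- b$order
    df$range <- b$range
    df
  })))
  range_map <- lapply(stats::setNames(blocks, vapply(blocks, `[[`, "",
                                                     "name")),
                      function(b) ranges[[b$range]])
  finalize_design(trials, layout, experiment = 2L, version = 2L,
                  range_map = range_map, seed = seed)
}

# Shared bookkeeping: active-band sets, edge classification, per-trial seeds.
finalize_design <- function(trials, layout, experiment, version, range_map,
                            seed) {
  n <- nrow(trials)
  rownames(trials) <- NULL
  trials$trial <- seq_len(n)
  trials$experiment <- experiment
  if (is.null(trials$range)) trials$range <- NA_character_
  active <- vector("list", n)
  for (i in seq_len(n)) {
    bands <- range_map[[trials$block[i]]]
    others <- setdiff(bands, trials$target_band[i])
    if (experiment == 2L && trials$present[i])
      others <- setdiff(others, trials$muted_band[i])
    if (experiment == 1L && version == 2L && trials$present[i])
      others <- setdiff(others, trials$muted_band[i])
    active[[i]] <- sort(if (trials$present[i])
      c(trials$target_band[i], others) else others)
  }
  trials$active_bands <- vapply(active, paste, "", collapse = ",")
  trials$edge_class <- vapply(seq_len(n), function(i)
    classify_edge(trials$target_band[i], active[[i]],
                  range_map[[trials$block[i]]]), "")
  trials$seed <- derive_seed(seed, trials$trial)
  cols <- c("experiment", "block", "trial", "order", "range", "target_band",
            "present", "muted_band", "active_bands", "edge_class", "seed")
  structure(list(trials = trials[, cols], layout = layout,
                 experiment = experiment, version = version,
                 range_map = range_map, seed = seed),
            class = "edge_design")
}

#' @export
print.edge_design <- function(x, ...) {
  cat(sprintf("Experiment %d design (version %d): %d trials, seed %d\n",
              x$experiment, x$version, nrow(x$trials), x$seed))
  print(table(order = x$trials$order, present = x$trials$present))
  invisible(x)
}

#' Classify a trial's target position in the auditory scene
#'
#' A target is an absolute edge if its band is the lowest or highest of the
#' block's frequency range; a relative edge if muting has left no active
#' band beyond it on one side, so an interior band becomes the extreme of
#' the mixture; and center if active bands lie both above and below it.
#' Classification is by design (the target band's hypothetical position),
#' so target-absent trials are classified the same way.
#'
#' @param target_band Target band index.
#' @param active_bands Integer vector of bands active in the mixture (may or
#'   may not include the target).
#' @param range_bands Bands of the block's frequency range.
#' @return One of "absolute_edge", "relative_edge", "center".
#' @export
classify_edge <- function(target_band, active_bands, range_bands) {
  if (target_band %in% c(min(range_bands), max(range_bands)))
    return("absolute_edge")
  others <- setdiff(active_bands, target_band)
  if (length(others) == 0) return("absolute_edge")
  if (target_band < min(others) || target_band > max(others))
    return("relative_edge")
  "center"
}

#' Parse the comma-separated active-band column of a manifest
#' @param x Character vector as stored in `trials$active_bands`.
#' @return List of integer vectors.
#' @export
parse_active_bands <- function(x) {
  lapply(strsplit(x, ","), as.integer)
}

#' Render one trial to audio
#'
#' Draws fresh melodies for every active band from the trial's recorded seed
#' (so a trial is reproducible in isolation), aligns all melodies to the
#' common A-weighted presentation level, and mixes them. The cue is the
#' target-band melody in isolation; on present trials the identical melody
#' (frequencies and timing) is embedded in the mixture, on absent trials it
#' is drawn but withheld and the target band stays silent.
#'
#' @param design An `edge_design`.
#' @param trial Trial number (row of `design$trials`).
#' @param rate_hz Sampling rate (default 44100).
#' @param amplitude Per-melody synthesis peak before alignment (default 0.05).
#' @param target_dba,cal_dbfs_spl Passed to [align_levels()].
#' @return List with `cue` and `mixture` [waveform()]s and `spec` (the
#'   manifest row).
#' @export
render_trial <- function(design, trial, rate_hz = 44100, amplitude = 0.05,
                         target_dba = 40, cal_dbfs_spl = 100) {
  stopifnot(inherits(design, "edge_design"))
  spec <- design$trials[design$trials$trial == trial, ]
  if (nrow(spec) != 1) stop("no such trial")
  active <- parse_active_bands(spec$active_bands)[[1]]
  melodies <- with_seed(spec$seed, {
    bands <- sort(unique(c(spec$target_band, active)))
    stats::setNames(lapply(bands, function(k) make_melody(design$layout, k)),
                    bands)
  })
  waves <- lapply(melodies, synthesize_melody, rate_hz = rate_hz,
                  amplitude = amplitude)
  waves <- align_levels(waves, target_dba = target_dba,
                        cal_dbfs_spl = cal_dbfs_spl)
  cue <- waves[[as.character(spec$target_band)]]
  mixture <- mix_waveforms(waves[as.character(active)])
  list(cue = cue, mixture = mixture, spec = spec)
}
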