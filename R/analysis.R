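#' Aggregate yes/no responses into hit and false-alarm counts
#'
#' Groups a response table into cells and counts target-present trials,
#' hits, target-absent trials and false alarms. With `center_only = TRUE`
#' target-present trials classified as relative edges are excluded before
#' counting (the split-range analysis considers a mid-band target only when
#' active bands lie both above and below it).
#'
#' @param responses A `response_table` (see [simulate_responses()]) or any
#'   data frame with columns `present`, `response`, `edge_class` and the
#'   grouping columns.
#' @param by Character vector of grouping columns.
#' @param center_only Exclude relative-edge present trials (default FALSE).
#' @return Data frame with the grouping columns plus `n_present`, `hits`,
#'   `n_absent`, `fas`, `hit_rate`, `fa_rate`.
#' @export
compute_rates <- function(responses,
                          by = c("participant", "order", "target_band"),
                          center_only = FALSE) {
  miss <- setdiff(c(by, "present", "response"), names(responses))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (center_only)
    responses <- responses[!(responses$present &
                               responses$edge_class == "relative_edge"), ]
  counts <- stats::aggregate(
    cbind(n_present = responses$present,
          hits = responses$present & responses$response,
          n_absent = !responses$present,
          fas = !responses$present & responses$response),
    by = responses[by], FUN = sum)
  counts$hit_rate <- counts$hits / counts$n_present
  counts$fa_rate <- counts$fas / counts$n_absent
  counts[do.call(order, counts[by]), , drop = FALSE]
}

#' Yes/no sensitivity d-prime from counts
#'
#' Equal-variance signal-detection sensitivity d' = z(hit rate) -
#' z(false-alarm rate). The default log-linear correction adds 0.5 to each
#' count and 1 to each total before taking rates, so perfect rates stay
#' finite; `"clamp"` instead clips rates to [1/(2N), 1 - 1/(2N)]; `"none"`
#' applies no correction (infinite at perfect rates).
#'
#' @param hits,n_present,fas,n_absent Counts (vectorised).
#' @param correction "loglinear" (default), "clamp" or "none".
#' @return d' (numeric vector).
#' @examples
#' dprime(5, 10, 5, 10)                    # 0
#' dprime(840, 1000, 160, 1000, "none")    # ~1.989
#' @export
dprime <- function(hits, n_present, fas, n_absent,
                   correction = c("loglinear", "clamp", "none")) {
  correction <- match.arg(correction)
  if (any(n_present == 0) || any(n_absent == 0))
    stop("d-prime undefined for cells with zero trials")
  if (any(hits > n_present) || any(fas > n_absent))
    stop("counts exceed totals")
  hf <- switch(correction,
    loglinear = cbind((hits + 0.5) / (n_present + 1),
                      (fas + 0.5) / (n_absent + 1)),
    clamp = cbind(pmin(pmax(hits / n_present, 1 / (2 * n_present)),
                       1 - 1 / (2 * n_present)),
                  pmin(pmax(fas / n_absent, 1 / (2 * n_absent)),
                       1 - 1 / (2 * n_absent))),
    none = cbind(hits / n_present, fas / n_absent))
  stats::qnorm(hf[, 1]) - stats::qnorm(hf[, 2])
}

#' Per-cell d-prime table from a response table
#'
#' Convenience wrapper: [compute_rates()] then [dprime()], carrying along
#' per-participant covariate columns (`msi_perception`, `msi_training`)
#' when present, and labelling each cell as an edge or mid band within its
#' frequency range.
#'
#' @inheritParams compute_rates
#' @param correction Passed to [dprime()].
#' @return Data frame with grouping columns, counts, `dprime`, and `edge`
#'   (logical: band is the lowest or highest of its range) when the grouping
#'   includes `target_band`.
#' @export
dprime_table <- function(responses,
                         by = intersect(c("participant", "order", "range",
                                          "target_band"), names(responses)),
                         correction = "loglinear", center_only = FALSE) {
  by <- by[vapply(by, function(b) length(unique(responses[[b]])) > 0 &&
                    !all(is.na(responses[[b]])), logical(1))]
  tab <- compute_rates(responses, by = by, center_only = center_only)
  tab$dprime <- dprime(tab$hits, tab$n_present, tab$fas, tab$n_absent,
                       correction = correction)
  if ("target_band" %in% by) {
    if ("range" %in% by && !all(is.na(tab$range))) {
      lim <- lapply(split(responses$target_band, responses$range), range)
      tab$edge <- mapply(function(b, r)
        b %in% lim[[r]], tab$target_band, tab$range)
    } else {
      tab$edge <- tab$target_band %in% range(responses$target_band)
    }
  }
  if ("participant" %in% by &&
      all(c("msi_perception", "msi_training") %in% names(responses))) {
    msi <- unique(responses[c("participant", "msi_perception",
                              "msi_training")])
    tab <- merge(tab, msi, by = "participant", sort = FALSE)
  }
  tab[do.call(order, tab[by]), , drop = FALSE]
}

#' Percentile bootstrap confidence interval over sampling units
#'
#' Resamples the supplied per-unit values (participants, in this pipeline)
#' with replacement `B` times and returns the percentile interval of the
#' statistic.
#'
#' @param x Numeric vector of per-unit values (length >= 2).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param B Number of resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Numeric `c(low, high)` with attribute `boot_mean`.
#' @export
bootstrap_ci <- function(x, statistic = mean, B = 10000, level = 0.95,
                         seed = NULL) {
  n <- length(x)
  if (n < 2) stop("bootstrap CI needs at least 2 sampling units")
  run <- function() {
    stat <- if (identical(statistic, mean)) {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      colMeans(matrix(x[idx], nrow = n))
    } else {
      replicate(B, statistic(x[sample.int(n, n, replace = TRUE)]))
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
    attr(ci, "boot_mean") <- mean(stat)
    ci
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Edge-effect contrast: edge bands minus mid bands
#'
#' The study's headline statistic: the difference between mean d' for
#' targets in the lowest/highest band of the frequency range and mean d'
#' for targets in between. Positive values mean an edge advantage. With a
#' `participant` column the contrast is computed per participant and
#' summarised over the cohort with a percentile bootstrap CI; without one
#' the plain contrast of the supplied cell values is returned.
#'
#' @param dp Data frame with columns `dprime` and logical `edge` (e.g. from
#'   [dprime_table()]), optionally `participant`.
#' @param B,level,seed Bootstrap settings (see [bootstrap_ci()]); `B = 0`
#'   skips the CI.
#' @return Object of class `edge_effect_result`: list with `delta` (cohort
#'   mean contrast), `per_participant` (or NULL), `ci`.
#' @examples
#' edge_effect(data.frame(dprime = c(2.54, 1.93), edge = c(TRUE, FALSE)))
#' @export
edge_effect <- function(dp, B = 10000, level = 0.95, seed = NULL) {
  stopifnot(all(c("dprime", "edge") %in% names(dp)))
  contrast <- function(d)
    mean(d$dprime[d$edge]) - mean(d$dprime[!d$edge])
  if ("participant" %in% names(dp) && length(unique(dp$participant)) > 1) {
    per <- vapply(split(dp, dp$participant), contrast, numeric(1))
    ci <- if (B > 0) bootstrap_ci(per, B = B, level = level, seed = seed)
    structure(list(delta = mean(per), per_participant = per, ci = ci),
              class = "edge_effect_result")
  } else {
    structure(list(delta = contrast(dp), per_participant = NULL, ci = NULL),
              class = "edge_effect_result")
  }
}

#' @export
print.edge_effect_result <- function(x, ...) {
  cat(sprintf("Edge effect (edge - mid): %+.3f d' units\n", x$delta))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] over %d participants\n",
                x$ci[1], x$ci[2], length(x$per_participant)))
  invisible(x)
}

#' Order-effect contrast: Target-Mixture minus Mixture-Target
#'
#' Difference in mean d' between the two presentation orders; positive
#' values mean the cued (Target-Mixture) order is easier. Same conventions
#' as [edge_effect()].
#'
#' @param dp Data frame with columns `dprime` and `order` ("TM"/"MT"),
#'   optionally `participant`.
#' @inheritParams edge_effect
#' @return Object of class `edge_effect_result` (delta = TM - MT).
#' @export
order_effect <- function(dp, B = 10000, level = 0.95, seed = NULL) {
  stopifnot(all(c("dprime", "order") %in% names(dp)))
  contrast <- function(d)
    mean(d$dprime[d$order == "TM"]) - mean(d$dprime[d$order == "MT"])
  if ("participant" %in% names(dp) && length(unique(dp$participant)) > 1) {
    per <- vapply(split(dp, dp$participant), contrast, numeric(1))
    ci <- if (B > 0) bootstrap_ci(per, B = B, level = level, seed = seed)
    structure(list(delta = mean(per), per_participant = per, ci = ci),
              class = "edge_effect_result")
  } else {
    structure(list(delta = contrast(dp), per_participant = NULL, ci = NULL),
              class = "edge_effect_result")
  }
}

#' Squared correlation between participant sensitivity and a covariate
#'
#' @param d Per-participant mean d' values.
#' @param covariate Matching covariate scores (e.g. a Gold-MSI subscale).
#' @return Squared Pearson correlation (scalar).
#' @export
covariate_r2 <- function(d, covariate) {
  if (length(d) != length(covariate) || length(d) < 3)
    stop("need matched vectors of at least 3 participants")
  if (stats::sd(covariate) == 0 || stats::sd(d) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(d, covariate)^2
}
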