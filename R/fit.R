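#' Fit the edge-salience analysis to a response table
#'
#' The full statistical chain of the melody-detection paradigm in one call:
#' per-participant hit/false-alarm rates, d' per (participant, order, band)
#' cell, cohort cell means with percentile bootstrap CIs over participants,
#' the per-participant edge-effect statistic (mean d' in the outermost bands
#' minus mean d' in the bands between) and order-effect statistic
#' (Target-Mixture minus Mixture-Target), and a linear mixed model of cell
#' d' on order, edge position, their interaction, band, and
#' musical-sophistication covariates, with participant random intercepts.
#' For the split-range experiment, mid-band d' cells use only trials where
#' the target was truly embedded in the center of the active scene, and the
#' within-band relative-edge hit-rate analysis is added.
#'
#' @param responses A `response_table` (from [simulate_responses()] or read
#'   with [read_responses()]).
#' @param experiment 1 or 2; inferred from the table when NULL.
#' @param correction Extreme-rate correction for [dprime()].
#' @param B Bootstrap resamples for all CIs (default 10000).
#' @param seed Seed for the bootstrap streams.
#' @return Object of class `edge_salience_fit` with components `cells`
#'   (cohort d' per order x band with CIs), `participant_cells`,
#'   `edge_effect`, `edge_effect_by_order`, `order_effect`, `model`
#'   (an `edge_model_fit`), `covariates` (R-squared table or NULL),
#'   `hit_rate_edge` (experiment 2 only), `experiment`, `n_participants`.
#' @examples
#' des <- build_experiment1(band_layout(), 4, 4, seed = 1)
#' resp <- simulate_responses(observer_params(), des, 8, seed = 2)
#' fit <- edge_salience(resp, B = 200, seed = 3)
#' fit
#' @export
edge_salience <- function(responses, experiment = NULL,
                          correction = "loglinear", B = 10000, seed = NULL) {
  if (is.null(experiment))
    experiment <- unique(responses$experiment)
  stopifnot(length(experiment) == 1, experiment %in% 1:2)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  center_only <- experiment == 2

  pc <- dprime_table(responses, correction = correction,
                     center_only = center_only)
  n_participants <- length(unique(pc$participant))

  # cohort d' per (order, range, band): mean of participant cells + CI
  cell_by <- intersect(c("order", "range", "target_band"), names(pc))
  cell_by <- cell_by[!vapply(cell_by, function(b) all(is.na(pc[[b]])),
                             logical(1))]
  groups <- split(pc, pc[cell_by], drop = TRUE)
  cells <- do.call(rbind, Map(
    function(d, i) {
      ci <- if (B > 0 && nrow(d) > 1)
        bootstrap_ci(d$dprime, B = B, seed = derive_seed(seed, 100 + i))
      else c(NA, NA)
      cbind(d[1, cell_by, drop = FALSE],
            data.frame(dprime = mean(d$dprime), ci_low = ci[1],
                       ci_high = ci[2], edge = d$edge[1],
                       n = nrow(d)))
    }, groups, seq_along(groups)))
  rownames(cells) <- NULL
  cells <- cells[do.call(order, cells[cell_by]), ]

  ee <- edge_effect(pc, B = B, seed = derive_seed(seed, 2))
  ee_order <- lapply(split(pc, pc$order), edge_effect, B = B,
                     seed = derive_seed(seed, 3))
  oe <- order_effect(pc, B = B, seed = derive_seed(seed, 4))
  model <- fit_mixed_model(pc)

  covariates <- NULL
  if (all(c("msi_perception", "msi_training") %in% names(pc)) &&
      stats::sd(pc$msi_training) > 0) {
    per <- stats::aggregate(
      cbind(dprime = pc$dprime, msi_perception = pc$msi_perception,
            msi_training = pc$msi_training),
      by = pc["participant"], FUN = mean)
    covariates <- data.frame(
      covariate = c("msi_perception", "msi_training"),
      r2 = c(covariate_r2(per$dprime, per$msi_perception),
             covariate_r2(per$dprime, per$msi_training)))
  }

  hre <- NULL
  if (experiment == 2)
    hre <- hit_rate_edge_analysis(responses, B = B,
                                  seed = derive_seed(seed, 5))

  structure(list(cells = cells, participant_cells = pc, edge_effect = ee,
                 edge_effect_by_order = ee_order, order_effect = oe,
                 model = model, covariates = covariates,
                 hit_rate_edge = hre, experiment = experiment,
                 n_participants = n_participants, correction = correction,
                 B = B, seed = seed, call = match.call()),
            class = "edge_salience_fit")
}

#' @export
print.edge_salience_fit <- function(x, ...) {
  cat(sprintf("Edge-salience fit: experiment %d, %d participants\n",
              x$experiment, x$n_participants))
  cat(sprintf("  order effect (TM - MT): %+.2f d'", x$order_effect$delta))
  if (!is.null(x$order_effect$ci))
    cat(sprintf("  [%.2f, %.2f]", x$order_effect$ci[1], x$order_effect$ci[2]))
  cat(sprintf("\n  edge effect (edge - mid): %+.2f d'", x$edge_effect$delta))
  if (!is.null(x$edge_effect$ci))
    cat(sprintf("  [%.2f, %.2f]", x$edge_effect$ci[1], x$edge_effect$ci[2]))
  cat("\n")
  for (o in names(x$edge_effect_by_order))
    cat(sprintf("    %s: %+.2f d'\n", o, x$edge_effect_by_order[[o]]$delta))
  invisible(x)
}

#' @export
summary.edge_salience_fit <- function(object, ...) {
  print(object)
  cat("\nCohort d' by cell:\n")
  out <- object$cells
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 2)
  print(out, row.names = FALSE)
  cat("\n")
  print(object$model)
  if (!is.null(object$covariates)) {
    cat("\nCovariate R-squared (participant mean d' vs Gold-MSI):\n")
    print(transform(object$covariates, r2 = round(r2, 3)),
          row.names = FALSE)
  }
  if (!is.null(object$hit_rate_edge)) {
    cat("\n")
    print(object$hit_rate_edge)
  }
  invisible(object)
}

#' @export
coef.edge_salience_fit <- function(object, ...) coef(object$model)

#' @export
residuals.edge_salience_fit <- function(object, ...)
  stats::residuals(object$model$fit, ...)

#' @export
predict.edge_salience_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$model$fit, ...)
  else stats::predict(object$model$fit, newdata = newdata, ...)
}

#' Plot cohort sensitivity by band and presentation order
#'
#' Base-graphics rendition of the detection profile: cohort mean d' per
#' frequency band, one line per presentation order (split-range fits are
#' panelled by range), with bootstrap 95% CI error bars.
#'
#' @param x An `edge_salience_fit`.
#' @param ... Passed to [graphics::matplot()]-style underlying calls.
#' @return `x`, invisibly.
#' @export
plot.edge_salience_fit <- function(x, ...) {
  cells <- x$cells
  panels <- if ("range" %in% names(cells)) split(cells, cells$range)
            else list(all = cells)
  old <- graphics::par(mfrow = c(1, length(panels)))
  on.exit(graphics::par(old))
  for (nm in names(panels)) {
    p <- panels[[nm]]
    ylim <- range(c(p$ci_low, p$ci_high, p$dprime), na.rm = TRUE)
    graphics::plot(NA, xlim = range(p$target_band), ylim = ylim,
                   xlab = "frequency band", ylab = "d'",
                   main = if (nm == "all") "" else paste(nm, "range"), ...)
    for (o in unique(p$order)) {
      d <- p[p$order == o, ]
      d <- d[order(d$target_band), ]
      pch <- if (o == "TM") 15 else 16
      graphics::lines(d$target_band, d$dprime, type = "b", pch = pch)
      graphics::arrows(d$target_band, d$ci_low, d$target_band, d$ci_high,
                       angle = 90, code = 3, length = 0.03)
    }
    graphics::legend("bottomleft", legend = unique(p$order),
                     pch = c(15, 16)[seq_along(unique(p$order))], bty = "n")
  }
  invisible(x)
}
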