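#' Mixed-effects model of sensitivity
#'
#' Fits the study's linear mixed model: participant-cell d' regressed on
#' presentation order (Mixture-Target as reference, so a positive
#' coefficient means the cued order helps), edge position (binary), their
#' interaction, frequency band (numeric), musical-sophistication subscale
#' scores when available, and — for the split-range experiment — a binary
#' low/high range predictor; with a random intercept per participant.
#' A trial-level binomial variant (`response = "trial"`) regresses
#' trial-by-trial accuracy on the same predictors via a logit GLMM.
#'
#' @param x A participant-cell d' table from [dprime_table()] (default
#'   response) or a raw `response_table` (`response = "trial"`).
#' @param response "dprime" or "trial".
#' @param extra Additional fixed-effect terms (character), e.g. "range01".
#' @return Object of class `edge_model_fit`: list with `coefficients` (data
#'   frame: estimate, se, statistic, p), `formula`, `ranef_sd`, `fit` (the
#'   underlying lmerTest/lme4 fit).
#' @export
fit_mixed_model <- function(x, response = c("dprime", "trial"),
                            extra = character()) {
  response <- match.arg(response)
  dat <- as.data.frame(x)
  if (response == "trial") {
    stopifnot(all(c("response", "present", "target_band") %in% names(dat)))
    dat$acc <- as.numeric(dat$response == dat$present)
    if (!"edge" %in% names(dat))
      dat$edge <- dat$edge_class == "absolute_edge"
  } else {
    stopifnot(all(c("dprime", "edge") %in% names(dat)))
  }
  dat$order01 <- as.numeric(dat$order == "TM")
  dat$edge01 <- as.numeric(dat$edge)
  if ("range" %in% names(dat) && !all(is.na(dat$range)))
    dat$range01 <- as.numeric(dat$range == "high")
  terms <- c("order01", "edge01", "order01:edge01")
  if ("target_band" %in% names(dat)) {
    dat$band_num <- as.numeric(dat$target_band)
    terms <- c(terms, "band_num")
  }
  if ("range01" %in% names(dat)) terms <- c(terms, "range01")
  for (m in c("msi_perception", "msi_training"))
    if (m %in% names(dat) && stats::sd(dat[[m]]) > 0) terms <- c(terms, m)
  terms <- unique(c(terms, extra))
  lhs <- if (response == "trial") "acc" else "dprime"
  fml <- stats::as.formula(paste(lhs, "~", paste(terms, collapse = " + "),
                                 "+ (1 | participant)"))
  if (response == "trial") {
    fit <- lme4::glmer(fml, data = dat, family = stats::binomial())
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], statistic = co[, 3], p = co[, 4],
                        row.names = NULL)
  } else {
    fit <- lmerTest::lmer(fml, data = dat)
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"],
                        statistic = co[, "t value"],
                        p = co[, "Pr(>|t|)"], row.names = NULL)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs, formula = fml,
                 ranef_sd = vc$sdcor[vc$grp == "participant"][1],
                 fit = fit),
            class = "edge_model_fit")
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat("Mixed-model fit:", deparse(x$formula), "\n")
  out <- x$coefficients
  out[-1] <- lapply(out[-1], round, 4)
  print(out, row.names = FALSE)
  cat(sprintf("participant random-intercept SD: %.3f\n", x$ranef_sd))
  invisible(x)
}

#' @export
coef.edge_model_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Within-band hit-rate analysis of relative edges
#'
#' Split-range experiment only. Target-present trials in the inner bands of
#' each range are split into relative edges (an adjacent outer band was
#' muted, leaving the target at the extreme of the active scene) versus
#' center (active bands on both sides). Because the cue and target band are
#' identical across the two classes, a hit-rate difference isolates the
#' relative position of the band in the scene. Hits are modelled with a
#' logit GLMM (hit ~ relative-edge + order + band + range, random intercept
#' per participant), and class-wise cohort hit rates get percentile
#' bootstrap CIs over participants.
#'
#' @param responses A `response_table` from the split-range design.
#' @param B,level,seed Bootstrap settings for the class-wise rates.
#' @return List of class `hit_rate_edge_result`: `model` (an
#'   `edge_model_fit`), `rates` (data frame: class, hit rate, CI).
#' @export
hit_rate_edge_analysis <- function(responses, B = 10000, level = 0.95,
                                   seed = NULL) {
  dat <- responses[responses$present &
                     responses$edge_class %in% c("relative_edge", "center"), ]
  if (!nrow(dat)) stop("no present trials in inner-band classes")
  if (!all(c("relative_edge", "center") %in% unique(dat$edge_class)))
    stop("a relative-edge class has no trials")
  dat$rel01 <- as.numeric(dat$edge_class == "relative_edge")
  dat$hit <- as.numeric(dat$response)
  dat$order01 <- as.numeric(dat$order == "TM")
  dat$band_num <- as.numeric(dat$target_band)
  terms <- c("rel01", "order01", "band_num")
  if ("range" %in% names(dat) && !all(is.na(dat$range))) {
    dat$range01 <- as.numeric(dat$range == "high")
    terms <- c(terms, "range01")
  }
  fml <- stats::as.formula(paste("hit ~", paste(terms, collapse = " + "),
                                 "+ (1 | participant)"))
  fit <- lme4::glmer(fml, data = dat, family = stats::binomial())
  co <- summary(fit)$coefficients
  model <- structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], statistic = co[, 3],
                              p = co[, 4], row.names = NULL),
    formula = fml,
    ranef_sd = as.data.frame(lme4::VarCorr(fit))$sdcor[1],
    fit = fit), class = "edge_model_fit")
  rates <- do.call(rbind, lapply(split(dat, dat$edge_class), function(d) {
    per <- vapply(split(d$hit, d$participant), mean, numeric(1))
    ci <- if (B > 0 && length(per) > 1)
      bootstrap_ci(per, B = B, level = level, seed = seed) else c(NA, NA)
    data.frame(edge_class = d$edge_class[1], hit_rate = mean(per),
               ci_low = ci[1], ci_high = ci[2],
               n_participants = length(per), n_trials = nrow(d))
  }))
  rownames(rates) <- NULL
  structure(list(model = model, rates = rates),
            class = "hit_rate_edge_result")
}

#' @export
print.hit_rate_edge_result <- function(x, ...) {
  cat("Within-band relative-edge hit-rate analysis\n")
  r <- x$rates
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-13s hit rate %.2f  [%.2f, %.2f]\n", r$edge_class[i],
                r$hit_rate[i], r$ci_low[i], r$ci_high[i]))
  print(x$model)
  invisible(x)
}

#' Adjacent versus non-adjacent muted-band contrast
#'
#' Constant-density (version 2) six-band trials only: on target-present
#' trials one nontarget band was muted; this contrasts detection when the
#' muted band was adjacent to the target band against when it was not,
#' with an interaction by presentation order. A null contrast indicates
#' that local spectral edges created by muting (and, by extension,
#' energetic masking from immediate neighbours) did not drive detection.
#' Participant-cell hit rates are modelled with a linear mixed model.
#'
#' @param responses A `response_table` with muting metadata.
#' @return An `edge_model_fit`; the `adjacent01` row is the contrast.
#' @export
adjacent_muting_contrast <- function(responses) {
  dat <- responses[responses$present & !is.na(responses$muted_band), ]
  if (!nrow(dat)) stop("no muted present trials (need a version-2 design)")
  dat$adjacent <- abs(dat$muted_band - dat$target_band) == 1
  cells <- stats::aggregate(
    cbind(hit_rate = as.numeric(dat$response)),
    by = dat[c("participant", "order", "adjacent")], FUN = mean)
  cells$adjacent01 <- as.numeric(cells$adjacent)
  cells$order01 <- as.numeric(cells$order == "TM")
  fit <- lmerTest::lmer(
    hit_rate ~ adjacent01 * order01 + (1 | participant), data = cells)
  co <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                              se = co[, "Std. Error"],
                              statistic = co[, "t value"],
                              p = co[, "Pr(>|t|)"], row.names = NULL),
    formula = hit_rate ~ adjacent01 * order01 + (1 | participant),
    ranef_sd = as.data.frame(lme4::VarCorr(fit))$sdcor[1],
    fit = fit), class = "edge_model_fit")
}
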