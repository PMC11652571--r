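# Rates, d-prime arithmetic, contrasts, bootstrap, covariates.

test_that("rate aggregation partitions trials and respects the design", {
  des <- small_design1(seed = 61)
  resp <- rigged_responses(des, accuracy = 1, n_participants = 2)
  rt <- compute_rates(resp, by = c("participant", "order", "target_band"))
  expect_true(all(rt$hit_rate == 1 & rt$fa_rate == 0))
  expect_equal(sum(rt$n_present + rt$n_absent), 2 * nrow(des$trials))
  expect_true(all(rt$n_present == rt$n_absent))   # counterbalancing
  # an all-yes observer has unit hit and false-alarm rates
  resp$response <- TRUE
  rt2 <- compute_rates(resp, by = "participant")
  expect_true(all(rt2$hit_rate == 1 & rt2$fa_rate == 1))
  expect_error(compute_rates(resp[, -3], by = "nonexistent"), "missing")
})

test_that("a random responder converges to rate one half", {
  des <- build_experiment1(paper_layout(), 40, 40, seed = 62)
  params <- observer_params(dprime_map = c(TM.edge = 0, TM.mid = 0,
                                           MT.edge = 0, MT.mid = 0),
                            participant_sd = 0)
  resp <- simulate_responses(params, des, 5, seed = 63)
  rt <- compute_rates(resp, by = "participant")
  # binomial oracle: SE of a rate at p = 0.5 with n trials
  n <- rt$n_present[1]
  expect_true(all(abs(rt$hit_rate - 0.5) < 4 * sqrt(0.25 / n)))
  expect_true(all(abs(rt$fa_rate - 0.5) < 4 * sqrt(0.25 / n)))
})

test_that("d-prime arithmetic matches the inverse-normal oracle", {
  expect_equal(dprime(5, 10, 5, 10), 0)
  # uncorrected rates 0.84 / 0.16 at large n
  expect_equal(dprime(840000, 1e6, 160000, 1e6, correction = "none"),
               qnorm(0.84) - qnorm(0.16), tolerance = 1e-12)
  expect_equal(qnorm(0.84) - qnorm(0.16), 1.98892, tolerance = 1e-5)
  # log-linear correction keeps perfect performance finite:
  # d' = z(10.5/11) - z(0.5/11) = 2 z(10.5/11) ~= 3.3812
  expect_equal(dprime(10, 10, 0, 10), 2 * qnorm(10.5 / 11), tolerance = 1e-12)
  expect_equal(dprime(10, 10, 0, 10), 3.38124, tolerance = 1e-4)
  expect_true(is.finite(dprime(10, 10, 0, 10, correction = "clamp")))
  expect_error(dprime(1, 0, 0, 10), "zero trials")
  expect_error(dprime(11, 10, 0, 10), "exceed")
})

test_that("d-prime is antisymmetric in hits and false alarms", {
  for (h in c(3, 7, 10)) for (f in c(0, 2, 5)) {
    expect_equal(dprime(h, 10, f, 10), -dprime(f, 10, h, 10))
  }
})

test_that("edge and order contrasts reproduce printed-mean arithmetic", {
  # grand means: edge 2.54 vs mid 1.93 -> 0.61 edge advantage
  e1 <- edge_effect(data.frame(dprime = c(2.54, 1.93),
                               edge = c(TRUE, FALSE)))
  expect_equal(e1$delta, 0.61, tolerance = 1e-12)
  # orders: TM 2.68 vs MT 1.58 -> 1.10
  o1 <- order_effect(data.frame(dprime = c(2.68, 1.58),
                                order = c("TM", "MT")))
  expect_equal(o1$delta, 1.10, tolerance = 1e-12)
  # a participant better at mid frequencies has a negative (reversed) effect
  rev <- edge_effect(data.frame(dprime = c(2.0, 2.26),
                                edge = c(TRUE, FALSE)))
  expect_equal(rev$delta, -0.26, tolerance = 1e-12)
  # identical means give zero
  expect_equal(edge_effect(data.frame(dprime = c(2, 2),
                                      edge = c(TRUE, FALSE)))$delta, 0)
})

test_that("edge effect is invariant to participant intercepts", {
  set.seed(7)
  dp <- data.frame(participant = rep(1:6, each = 4),
                   dprime = rnorm(24, 2, 0.3),
                   edge = rep(c(TRUE, TRUE, FALSE, FALSE), 6))
  shifted <- dp
  shifted$dprime <- dp$dprime + rep(rnorm(6, 0, 5), each = 4)
  a <- edge_effect(dp, B = 0)
  b <- edge_effect(shifted, B = 0)
  expect_equal(a$per_participant, b$per_participant, tolerance = 1e-12)
  expect_equal(a$delta, b$delta, tolerance = 1e-12)
})

test_that("bootstrap CIs behave like the closed-form standard error", {
  expect_equal(as.numeric(bootstrap_ci(rep(3, 10), B = 500, seed = 1)),
               c(3, 3))
  set.seed(2)
  x <- rnorm(100)
  ci <- bootstrap_ci(x, B = 10000, seed = 3)
  # oracle: mean +/- 1.96 / sqrt(100) for a standard normal sample
  expect_equal(ci[1], mean(x) - 1.96 * sd(x) / 10, tolerance = 0.05)
  expect_equal(ci[2], mean(x) + 1.96 * sd(x) / 10, tolerance = 0.05)
  expect_error(bootstrap_ci(1), "at least 2")
  # seeded and reproducible, without touching the global stream
  expect_identical(bootstrap_ci(x, B = 200, seed = 9),
                   bootstrap_ci(x, B = 200, seed = 9))
})

test_that("bootstrap CI width shrinks like one over sqrt(n)", {
  set.seed(4)
  widths <- vapply(c(25, 100, 400), function(n) {
    x <- rnorm(n)
    ci <- bootstrap_ci(x, B = 4000, seed = n)
    ci[2] - ci[1]
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("covariate R-squared has its closed-form extremes", {
  d <- c(1.2, 1.8, 2.4, 2.0, 2.9)
  expect_equal(covariate_r2(d, d), 1)
  expect_equal(covariate_r2(d, 10 - 2 * d), 1)
  set.seed(5)
  expect_lt(covariate_r2(rnorm(2000), rnorm(2000)), 0.01)
  expect_error(covariate_r2(d, rep(1, 5)), "zero-variance")
  expect_error(covariate_r2(d[1:2], d[1:2]), "at least 3")
})

test_that("split-range mid cells use only center-classified present trials", {
  des <- small_design2(seed = 66)
  resp <- simulate_responses(exp2_observer_params(participant_sd = 0),
                             des, 4, seed = 67)
  all_cells <- compute_rates(resp, by = c("participant", "target_band"),
                             center_only = FALSE)
  ctr_cells <- compute_rates(resp, by = c("participant", "target_band"),
                             center_only = TRUE)
  inner <- ctr_cells$target_band %in% 2:5
  expect_true(all(ctr_cells$n_present[inner] <=
                    all_cells$n_present[all_cells$target_band %in% 2:5]))
  # absent counts are untouched by the exclusion
  expect_equal(ctr_cells$n_absent, all_cells$n_absent)
  expect_lt(sum(ctr_cells$n_present), sum(all_cells$n_present))
})
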