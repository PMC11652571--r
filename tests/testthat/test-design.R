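# Trial-list construction, counterbalancing, muting and edge bookkeeping.

test_that("six-band design has the paper block sizes and exact counterbalancing", {
  des <- build_experiment1(paper_layout(), seed = 1)
  tr <- des$trials
  expect_equal(sum(tr$order == "TM"), 120)
  expect_equal(sum(tr$order == "MT"), 240)
  counts <- table(tr$order, tr$target_band, tr$present)
  expect_true(all(counts["TM", , "TRUE"] == 10))
  expect_true(all(counts["TM", , "FALSE"] == 10))
  expect_true(all(counts["MT", , "TRUE"] == 20))
  expect_true(all(counts["MT", , "FALSE"] == 20))
  expect_error(build_experiment1(paper_layout(), n_tm_per_cond = 5),
               "counterbalancing")
})

test_that("version 2 keeps density at five bands; version 1 does not mute", {
  des2 <- small_design1(seed = 5, version = 2)
  act2 <- parse_active_bands(des2$trials$active_bands)
  expect_true(all(lengths(act2) == 5))
  pres <- des2$trials$present
  expect_true(all(!is.na(des2$trials$muted_band[pres])))
  expect_true(all(des2$trials$muted_band[pres] !=
                    des2$trials$target_band[pres]))
  expect_true(all(is.na(des2$trials$muted_band[!pres])))
  # absent trials: target band silent, all other five active
  for (i in which(!pres))
    expect_identical(act2[[i]],
                     setdiff(1:6, des2$trials$target_band[i]))

  des1 <- small_design1(seed = 5, version = 1)
  act1 <- parse_active_bands(des1$trials$active_bands)
  expect_true(all(lengths(act1)[des1$trials$present] == 6))
  expect_true(all(lengths(act1)[!des1$trials$present] == 5))
  expect_true(all(is.na(des1$trials$muted_band)))
})

test_that("muted bands are chosen uniformly among the five candidates", {
  # chi-square goodness of fit over many seeded designs
  tab <- integer(6)
  for (s in 1:40) {
    tr <- build_experiment1(paper_layout(), 6, 6, seed = s)$trials
    m <- tr$muted_band[tr$present & tr$target_band == 3]
    tab <- tab + tabulate(m, 6)
  }
  expect_equal(tab[3], 0)   # never the target band
  expect_gt(chisq.test(tab[-3])$p.value, 0.01)
})

test_that("split-range design has the paper totals and density three", {
  des <- build_experiment2(paper_layout(), seed = 2)
  tr <- des$trials
  expect_equal(sum(tr$order == "TM"), 160)
  expect_equal(sum(tr$order == "MT"), 320)
  expect_true(all(lengths(parse_active_bands(tr$active_bands)) == 3))
  expect_setequal(unique(tr$target_band[tr$range == "low"]), 1:4)
  expect_setequal(unique(tr$target_band[tr$range == "high"]), 3:6)
  counts <- table(tr$order, tr$range, tr$target_band, tr$present)
  expect_true(all(counts["TM", "low", 1:4, ] == 10))
  expect_true(all(counts["MT", "high", 3:6, ] == 20))
  # range order is counterbalanced by start_range
  lo <- build_experiment2(paper_layout(), 2, 2, start_range = "low",
                          seed = 3)$trials
  hi <- build_experiment2(paper_layout(), 2, 2, start_range = "high",
                          seed = 3)$trials
  expect_equal(unique(lo$range[lo$block == "TM1"]), "low")
  expect_equal(unique(hi$range[hi$block == "TM1"]), "high")
})

test_that("edge classification distinguishes absolute, relative and center", {
  expect_equal(classify_edge(1, 1:5, 1:6), "absolute_edge")
  expect_equal(classify_edge(6, 2:6, 1:6), "absolute_edge")
  # range 1-4, target 2, band 1 muted: target becomes the lowest active band
  expect_equal(classify_edge(2, c(2, 3, 4), 1:4), "relative_edge")
  expect_equal(classify_edge(3, c(2, 3, 4), 1:4), "center")
  # absent trial, classification by design
  expect_equal(classify_edge(2, c(1, 3, 4), 1:4), "center")
  # high range 3-6: band 4 with band 3 muted becomes the lowest active
  expect_equal(classify_edge(4, c(4, 5, 6), 3:6), "relative_edge")
  expect_equal(classify_edge(3, c(3, 4, 5), 3:6), "absolute_edge")
})

test_that("manifest edge classes are consistent with active bands", {
  tr <- small_design2(seed = 9)$trials
  act <- parse_active_bands(tr$active_bands)
  for (i in seq_len(nrow(tr))) {
    rng <- if (tr$range[i] == "low") 1:4 else 3:6
    expect_equal(tr$edge_class[i],
                 classify_edge(tr$target_band[i], act[[i]], rng))
  }
  # relative edges exist and only in inner bands
  rel <- tr$edge_class == "relative_edge"
  expect_gt(sum(rel), 0)
  expect_true(all(tr$target_band[rel & tr$range == "low"] %in% 2:3))
  expect_true(all(tr$target_band[rel & tr$range == "high"] %in% 4:5))
})

test_that("designs are reproducible from their seed", {
  a <- build_experiment1(paper_layout(), 4, 4, seed = 77)$trials
  b <- build_experiment1(paper_layout(), 4, 4, seed = 77)$trials
  expect_identical(a, b)
  c <- build_experiment1(paper_layout(), 4, 4, seed = 78)$trials
  expect_false(identical(a$target_band, c$target_band))
})

test_that("rendered trials embed the cue exactly when present, silence when absent", {
  des <- small_design1(seed = 31, n_tm = 2, n_mt = 2)
  tr <- des$trials
  ipresent <- which(tr$present)[1]
  iabsent <- which(!tr$present)[1]
  rp <- render_trial(des, tr$trial[ipresent], rate_hz = 16000)
  ra <- render_trial(des, tr$trial[iabsent], rate_hz = 16000)
  # present: cue waveform is contained additively in the mixture, so
  # subtracting it removes all energy in the target band
  lay <- des$layout
  band_energy <- function(w, k) {
    r <- band_range(lay, k)
    spec <- Mod(fft(w$samples))^2
    f <- (seq_along(spec) - 1) * w$rate_hz / length(spec)
    sum(spec[f >= r[1] * 0.97 & f <= r[2] * 1.03])
  }
  kp <- tr$target_band[ipresent]
  resid <- waveform(rp$mixture$samples - rp$cue$samples, 16000)
  expect_lt(band_energy(resid, kp) / band_energy(rp$mixture, kp), 1e-6)
  # absent: the target band of the mixture is empty, but the cue is not
  ka <- tr$target_band[iabsent]
  expect_lt(band_energy(ra$mixture, ka) / band_energy(ra$cue, ka), 1e-3)
  # all rendered melodies aligned: re-measure the cue level
  expect_equal(a_weight_level(rp$cue), -60, tolerance = 0.01)
})
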