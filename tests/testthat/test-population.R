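test_that("fast/delayed classification uses a strict less-than rule", {
  expect_equal(classifyFastDelayed(1.0, 1.71), "fast")
  expect_equal(classifyFastDelayed(1.71, 1.71), "delayed")  # tie rule
  expect_equal(classifyFastDelayed(numeric(0), 1.71), character(0))
  expect_equal(classifyFastDelayed(c(0.5, 1.71, 3), 1.71),
               c("fast", "delayed", "delayed"))
  expect_error(classifyFastDelayed(c(1, NA), 1.71), "finite")
})

test_that("neuron tiers partition amplitudes exactly at the printed
           boundaries", {
  expect_equal(classifyNeuronTier(c(1.91, 1.92, 3.46, 3.47)),
               c("low", "mid", "mid", "high"))
  expect_equal(classifyNeuronTier(1.0), "low")
  expect_equal(classifyNeuronTier(0), "low")
  expect_error(classifyNeuronTier(-0.1), ">= 0")
  # every amplitude lands in exactly one tier
  set.seed(71)
  amps <- c(runif(200, 0, 6), 1.92, 3.47)
  tiers <- classifyNeuronTier(amps)
  expect_true(all(tiers %in% c("low", "mid", "high")))
  expect_equal(sum(tiers == "low") + sum(tiers == "mid") +
               sum(tiers == "high"), length(amps))
  expect_true(all(amps[tiers == "low"] < 1.92))
  expect_true(all(amps[tiers == "mid"] >= 1.92 & amps[tiers == "mid"] <
                  3.47))
  expect_true(all(amps[tiers == "high"] >= 3.47))
})

test_that("compartment assignment labels manual regions and defaults to
           process", {
  lin <- function(r, cc) (cc - 1L) * 20L + r
  soma <- as.vector(outer(2:5, 2:5, lin))
  free <- as.vector(outer(12:14, 12:14, lin))
  rois <- makeRoiSet(10, 20, 20, list(soma, free), list(1:2, 3:4))
  manual <- matrix(0L, 20, 20)
  manual[2:5, 2:5] <- 1L
  masks <- CompartmentMasks(manual, c("1" = "endfoot"))
  out <- assignCompartments(rois, masks)
  expect_equal(roiInfo(out)$compartment, c("endfoot", "process"))
  # without masks everything is process; counts are conserved
  out2 <- assignCompartments(rois)
  expect_equal(roiInfo(out2)$compartment, c("process", "process"))
  expect_equal(sum(table(roiInfo(out)$compartment)), nROIs(rois))
})

test_that("barrel-area normalization is the stated ratio", {
  expect_equal(roisPerBarrelArea(8, 64000), 4)
  expect_equal(roisPerBarrelArea(13, 32000), 13)   # identity at 32k um2
  expect_equal(roisPerBarrelArea(0, 50000), 0)
  # linear in count, inversely linear in FOV area
  expect_equal(roisPerBarrelArea(6, 48000), 3 * roisPerBarrelArea(2, 48000))
  expect_equal(roisPerBarrelArea(6, 96000),
               roisPerBarrelArea(6, 48000) / 2)
  expect_error(roisPerBarrelArea(1, 0), "> 0")
})

test_that("active-pixel fraction counts set intersections", {
  astro <- matrix(FALSE, 10, 10); astro[3:8, 3:8] <- TRUE
  expect_equal(activePixelFraction(astro, astro), 1)
  none <- matrix(FALSE, 10, 10); none[1, 1] <- TRUE
  expect_equal(activePixelFraction(none, astro), 0)
  half <- matrix(FALSE, 10, 10); half[3:8, 3:5] <- TRUE
  expect_equal(activePixelFraction(half, astro), 0.5)
  expect_error(activePixelFraction(astro, matrix(FALSE, 10, 10)), "empty")
})

test_that("trial response maps and repeated-response scores match counting
           oracles", {
  astro <- matrix(TRUE, 8, 8)
  m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
  same4 <- list(m, m, m, m)
  expect_equal(repeatedResponseScore(same4, astro, 2), 9 / 64)
  expect_true(all(trialResponseMap(same4) %in% c(0, 1)))
  # active in exactly 1 of 4 trials contributes nothing at min_trials = 2
  single <- list(m, matrix(FALSE, 8, 8), matrix(FALSE, 8, 8),
                 matrix(FALSE, 8, 8))
  expect_equal(repeatedResponseScore(single, astro, 2), 0)
  expect_equal(max(trialResponseMap(single)), 0.25)
  # random masks vs the per-pixel counting oracle
  set.seed(72)
  masks <- lapply(1:5, function(i) matrix(runif(64) < 0.3, 8, 8))
  astro2 <- matrix(runif(64) < 0.7, 8, 8)
  for (mt in 1:4)
    expect_equal(repeatedResponseScore(masks, astro2, mt),
                 oracleRepeatScore(masks, astro2, mt))
  # non-increasing in min_trials
  scores <- vapply(1:5, function(mt)
    repeatedResponseScore(masks, astro2, mt), numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_error(repeatedResponseScore(masks, matrix(FALSE, 8, 8), 2),
               "empty")
})

test_that("pairwise synchrony reproduces the textbook correlation", {
  fps <- 10
  proto <- TrialProtocol(trial_len_s = 15)
  nT <- 150
  set.seed(73)
  base <- rnorm(nT)
  mk <- function(v, id) makeTrace(v, fps = fps, roiId = id)
  tr1 <- mk(base, 1); tr2 <- mk(base, 2); tr3 <- mk(-base, 3)
  out <- pairwiseSynchrony(list(tr1, tr2, tr3), proto)
  expect_equal(out$r[out$roi_i == 1 & out$roi_j == 2], 1)
  expect_equal(out$r[out$roi_i == 1 & out$roi_j == 3], -1)
  expect_true(all(out$included))
  # random pairs vs the naive-loop oracle
  set.seed(74)
  traces <- lapply(1:4, function(i) mk(rnorm(nT), i))
  out2 <- pairwiseSynchrony(traces, proto)
  sel <- which((seq_len(nT) - 1) / fps >= 5 & (seq_len(nT) - 1) / fps < 13)
  for (k in seq_len(nrow(out2))) {
    x <- dff(traces[[out2$roi_i[k]]])[sel]
    y <- dff(traces[[out2$roi_j[k]]])[sel]
    expect_lt(abs(out2$r[k] - oraclePearson(x, y)), 1e-12)
  }
  # zero-variance trace in the window: excluded with a flag
  tz <- mk(c(rnorm(50), rep(0, 100)), 9)
  out3 <- pairwiseSynchrony(list(tr1, tz), proto)
  expect_equal(out3$flag, "zero_variance")
  expect_false(any(out3$included))
  expect_error(pairwiseSynchrony(list(tr1), proto), ">= 2")
})

test_that("synchrony on traces with known common-signal mixing recovers the
           analytic correlation", {
  # X_i = s + e_i with var(s) = v, var(e) = 1 - v: expected r = v
  fps <- 100
  proto <- TrialProtocol(baseline_s = 1, stim_onset_s = 1,
                         analysis_window_s = 100, trial_len_s = 102)
  params <- ClassificationParams(corr_window = c(0, 100))
  nT <- 101 * fps
  v <- 0.4
  set.seed(75)
  s <- rnorm(nT, 0, sqrt(v))
  traces <- lapply(1:3, function(i)
    makeTrace(s + rnorm(nT, 0, sqrt(1 - v)), fps = fps, baselineS = 1,
              roiId = i))
  out <- pairwiseSynchrony(traces, proto, params)
  expect_equal(mean(out$r), v, tolerance = 0.05)
  expect_equal(synchronySummary(list(out)), mean(out$r[out$included]))
  # pooled and per-trial summaries agree for a single trial
  expect_equal(synchronySummary(list(out), "pooled"),
               synchronySummary(list(out), "per_trial"))
})

test_that("corrected total fluorescence formulas", {
  expect_equal(computeCTCF(1000, 50, 2), 900)
  expect_equal(computeCTCF(1234, 10, 0), 1234)   # zero background
  expect_equal(computeCTCF(50 * 3, 50, 3), 0)    # null case
  expect_equal(computeCTFF(1000, 100, 2), 800)
  expect_equal(computeCTFF(777, 5, 0), 777)
  expect_error(computeCTCF(1, -2, 1), ">= 0")
  expect_error(computeCTFF(1, 2, NA), "is.finite")
})

test_that("FOV summaries aggregate counts consistently", {
  lin <- function(r, cc) (cc - 1L) * 16L + r
  rois <- makeRoiSet(10, 16, 16,
                     list(as.vector(outer(2:4, 2:4, lin)),
                          as.vector(outer(9:11, 9:11, lin))),
                     list(1:3, 5:8), pixelSize = 2)
  rois <- assignCompartments(rois)
  events <- data.frame(roi_id = c(1, 2), amplitude_dff = c(1.5, 4),
                       peak_time_s = c(6, 7), onset_latency_s = c(1, 2),
                       auc = c(3, 4), in_stim_window = TRUE)
  astro <- matrix(TRUE, 16, 16)
  active <- matrix(FALSE, 16, 16); active[1:8, ] <- TRUE
  s <- fovSummary(rois, events, active, astro)
  expect_equal(s$n_rois, 2L)
  expect_equal(s$n_process, 2L)
  expect_equal(s$fov_area_um2, 16 * 16 * 4)
  expect_equal(s$rois_per_barrel_area,
               roisPerBarrelArea(2, 16 * 16 * 4))
  expect_equal(s$n_low, 1L)
  expect_equal(s$n_high, 1L)
  expect_equal(s$active_pixel_fraction, 0.5)
})
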