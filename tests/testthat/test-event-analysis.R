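test_that("dF/F extraction is exact for known modulations", {
  ny <- 16; nx <- 16; nT <- 100; fps <- 10
  fp <- which(diskFootprint(ny, nx, 8, 8, 2.5))
  rois <- makeRoiSet(fps, ny, nx, list(fp), list(10:20))
  proto <- TrialProtocol(analysis_window_s = 5, trial_len_s = 10)
  # raw equal to F0 throughout: dff all zeros
  mv0 <- MovieStack(array(50, c(nT, ny, nx)), fps, 1)
  tr0 <- extractDff(mv0, rois, proto)[[1]]
  expect_true(all(dff(tr0) == 0))
  # raw = F0 * (1 + g(t)): dff = g(t) exactly
  g <- 0.5 * sin(seq_len(nT) / 7)
  g[1:50] <- 0  # flat baseline window
  arr <- array(80, c(nT, ny, nx))
  for (t in seq_len(nT)) arr[t, , ] <- 80 * (1 + g[t])
  tr <- extractDff(MovieStack(arr, fps, 1), rois, proto)[[1]]
  expect_equal(dff(tr), g, tolerance = 1e-12)
  # planted event at zero noise: max(dff) equals the amplitude
  truth <- makeEventTruth(fps = 10, onset = 6, rise = 0.5, amp = 1.7,
                          noise = 0)
  mvE <- generateMovie(truth)$movie
  roisE <- makeRoiSet(10, 32, 32, list(which(truth@events[[1]]@footprint)),
                      list(61:80))
  trE <- extractDff(mvE, roisE, truth@protocol)[[1]]
  expect_lt(abs(max(dff(trE)) - 1.7), 1e-9)
  # nonpositive baseline is an error naming the ROI
  bad <- MovieStack(array(0, c(nT, ny, nx)) , fps, 1)
  expect_error(extractDff(bad, rois, proto), "ROI 1")
})

test_that("dF/F is invariant to a multiplicative gain on the movie", {
  truth <- makeEventTruth(fps = 10, amp = 2, noise = 3, seed = 9)
  mv <- generateMovie(truth)$movie
  rois <- makeRoiSet(10, 32, 32, list(which(truth@events[[1]]@footprint)),
                     list(61:80))
  tr1 <- extractDff(mv, rois, truth@protocol)[[1]]
  mv2 <- MovieStack(frames(mv) * 3.7, 10, 1)
  tr2 <- extractDff(mv2, rois, truth@protocol)[[1]]
  expect_equal(dff(tr1), dff(tr2), tolerance = 1e-12)
})

test_that("peak detection finds forced events and matches the naive scan",
{
  # monotone flat trace: no events
  expect_equal(nrow(detectEvents(makeTrace(rep(0, 80)))), 0L)
  # one triangular bump of height 3 over a sd-0.1 baseline
  set.seed(61)
  base <- rnorm(50, 0, 0.1)
  bump <- c(seq(0, 3, length.out = 10), seq(3, 0, length.out = 10)[-1])
  x <- c(base, bump, rnorm(20, 0, 0.1))
  tr <- makeTrace(x)
  ev <- detectEvents(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_dff, 3, tolerance = 1e-9)
  # two bumps separated by a deep dip: two events
  x2 <- c(base, bump, rep(0, 5), bump, rnorm(10, 0, 0.1))
  ev2 <- detectEvents(makeTrace(x2))
  expect_equal(nrow(ev2), 2L)
  # random smooth traces agree with the naive oracle
  for (seed in 1:5) {
    set.seed(seed)
    y <- stats::filter(rnorm(150), rep(1 / 5, 5), sides = 2)
    y[is.na(y)] <- 0
    trR <- makeTrace(as.numeric(y))
    got <- detectEvents(trR)$peak_frame
    want <- oraclePeaks(as.numeric(y), 2.5 * trR@baselineSd,
                        2 * trR@baselineSd)
    expect_equal(got, want)
  }
  # degenerate zero-SD baseline falls back to the absolute floor
  xz <- c(rep(0, 60), bump, rep(0, 20))
  evz <- detectEvents(makeTrace(xz))
  expect_equal(nrow(evz), 1L)
})

test_that("onset latency follows the smoothed first-crossing rule", {
  fps <- 10
  proto <- TrialProtocol(trial_len_s = 15)
  # never exceeding the threshold: undefined
  set.seed(62)
  flat <- makeTrace(rnorm(150, 0, 0.01), fps = fps)
  expect_true(is.na(onsetLatency(flat, proto)))
  expect_equal(attr(onsetLatency(flat, proto), "reason"), "no_crossing")
  # a step exactly at frame k after onset, no smoothing: latency = k / fps
  set.seed(63)
  x <- rnorm(150, 0, 0.02)
  k <- 7L
  stepFrame <- 51L + k  # stim onset 5 s = 0-based frame 50
  x[stepFrame:150] <- x[stepFrame:150] + 10 * sd(x[1:50])
  lat <- onsetLatency(makeTrace(x, fps = fps), proto,
                      EventParams(smooth_frames = 1))
  expect_equal(lat, k / fps)
  # ramp with 5-frame smoothing matches the hand-rolled oracle
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(150, 0, 0.05)
    y[60:150] <- y[60:150] + seq(0, 3, length.out = 91)
    trR <- makeTrace(y, fps = fps)
    expect_equal(onsetLatency(trR, proto, EventParams()),
                 oracleOnset(y, fps, 5, 5, 5, 2.5))
  }
  # degenerate baseline
  z <- c(rep(0, 60), seq(0, 2, length.out = 90))
  latz <- onsetLatency(makeTrace(z, fps = fps), proto)
  expect_true(is.na(latz))
  expect_equal(attr(latz, "reason"), "degenerate_baseline")
})

test_that("onset latency is non-decreasing in the SD multiplier", {
  proto <- TrialProtocol(trial_len_s = 15)
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(150, 0, 0.05)
    y[70:150] <- y[70:150] + seq(0, 1.5, length.out = 81)
    tr <- makeTrace(y)
    lats <- vapply(c(1.5, 2.5, 4, 6), function(m) {
      l <- onsetLatency(tr, proto, EventParams(onset_sd_mult = m))
      if (is.na(l)) Inf else l
    }, numeric(1))
    expect_true(all(diff(lats) >= 0))
  }
})

test_that("the adaptation slope is the OLS slope over 0.5-1 s after
           stimulus", {
  fps <- 13.84
  proto <- TrialProtocol()
  nT <- 346
  times <- (seq_len(nT) - 1) / fps
  # exact line dff = 2 - 1 * (t - stim onset): slope -1
  y <- 2 - (times - 5)
  expect_equal(adaptationSlope(makeTrace(y, fps = fps), proto), -1,
               tolerance = 1e-9)
  # constant: slope 0
  expect_equal(adaptationSlope(makeTrace(rep(1, nT), fps = fps), proto), 0)
  # too few frames in the window: error
  slowTr <- makeTrace(rep(1, 20), fps = 1)
  expect_error(adaptationSlope(slowTr, proto), ">= 2")
  # noisy line over many seeds: mean recovers truth, SE matches theory
  sel <- which(times >= 5.5 & times < 6)
  sigma <- 0.3
  slopes <- vapply(1:1000, function(s) {
    set.seed(s)
    yn <- y + rnorm(nT, 0, sigma)
    adaptationSlope(makeTrace(yn, fps = fps), proto)
  }, numeric(1))
  seTheory <- sigma / sqrt(sum((times[sel] - mean(times[sel]))^2))
  expect_lt(abs(mean(slopes) + 1), 3 * seTheory / sqrt(1000) * 4)
  expect_lt(abs(sd(slopes) - seTheory) / seTheory, 0.1)
})

test_that("trapezoidal AUC equals the analytic integral of piecewise-linear
           traces", {
  fps <- 10
  proto <- TrialProtocol(trial_len_s = 15)
  nT <- 150
  times <- (seq_len(nT) - 1) / fps
  # triangle: 0 at 5 s, rises to 2 at 9 s, back to 0 at 13 s
  y <- numeric(nT)
  up <- times >= 5 & times <= 9
  dn <- times > 9 & times <= 13
  y[up] <- (times[up] - 5) / 4 * 2
  y[dn] <- (13 - times[dn]) / 4 * 2
  tr <- makeTrace(y, fps = fps)
  got <- aucTrace(tr, proto, "window")
  # window frames run 5.0 ... 12.9 s; the trapezoid rule is exact on a
  # piecewise-linear curve sampled at its breakpoints
  a <- 4 * 2 / 2                      # rising half, [5, 9]
  b <- (2 + y[130]) / 2 * (12.9 - 9)  # falling part to the last frame
  expect_equal(got, a + b, tolerance = 1e-9)
})

test_that("the event table combines metrics with the stimulation-window
           flag", {
  truth <- makeEventTruth(fps = 10, onset = 7, rise = 0.5, amp = 2,
                          noise = 2, seed = 64)
  mv <- generateMovie(truth)$movie
  det <- detectMicrodomains(mv, detectionParams())
  traces <- extractDff(mv, det$rois, truth@protocol)
  tab <- buildEventTable(traces, truth@protocol, EventParams())
  expect_gte(nrow(tab), 1L)
  expect_true(all(c("roi_id", "amplitude_dff", "peak_time_s",
                    "onset_latency_s", "auc", "in_stim_window") %in%
                  names(tab)))
  expect_true(all(tab$in_stim_window))
  expect_equal(tab$amplitude_dff[1], 2, tolerance = 0.15)
  expect_equal(tab$onset_latency_s[1], 2, tolerance = 0.4)
})
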