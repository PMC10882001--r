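test_that("boxcar statistics match hand computation and a brute-force
           oracle", {
  # constant movie: mean = c, sd = 0 everywhere
  mov <- MovieStack(array(7, c(12, 4, 4)), frameRate = 1, pixelSize = 1)
  bs <- boxcarStats(mov, boxcar_s = 5)
  expect_true(all(bs$mean == 7))
  expect_true(all(bs$sd == 0))
  # single pixel trace 1..5, 3-frame centered window at the middle frame
  tr <- array(0, c(5, 1, 1)); tr[, 1, 1] <- 1:5
  bs2 <- boxcarStats(MovieStack(tr, frameRate = 1, pixelSize = 1),
                     boxcar_s = 3)
  expect_equal(bs2$mean[3, 1, 1], 3)
  expect_equal(bs2$sd[3, 1, 1], 1)
  # random movie vs oracle, both alignments
  set.seed(31)
  arr <- array(rnorm(20 * 5 * 5, 100, 10), c(20, 5, 5))
  mov3 <- MovieStack(arr, frameRate = 2, pixelSize = 1)
  for (align in c("centered", "trailing")) {
    bs3 <- boxcarStats(mov3, boxcar_s = 3.5, align = align)
    w <- round(3.5 * 2)
    for (r in 1:5) for (cc in 1:5) {
      o <- oracleBoxcar(arr[, r, cc], w, align)
      expect_lt(max(abs(bs3$mean[, r, cc] - o$mean)), 1e-9)
      expect_lt(max(abs(bs3$sd[, r, cc] - o$sd), na.rm = TRUE), 1e-9)
      expect_identical(is.nan(bs3$sd[, r, cc]), is.nan(o$sd))
    }
  }
  expect_error(boxcarStats(mov3, boxcar_s = 1), ">= 3 frames")
  expect_error(boxcarStats(mov3, boxcar_s = 30), "longer than movie")
})

test_that("per-pixel robust noise SD matches its oracle and ignores
           transients", {
  set.seed(32)
  arr <- array(rnorm(60 * 3 * 3, 50, 4), c(60, 3, 3))
  arr[20:26, 2, 2] <- arr[20:26, 2, 2] + 200  # a large transient
  mov <- MovieStack(arr, frameRate = 10, pixelSize = 1)
  ns <- pixelNoiseSd(mov)
  for (r in 1:3) for (cc in 1:3)
    expect_equal(ns[r, cc], oracleNoiseSd(arr[, r, cc]), tolerance = 1e-12)
  # the transient pixel's estimate stays near the true noise scale
  expect_lt(abs(ns[2, 2] - 4), 2.5)
})

test_that("active-pixel classification obeys the amplitude and rise-time
           gates", {
  # noise-free constant movie: no active pixels (strict inequality)
  mov <- MovieStack(array(5, c(60, 6, 6)), frameRate = 10, pixelSize = 1)
  expect_false(any(detectActivePixels(mov, detectionParams())))
  # planted event, high SNR, rise 0.3 s: footprint pixels become active
  truth <- makeEventTruth(fps = 10, onset = 8, rise = 0.3, decay = 0.8,
                          amp = 2, noise = 2, seed = 5)
  mv <- generateMovie(truth)$movie
  mask <- detectActivePixels(mv, detectionParams("invivo-astro"))
  fp <- which(truth@events[[1]]@footprint)
  flat <- matrix(mask, nFrames(mv), 32 * 32)
  expect_true(all(colSums(flat[, fp]) > 0))
  # active times lie within the event's span
  tAct <- which(rowSums(flat) > 0)
  expect_true(all(tAct / 10 >= truth@events[[1]]@onset_s - 0.2))
  # a slow-rise event is rejected under the fast in vivo RCaMP bounds
  slow <- makeEventTruth(fps = 10, onset = 6, rise = 2.5, decay = 1,
                         amp = 2, noise = 2, seed = 6)
  mvSlow <- generateMovie(slow)$movie
  expect_false(any(detectActivePixels(mvSlow,
                                      detectionParams("invivo-neuro"))))
})

test_that("raising the SD multiplier never adds active pixels", {
  for (seed in 1:3) {
    truth <- makeEventTruth(fps = 10, onset = 7, amp = 1.2, noise = 4,
                            seed = seed)
    mv <- generateMovie(truth)$movie
    lo <- detectActivePixels(mv, detectionParams(amp_sd_mult = 5))
    hi <- detectActivePixels(mv, detectionParams(amp_sd_mult = 7))
    expect_true(all(lo[hi]))  # hi-threshold actives are a subset
  }
})

test_that("spatiotemporal grouping matches the exact pairwise closure", {
  # two pixels 3 um apart in the same frame: one component
  mk <- function(coords, nT = 6, ny = 20, nx = 20) {
    m <- array(FALSE, c(nT, ny, nx))
    for (i in seq_len(nrow(coords)))
      m[coords[i, 1], coords[i, 2], coords[i, 3]] <- TRUE
    m
  }
  m1 <- mk(rbind(c(3, 10, 5), c(3, 10, 8)))
  g1 <- groupActivePixels(m1, 4, 0.5, 1, 10)
  expect_equal(max(g1), 1L)
  # 10 um apart: two components
  m2 <- mk(rbind(c(3, 10, 5), c(3, 10, 15)))
  expect_equal(max(groupActivePixels(m2, 4, 0.5, 1, 10)), 2L)
  # separated in time beyond the gap: two components
  m3 <- mk(rbind(c(1, 10, 5), c(6, 10, 5)))
  expect_equal(max(groupActivePixels(m3, 4, 0.2, 1, 10)), 2L)
  # random sparse masks vs the union-find oracle, incl. sub-pixel radius
  for (cfg in list(list(r = 4, gap = 0.5), list(r = 1.2, gap = 0.3),
                   list(r = 0.9, gap = 0.2))) {
    set.seed(100 + cfg$r * 10)
    nT <- 12; ny <- 15; nx <- 15
    mask <- array(runif(nT * ny * nx) < 0.08, c(nT, ny, nx))
    labs <- groupActivePixels(mask, cfg$r, cfg$gap, 1, 10)
    vox <- which(mask, arr.ind = TRUE)
    vox <- data.frame(t = vox[, 1], row = vox[, 2], col = vox[, 3])
    expect_lte(nrow(vox), 500)
    oracleRoots <- oracleGroup(vox, cfg$r, floor(cfg$gap * 10 + 1e-9))
    got <- labs[cbind(vox$t, vox$row, vox$col)]
    # identical partitions up to label renaming
    expect_equal(length(unique(got)), length(unique(oracleRoots)))
    expect_true(all(tapply(oracleRoots, got,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("ROI construction projects, normalizes and thresholds
           components", {
  # component active in all frames over a square: ROI = that square
  comp <- array(0L, c(10, 12, 12))
  comp[, 3:6, 3:6] <- 1L
  rs <- buildRoiMask(comp, pixel_size_um = 2)
  expect_equal(nROIs(rs), 1L)
  expect_equal(sort(footprints(rs)[[1]]),
               which(outer(1:12 %in% 3:6, 1:12 %in% 3:6, FUN = "&")))
  expect_equal(roiInfo(rs)$area_px, 16L)
  expect_equal(roiInfo(rs)$area_um2, 64)
  expect_equal(activeFrames(rs)[[1]], 1:10)
  # a pixel active 1 of 10 frames (max 10), q = 0.2: excluded
  comp2 <- array(0L, c(10, 8, 8))
  comp2[, 4, 4] <- 1L        # core pixel: 10 active frames
  comp2[1, 4, 5] <- 1L       # fringe pixel: 1 of 10 -> 0.1 < 0.2
  comp2[1:3, 4, 3] <- 1L     # 0.3 >= 0.2 -> kept
  rs2 <- buildRoiMask(comp2)
  fp <- footprints(rs2)[[1]]
  expect_true(((3L - 1L) * 8L + 4L) %in% fp)   # (4,3) kept
  expect_false(((5L - 1L) * 8L + 4L) %in% fp)  # (4,5) dropped
  # empty-footprint components are dropped with a log entry
  expect_equal(nROIs(buildRoiMask(array(0L, c(4, 4, 4)))), 0L)
})

test_that("the ANOVA filter retains real events and rejects degenerate
           ROIs", {
  set.seed(41)
  # planted ROI at 5x noise SD on a flat background: retained, tiny p
  truth <- makeEventTruth(fps = 10, onset = 7, amp = 1, noise = 5,
                          base = 100, seed = 41)
  mv <- generateMovie(truth)$movie
  fp <- which(truth@events[[1]]@footprint)
  rois <- makeRoiSet(10, 32, 32, list(fp), list(71:90))
  out <- filterFalsePositives(mv, rois, 0.05, 2)
  expect_equal(nROIs(out), 1L)
  expect_lt(roiInfo(out)$fp_pvalue, 1e-6)
  # zero-variance degenerate comparison: p = 1 convention, removed
  lin <- function(r, cc) (cc - 1L) * 16L + r
  flat <- MovieStack(array(10, c(20, 16, 16)), 10, 1)
  roisFlat <- makeRoiSet(10, 16, 16, list(as.vector(outer(7:9, 7:9, lin))),
                         list(1:5))
  expect_equal(nROIs(filterFalsePositives(flat, roisFlat, 0.05, 2)), 0L)
  # surround consumed by other ROIs: retained with 'untestable' flag
  inner <- as.vector(outer(7:9, 7:9, lin))
  ring <- setdiff(as.vector(outer(4:12, 4:12, lin)), inner)
  set.seed(42)
  noisy <- MovieStack(array(rnorm(20 * 16 * 16, 100, 5), c(20, 16, 16)),
                      10, 1)
  rois2 <- makeRoiSet(10, 16, 16, list(inner, ring), list(1:5, 1:5))
  expect_warning(out2 <- filterFalsePositives(noisy, rois2, 0.05, 2),
                 "no testable surround")
  expect_true("untestable" %in% roiInfo(out2)$fp_flag)
})

test_that("manual-mask deduplication removes exactly the overlap", {
  lin <- function(r, cc) (cc - 1L) * 20L + r
  auto1 <- as.vector(outer(2:5, 2:5, lin))    # fully inside manual
  auto2 <- as.vector(outer(14:17, 14:17, lin))  # disjoint
  auto3 <- as.vector(outer(8:11, 2:5, lin))   # half overlap (rows 8:9)
  rois <- makeRoiSet(10, 20, 20, list(auto1, auto2, auto3),
                     list(1:3, 4:6, 7:9))
  manual <- matrix(0L, 20, 20)
  manual[1:9, 1:6] <- 1L
  masks <- CompartmentMasks(manual, c("1" = "soma"))
  out <- excludeManualOverlap(rois, masks)
  expect_equal(nROIs(out), 2L)
  expect_equal(sort(footprints(out)[[1]]), sort(auto2))
  expect_equal(sort(footprints(out)[[2]]),
               sort(setdiff(auto3, which(manual > 0))))
  expect_equal(roiInfo(out)$area_px, c(16L, 8L))
  # no manual pixels: identity
  none <- CompartmentMasks(matrix(0L, 20, 20), character())
  expect_equal(nROIs(excludeManualOverlap(rois, none)), 3L)
})

test_that("detection is deterministic and survives a temporal-shuffle
           null", {
  truth <- randomSyntheticTruth(seed = 51, nEvents = 6, ny = 80, nx = 80)
  mv <- generateMovie(truth)$movie
  d1 <- detectMicrodomains(mv, detectionParams())
  d2 <- detectMicrodomains(mv, detectionParams())
  expect_identical(labelImage(d1$rois), labelImage(d2$rois))
  expect_identical(roiInfo(d1$rois), roiInfo(d2$rois))
  expect_gte(nROIs(d1$rois), 5L)
  # shuffling frames destroys rise-time structure: fewer ROIs survive
  set.seed(52)
  nShuffledRois <- vapply(1:3, function(i) {
    arr <- frames(mv)[sample(nFrames(mv)), , ]
    sh <- MovieStack(arr, frameRate = frameRate(mv), pixelSize = 1)
    nROIs(detectMicrodomains(sh, detectionParams())$rois)
  }, integer(1))
  expect_lt(mean(nShuffledRois), nROIs(d1$rois))
})

test_that("detection parameter presets encode the channel-specific
           settings", {
  pa <- detectionParams("invivo-astro")
  expect_equal(pa@amp_sd_mult, 7)
  expect_equal(pa@rise_bounds_s, c(0.1, 1))
  expect_equal(pa@group_time_s, 0.5)
  pn <- detectionParams("invivo-neuro")
  expect_equal(pn@rise_bounds_s, c(0.07, 1))
  expect_equal(pn@group_time_s, 0.2)
  pv <- detectionParams("invitro-astro")
  expect_equal(pv@amp_sd_mult, 5)
  expect_equal(pv@rise_bounds_s, c(0.1, 8))
  expect_equal(pa@group_radius_um, 4)
  expect_equal(pa@roi_threshold_q, 0.2)
  expect_error(detectionParams(amp_sd_mult = -1), "amp_sd_mult")
})
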