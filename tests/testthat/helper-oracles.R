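# Independent brute-force oracles and tiny fixture builders. Oracles are
# deliberately naive (explicit loops, textbook formulas) and share no code
# with the package internals they check.

oracleBoxcar <- function(trace, w, align = "centered") {
  n <- length(trace)
  mu <- sdv <- numeric(n)
  for (t in seq_len(n)) {
    if (align == "centered") {
      hl <- (w - 1) %/% 2
      lo <- max(1, t - hl); hi <- min(n, t + (w - 1 - hl))
    } else {
      lo <- max(1, t - w + 1); hi <- t
    }
    win <- trace[lo:hi]
    mu[t] <- mean(win)
    sdv[t] <- if (length(win) >= 2) stats::sd(win) else NaN
  }
  list(mean = mu, sd = sdv)
}

oracleNoiseSd <- function(trace) {
  d <- numeric(length(trace) - 1)
  for (i in seq_along(d)) d[i] <- abs(trace[i + 1] - trace[i])
  stats::median(d) / (sqrt(2) * stats::qnorm(0.75))
}

# Exact pairwise single-link closure over active voxels (t, row, col).
oracleGroup <- function(vox, rPx, gapFrames) {
  n <- nrow(vox)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (abs(vox$t[i] - vox$t[j]) <= gapFrames &&
        (vox$row[i] - vox$row[j])^2 + (vox$col[i] - vox$col[j])^2 <=
          rPx^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Textbook Pearson correlation via explicit sums.
oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# Per-pixel trial counting by explicit loops.
oracleRepeatScore <- function(masks, astro, minTrials) {
  nr <- nrow(astro); nc <- ncol(astro)
  hits <- 0; denom <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!astro[r, cc]) next
    denom <- denom + 1
    cnt <- 0
    for (m in masks) if (m[r, cc]) cnt <- cnt + 1
    if (cnt >= minTrials) hits <- hits + 1
  }
  hits / denom
}

# Moving average + first-crossing scan (onset latency oracle).
oracleOnset <- function(dffVec, fps, stimOnset, baselineS, k, sdMult) {
  n <- length(dffVec)
  sm <- numeric(n)
  h <- (k - 1) %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    sm[i] <- mean(dffVec[lo:hi])
  }
  times <- (seq_len(n) - 1) / fps
  bsd <- stats::sd(sm[times < baselineS])
  for (i in seq_len(n)) {
    if (times[i] >= stimOnset && sm[i] > sdMult * bsd)
      return(times[i] - stimOnset)
  }
  NA_real_
}

# Naive peak scan: local maxima with prominence from a full left/right walk.
oraclePeaks <- function(x, minHeight, minProm) {
  n <- length(x)
  out <- integer()
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] >= x[i + 1])) next
    j <- i; while (j > 1 && x[j - 1] <= x[i]) j <- j - 1
    lmin <- min(x[j:i])
    k <- i; while (k < n && x[k + 1] <= x[i]) k <- k + 1
    rmin <- min(x[i:k])
    prom <- x[i] - max(lmin, rmin)
    if (x[i] > minHeight && prom >= minProm) out <- c(out, i)
  }
  out
}

# One planted event on a uniform baseline; kinetics aligned to frame times
# when `alignFrames` so the analytic peak lands exactly on a frame.
makeEventTruth <- function(ny = 32, nx = 32, fps = 10, trialLen = 15,
                           onset = 6, rise = 0.5, decay = 0.8, amp = 2,
                           r0 = 16, c0 = 16, radius = 3, noise = 0,
                           base = 100, seed = 1,
                           protocol = TrialProtocol(
                             baseline_s = 5, stim_onset_s = 5,
                             analysis_window_s = 8,
                             trial_len_s = trialLen)) {
  SyntheticTruth(
    events = list(PlantedEvent(diskFootprint(ny, nx, r0, c0, radius),
                               onset_s = onset, rise_s = rise,
                               decay_s = decay, amplitude_dff = amp)),
    baselineImage = matrix(base, ny, nx), noiseSd = noise,
    protocol = protocol, frameRate = fps, pixelSize = 1, seed = seed)
}

makeTrace <- function(dffVec, fps = 10, baselineS = 5, roiId = 1) {
  times <- (seq_along(dffVec) - 1) / fps
  baseFr <- which(times < baselineS)
  new("ROITrace", roiId = roiId, dff = dffVec, frameRate = fps,
      baselineMean = mean(dffVec[baseFr]),
      baselineSd = stats::sd(dffVec[baseFr]))
}

# Minimal ROISet built directly from footprints (linear pixel indices).
makeRoiSet <- function(fps, ny, nx, footprintList, activeList,
                       pixelSize = 1) {
  n <- length(footprintList)
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(n)) lab[footprintList[[i]]] <- i
  if (n == 0L)
    return(new("ROISet", labelImage = lab, footprints = list(),
               activeFrames = list(),
               info = CaMicroDomains:::.emptyRoiInfo(),
               pixelSize = pixelSize))
  info <- data.frame(id = seq_len(n),
                     area_px = lengths(footprintList),
                     area_um2 = lengths(footprintList) * pixelSize^2,
                     fp_pvalue = NA_real_, fp_flag = "",
                     compartment = "unset", channel = "other")
  new("ROISet", labelImage = lab, footprints = footprintList,
      activeFrames = activeList, info = info, pixelSize = pixelSize)
}
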