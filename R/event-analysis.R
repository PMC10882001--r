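#' @include AllClasses.R utils.R
NULL

#' Extract per-ROI dF/F traces
#'
#' Per ROI: spatial mean of the raw intensity over the footprint per frame,
#' then dF/F against the mean of that trace over the baseline window
#' (frames with time in \code{[0, baseline_s)}).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param rois an \linkS4class{ROISet}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return list of \linkS4class{ROITrace}, one per ROI.
#' @export
extractDff <- function(movie, rois, protocol = TrialProtocol()) {
  arr <- frames(movie)
  nT <- dim(arr)[1L]
  x <- matrix(arr, nT, prod(dim(arr)[2:3]))
  times <- frameTimes(movie)
  baseFr <- which(times < protocol@baseline_s)
  if (!length(baseFr)) stop("baseline window contains no frames")
  lapply(seq_len(nROIs(rois)), function(i) {
    raw <- rowMeans(x[, rois@footprints[[i]], drop = FALSE])
    f0 <- mean(raw[baseFr])
    if (f0 <= 0)
      stop("ROI ", i, " has nonpositive baseline fluorescence (F0 = ",
           signif(f0, 4), "); dF/F undefined")
    d <- (raw - f0) / f0
    new("ROITrace", roiId = i, dff = d, frameRate = frameRate(movie),
        baselineMean = mean(d[baseFr]), baselineSd = stats::sd(d[baseFr]))
  })
}

## Local maxima with prominences and base indices. A sample is a peak when
## strictly above its left neighbor and at least its right neighbor (first
## sample of a plateau wins). Prominence: height above the higher of the two
## minima separating the peak from higher ground on either side.
.findPeaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(idx = integer(), height = numeric(),
                                prominence = numeric(), left = integer(),
                                right = integer()))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
               x[2:(n - 1L)] >= x[3:n]) + 1L
  res <- lapply(idx, function(i) {
    j <- i
    leftMin <- x[i]; leftPos <- i
    while (j > 1L && x[j - 1L] <= x[i]) {
      j <- j - 1L
      if (x[j] < leftMin) { leftMin <- x[j]; leftPos <- j }
    }
    if (j == 1L && x[1L] < leftMin) { leftMin <- x[1L]; leftPos <- 1L }
    k <- i
    rightMin <- x[i]; rightPos <- i
    while (k < n && x[k + 1L] <= x[i]) {
      k <- k + 1L
      if (x[k] < rightMin) { rightMin <- x[k]; rightPos <- k }
    }
    data.frame(idx = i, height = x[i],
               prominence = x[i] - max(leftMin, rightMin),
               left = leftPos, right = rightPos)
  })
  do.call(rbind, res)
}

#' Detect Ca2+ events (peaks) in a dF/F trace
#'
#' Local maxima of dF/F with height above
#' \code{onset_sd_mult * baselineSd} and prominence at least
#' \code{peak_min_prominence_sd * baselineSd}. Tying the operating point to
#' the trace's own baseline noise keeps the detector scale-free. When the
#' baseline SD is zero (degenerate noiseless baseline) both thresholds fall
#' back to the absolute \code{prominence_floor}, with a log message.
#'
#' @param trace a \linkS4class{ROITrace}.
#' @param params an \linkS4class{EventParams}.
#' @param verbose log fallback use.
#' @return data.frame, one row per event: \code{peak_frame} (1-based),
#'   \code{peak_time_s}, \code{amplitude_dff}, \code{prominence},
#'   \code{left_base}, \code{right_base}.
#' @export
detectEvents <- function(trace, params = EventParams(), verbose = FALSE) {
  x <- dff(trace)
  bsd <- trace@baselineSd
  if (bsd == 0) {
    .logStage("events", sprintf(
      "ROI %g: zero baseline SD, using absolute prominence floor %.3g",
      trace@roiId, params@prominence_floor), verbose = verbose)
    hThr <- params@prominence_floor
    pThr <- params@prominence_floor
  } else {
    hThr <- params@onset_sd_mult * bsd
    pThr <- params@peak_min_prominence_sd * bsd
  }
  pk <- .findPeaks(x)
  pk <- pk[pk$height > hThr & pk$prominence >= pThr, , drop = FALSE]
  data.frame(peak_frame = pk$idx,
             peak_time_s = (pk$idx - 1) / frameRate(trace),
             amplitude_dff = pk$height, prominence = pk$prominence,
             left_base = pk$left, right_base = pk$right)
}

#' Onset latency of the stimulation response
#'
#' The earliest time after stimulus onset at which the smoothed dF/F trace
#' (centered moving average over \code{smooth_frames} frames, edge
#' truncated) strictly exceeds \code{onset_sd_mult} times the SD of the
#' smoothed trace over the baseline window, minus the stimulus onset.
#' Latency is reported at frame resolution (no sub-frame interpolation).
#'
#' @param trace a \linkS4class{ROITrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param params an \linkS4class{EventParams}.
#' @return Latency in seconds, or \code{NA} if the threshold is never
#'   crossed (attribute \code{"reason"} distinguishes \code{"no_crossing"}
#'   from \code{"degenerate_baseline"}).
#' @export
onsetLatency <- function(trace, protocol = TrialProtocol(),
                         params = EventParams()) {
  x <- .movingAverage(dff(trace), as.integer(params@smooth_frames))
  times <- (seq_along(x) - 1) / frameRate(trace)
  baseFr <- which(times < protocol@baseline_s)
  bsd <- stats::sd(x[baseFr])
  if (!is.finite(bsd) || bsd == 0) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate_baseline"
    return(out)
  }
  cand <- which(times >= protocol@stim_onset_s &
                x > params@onset_sd_mult * bsd)
  if (!length(cand)) {
    out <- NA_real_
    attr(out, "reason") <- "no_crossing"
    return(out)
  }
  times[cand[1L]] - protocol@stim_onset_s
}

#' Adaptation slope of the stimulus response decay
#'
#' Ordinary least-squares slope of dF/F against time over the window
#' \code{[stim_onset + w1, stim_onset + w2)} (defaults 0.5-1 s after
#' stimulus start). More negative = faster adaptation.
#'
#' @param trace a \linkS4class{ROITrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param params an \linkS4class{EventParams} (slot
#'   \code{adaptation_window_s}).
#' @return Slope in dF/F per second.
#' @export
adaptationSlope <- function(trace, protocol = TrialProtocol(),
                            params = EventParams()) {
  x <- dff(trace)
  times <- (seq_along(x) - 1) / frameRate(trace)
  w <- protocol@stim_onset_s + params@adaptation_window_s
  sel <- which(times >= w[1L] & times < w[2L])
  if (length(sel) < 2L)
    stop("adaptation window [", w[1L], ", ", w[2L], ") contains ",
         length(sel), " frame(s); need >= 2 (frame rate too low)")
  .olsSlope(times[sel], x[sel])
}

#' Area under the dF/F curve
#'
#' Trapezoidal integral of dF/F over the analysis window
#' (\code{mode = "window"}, default) or over an event span
#' (\code{mode = "event"}, frames \code{[left, right]}).
#'
#' @param trace a \linkS4class{ROITrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param mode \code{"window"} or \code{"event"}.
#' @param left,right event base frames (1-based) for event mode.
#' @return AUC in dF/F * s.
#' @export
aucTrace <- function(trace, protocol = TrialProtocol(),
                     mode = c("window", "event"), left = NULL,
                     right = NULL) {
  mode <- match.arg(mode)
  x <- dff(trace)
  times <- (seq_along(x) - 1) / frameRate(trace)
  sel <- if (mode == "window")
    which(times >= protocol@stim_onset_s &
          times < protocol@stim_onset_s + protocol@analysis_window_s)
  else left:right
  if (length(sel) < 2L) return(0)
  pracma::trapz(times[sel], x[sel])
}

#' Assemble the tidy event table for a set of traces
#'
#' One row per detected event: ROI id, amplitude, peak time, the ROI's
#' onset latency after stimulus, AUC (window or per-event mode per
#' \code{params@auc_mode}) and the in-stimulation-window flag
#' (0 < latency < analysis window).
#'
#' @param traces list of \linkS4class{ROITrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param params an \linkS4class{EventParams}.
#' @return data.frame (possibly zero rows) with columns \code{roi_id},
#'   \code{amplitude_dff}, \code{peak_time_s}, \code{onset_latency_s},
#'   \code{auc}, \code{in_stim_window}.
#' @export
buildEventTable <- function(traces, protocol = TrialProtocol(),
                            params = EventParams()) {
  rows <- lapply(traces, function(tr) {
    ev <- detectEvents(tr, params)
    if (!nrow(ev)) return(NULL)
    lat <- onsetLatency(tr, protocol, params)
    auc <- if (params@auc_mode == "window")
      rep(aucTrace(tr, protocol, "window"), nrow(ev))
    else
      vapply(seq_len(nrow(ev)), function(i)
        aucTrace(tr, protocol, "event", ev$left_base[i], ev$right_base[i]),
        numeric(1))
    data.frame(roi_id = tr@roiId, amplitude_dff = ev$amplitude_dff,
               peak_time_s = ev$peak_time_s,
               onset_latency_s = as.numeric(lat), auc = auc,
               in_stim_window = !is.na(lat) && lat > 0 &&
                 lat < protocol@analysis_window_s)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(roi_id = integer(), amplitude_dff = numeric(),
                      peak_time_s = numeric(), onset_latency_s = numeric(),
                      auc = numeric(), in_stim_window = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
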