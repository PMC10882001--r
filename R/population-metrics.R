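#' @include AllClasses.R utils.R
NULL

#' Classify microdomain onsets as fast or delayed
#'
#' A microdomain is "fast" iff its onset latency is strictly less than the
#' reference median onset latency of the neuronal population, and "delayed"
#' otherwise (a tie is delayed, since fast requires strictly less). The
#' reference median is typically computed from the responding neuronal
#' events of the same experimental group; reported cohort values can be
#' supplied directly for reproduction runs.
#'
#' @param latencies numeric vector of astrocyte onset latencies (s);
#'   undefined latencies must be excluded upstream.
#' @param reference_median_s the neuronal median onset latency (s).
#' @return character vector of \code{"fast"} / \code{"delayed"} labels.
#' @examples
#' classifyFastDelayed(c(1.0, 1.71, 2.4), reference_median_s = 1.71)
#' @export
classifyFastDelayed <- function(latencies, reference_median_s) {
  stopifnot(length(reference_median_s) == 1L,
            is.finite(reference_median_s))
  if (!length(latencies)) return(character())
  if (any(!is.finite(latencies)))
    stop("latencies must be finite; drop undefined latencies first")
  ifelse(latencies < reference_median_s, "fast", "delayed")
}

#' Classify neurons into responsiveness tiers by event amplitude
#'
#' low: amplitude < 1.92 dF/F; mid: 1.92 <= amplitude < 3.47 dF/F;
#' high: amplitude >= 3.47 dF/F (cutoffs are the 88th and 98th percentiles
#' of the control amplitude distribution). The three tiers partition
#' [0, Inf).
#'
#' @param amplitude_dff numeric vector of event amplitudes (dF/F, >= 0).
#' @param params a \linkS4class{ClassificationParams}.
#' @return character vector of \code{"low"}/\code{"mid"}/\code{"high"}.
#' @export
classifyNeuronTier <- function(amplitude_dff,
                               params = ClassificationParams()) {
  if (any(amplitude_dff < 0)) stop("amplitudes must be >= 0")
  ifelse(amplitude_dff >= params@amp_cutoff_high, "high",
         ifelse(amplitude_dff >= params@amp_cutoff_mid, "mid", "low"))
}

#' Assign compartment labels to ROIs
#'
#' Manual compartment ROIs carry their role (soma, endfoot, neuron soma);
#' every remaining activity ROI is classified as a process. An activity ROI
#' is attributed to a manual compartment if the majority of its pixels lie
#' inside it (after \code{\link{excludeManualOverlap}} no such overlap
#' remains and everything automatic becomes process).
#'
#' @param rois an \linkS4class{ROISet}.
#' @param manual a \linkS4class{CompartmentMasks}, or NULL (everything
#'   becomes process).
#' @return The \linkS4class{ROISet} with compartments filled in.
#' @export
assignCompartments <- function(rois, manual = NULL) {
  n <- nROIs(rois)
  if (n == 0L) return(rois)
  comp <- rep("process", n)
  if (!is.null(manual)) {
    stopifnot(is(manual, "CompartmentMasks"))
    for (i in seq_len(n)) {
      labs <- manual@labels[rois@footprints[[i]]]
      labs <- labs[labs > 0]
      if (length(labs) > length(rois@footprints[[i]]) / 2) {
        role <- manual@roles[[as.character(labs[1L])]]
        comp[i] <- role
      }
    }
  }
  rois@info$compartment <- comp
  rois
}

#' Normalize an ROI count to the whisker-barrel reference area
#'
#' Fields of view are imaged at different magnifications; counts are made
#' comparable by normalizing to the reference area of a mouse whisker
#' barrel (32,000 um^2): \code{n_rois / (fov_area_um2 / barrel_area_um2)}.
#'
#' @param n_rois ROI count.
#' @param fov_area_um2 field-of-view area (um^2).
#' @param barrel_area_um2 reference barrel area (um^2).
#' @return ROIs per barrel area.
#' @export
roisPerBarrelArea <- function(n_rois, fov_area_um2,
                              barrel_area_um2 = 32000) {
  if (fov_area_um2 <= 0 || barrel_area_um2 <= 0)
    stop("areas must be > 0")
  n_rois / (fov_area_um2 / barrel_area_um2)
}

#' Fraction of astrocyte pixels active in a trial
#'
#' @param active_2d logical matrix: pixels active at any frame.
#' @param astro_area logical matrix: total astrocyte area (see
#'   \code{\link{astroAreaMask}}).
#' @return |active & astro| / |astro|.
#' @export
activePixelFraction <- function(active_2d, astro_area) {
  if (!any(astro_area)) stop("astro_area mask is empty")
  if (!identical(dim(active_2d), dim(astro_area)))
    stop("mask geometry mismatch")
  sum(active_2d & astro_area) / sum(astro_area)
}

#' Default astrocyte-area mask: Otsu threshold on the temporal mean image
#'
#' The total astrocyte area is taken as the pixels whose temporal-mean
#' fluorescence exceeds Otsu's threshold on the mean image; a manually
#' drawn mask can be supplied instead wherever an astro area is consumed.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @return logical matrix.
#' @export
astroAreaMask <- function(movie) {
  meanImg <- apply(frames(movie), c(2L, 3L), mean)
  meanImg > .otsu(as.vector(meanImg))
}

## Otsu's threshold: maximize between-class variance over a 256-bin
## histogram of the intensity range.
.otsu <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  sigmaB <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

#' Trial response map and repeated-response score
#'
#' \code{trialResponseMap} gives, per pixel, the fraction of trials in
#' which it was active. \code{repeatedResponseScore} is the fraction of
#' astrocyte-area pixels active in at least \code{min_trials} trials, a
#' measure of how reproducibly microdomains re-activate across repeated
#' stimulations.
#'
#' @param per_trial_active list of logical matrices (one per trial,
#'   identical geometry).
#' @return \code{trialResponseMap}: numeric matrix of fractions in [0, 1].
#' @export
trialResponseMap <- function(per_trial_active) {
  stopifnot(length(per_trial_active) >= 1L)
  dm <- dim(per_trial_active[[1L]])
  if (!all(vapply(per_trial_active,
                  function(m) identical(dim(m), dm), logical(1))))
    stop("trial masks have mismatching geometry")
  Reduce(`+`, lapply(per_trial_active, function(m) m * 1)) /
    length(per_trial_active)
}

#' @rdname trialResponseMap
#' @param astro_area logical matrix of the total astrocyte area.
#' @param min_trials minimum number of active trials (default 2).
#' @export
repeatedResponseScore <- function(per_trial_active, astro_area,
                                  min_trials = 2) {
  if (!any(astro_area)) stop("astro_area mask is empty")
  counts <- Reduce(`+`, lapply(per_trial_active, function(m) m * 1))
  if (!identical(dim(counts), dim(astro_area)))
    stop("mask geometry mismatch")
  sum(counts >= min_trials & astro_area) / sum(astro_area)
}

#' Pairwise synchrony (seed-based correlation) between ROI traces
#'
#' Pearson correlation of the dF/F vectors of every unordered ROI pair over
#' the stimulation window (\code{corr_window} seconds after stimulus
#' onset), with a two-sided p-value from the t distribution with n-2
#' degrees of freedom. A pair is included in the synchrony summary iff its
#' p-value is below \code{corr_alpha} (optionally after
#' Benjamini-Hochberg adjustment, \code{corr_adjust = "BH"}). Pairs with a
#' zero-variance trace in the window are excluded with a flag.
#'
#' @param traces list of at least two \linkS4class{ROITrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param params a \linkS4class{ClassificationParams}.
#' @return data.frame, one row per pair: \code{roi_i}, \code{roi_j},
#'   \code{r}, \code{p}, \code{included}, \code{flag}.
#' @export
pairwiseSynchrony <- function(traces, protocol = TrialProtocol(),
                              params = ClassificationParams()) {
  if (length(traces) < 2L) stop("need >= 2 traces")
  fr <- frameRate(traces[[1L]])
  times <- (seq_along(dff(traces[[1L]])) - 1) / fr
  sel <- which(times >= protocol@stim_onset_s + params@corr_window[1L] &
               times < protocol@stim_onset_s + params@corr_window[2L])
  if (length(sel) < 3L) stop("correlation window contains < 3 frames")
  mat <- vapply(traces, function(tr) dff(tr)[sel], numeric(length(sel)))
  ids <- vapply(traces, function(tr) tr@roiId, numeric(1))
  pairs <- utils::combn(length(traces), 2L)
  n <- length(sel)
  out <- data.frame(roi_i = ids[pairs[1L, ]], roi_j = ids[pairs[2L, ]],
                    r = NA_real_, p = NA_real_, included = FALSE,
                    flag = "")
  sds <- apply(mat, 2L, stats::sd)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (sds[i] == 0 || sds[j] == 0) {
      out$flag[k] <- "zero_variance"
      next
    }
    r <- stats::cor(mat[, i], mat[, j])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    out$r[k] <- r
    out$p[k] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  pAdj <- if (params@corr_adjust == "BH")
    stats::p.adjust(out$p, "BH") else out$p
  out$included <- !is.na(pAdj) & pAdj < params@corr_alpha
  out
}

#' Summarize synchrony across trials
#'
#' Mean Pearson r over included pairs, either averaged within each trial
#' first and then across trials (\code{"per_trial"}, default) or pooled
#' over all included pairs of all trials (\code{"pooled"}).
#'
#' @param pairTables list of data.frames from
#'   \code{\link{pairwiseSynchrony}} (one per trial).
#' @param method \code{"per_trial"} or \code{"pooled"}.
#' @return Mean correlation (NA when no pair is included).
#' @export
synchronySummary <- function(pairTables, method = c("per_trial", "pooled")) {
  method <- match.arg(method)
  if (method == "pooled") {
    r <- unlist(lapply(pairTables, function(d) d$r[d$included]))
    return(if (length(r)) mean(r) else NA_real_)
  }
  perTrial <- vapply(pairTables, function(d) {
    r <- d$r[d$included]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  if (all(is.na(perTrial))) NA_real_ else mean(perTrial, na.rm = TRUE)
}

#' Corrected total cell / field fluorescence
#'
#' \code{CTCF = integrated density - (cell area x background mean)};
#' \code{CTFF = integrated density - (field area x background mean)}.
#' Units follow the inputs.
#'
#' @param integrated_density summed intensity over the cell (or field)
#'   mask.
#' @param cell_area,field_area mask area.
#' @param background_mean mean background fluorescence.
#' @return The corrected fluorescence.
#' @export
computeCTCF <- function(integrated_density, cell_area, background_mean) {
  if (any(cell_area < 0)) stop("area must be >= 0")
  stopifnot(all(is.finite(integrated_density)),
            all(is.finite(background_mean)))
  integrated_density - cell_area * background_mean
}

#' @rdname computeCTCF
#' @export
computeCTFF <- function(integrated_density, field_area, background_mean) {
  if (any(field_area < 0)) stop("area must be >= 0")
  stopifnot(all(is.finite(integrated_density)),
            all(is.finite(background_mean)))
  integrated_density - field_area * background_mean
}

#' Per-FOV summary of microdomain activity
#'
#' @param rois an \linkS4class{ROISet} with compartments assigned.
#' @param events event table from \code{\link{buildEventTable}}.
#' @param active2d logical matrix of active pixels for this trial.
#' @param astro_area logical matrix of the total astrocyte area.
#' @param params a \linkS4class{ClassificationParams}.
#' @return One-row data.frame: FOV area, ROI counts (total and per
#'   compartment and tier), ROIs per barrel area, active-pixel fraction.
#' @export
fovSummary <- function(rois, events, active2d, astro_area,
                       params = ClassificationParams()) {
  px <- pixelSize(rois)
  fovArea <- prod(dim(labelImage(rois))) * px^2
  info <- roiInfo(rois)
  comp <- table(factor(info$compartment,
                       levels = c("soma", "endfoot", "process",
                                  "neuron_soma", "unset")))
  tiers <- if (nrow(events))
    table(factor(classifyNeuronTier(events$amplitude_dff, params),
                 levels = c("low", "mid", "high")))
  else c(low = 0L, mid = 0L, high = 0L)
  data.frame(
    fov_area_um2 = fovArea, n_rois = nrow(info),
    n_soma = as.integer(comp[["soma"]]),
    n_endfoot = as.integer(comp[["endfoot"]]),
    n_process = as.integer(comp[["process"]]),
    rois_per_barrel_area = roisPerBarrelArea(nrow(info), fovArea,
                                             params@barrel_area_um2),
    n_low = as.integer(tiers[["low"]]), n_mid = as.integer(tiers[["mid"]]),
    n_high = as.integer(tiers[["high"]]),
    active_pixel_fraction = activePixelFraction(active2d, astro_area))
}
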