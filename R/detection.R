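#' @include AllClasses.R utils.R
NULL

#' Detection parameter presets
#'
#' Builds a \linkS4class{DetectionParams} from one of the channel-specific
#' presets, with optional overrides:
#' \describe{
#'   \item{invivo-astro}{in vivo Lck-GCaMP6f: 7x noise SD, rise 0.1-1 s,
#'     grouping gap 0.5 s.}
#'   \item{invivo-neuro}{in vivo RCaMP1.07: 7x noise SD, rise 0.07-1 s,
#'     grouping gap 0.2 s.}
#'   \item{invitro-astro}{in vitro Lck-GCaMP6f: 5x noise SD, rise 0.1-8 s,
#'     grouping gap 0.5 s.}
#' }
#' All presets share: 5 s boxcar, 4 um grouping radius, projection threshold
#' q = 0.2, ANOVA alpha 0.05, 2 um surround ring.
#'
#' @param preset preset name.
#' @param ... named overrides for any \linkS4class{DetectionParams} slot.
#' @return A \linkS4class{DetectionParams}.
#' @examples
#' detectionParams("invivo-neuro")
#' detectionParams("invivo-astro", amp_sd_mult = 5)
#' @export
detectionParams <- function(preset = c("invivo-astro", "invivo-neuro",
                                       "invitro-astro"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "invivo-astro" = list(amp_sd_mult = 7, rise_bounds_s = c(0.1, 1),
                          group_time_s = 0.5),
    "invivo-neuro" = list(amp_sd_mult = 7, rise_bounds_s = c(0.07, 1),
                          group_time_s = 0.2),
    "invitro-astro" = list(amp_sd_mult = 5, rise_bounds_s = c(0.1, 8),
                           group_time_s = 0.5))
  args <- utils::modifyList(
    c(base, list(boxcar_s = 5, group_radius_um = 4, roi_threshold_q = 0.2,
                 fp_alpha = 0.05, surround_width_um = 2,
                 boxcar_align = "centered", normalization = "component")),
    list(...))
  do.call(methods::new, c(list("DetectionParams"), args))
}

#' Sliding-boxcar mean and SD per pixel and frame
#'
#' For each (frame, pixel), the mean and unbiased (n-1) SD of that pixel's
#' intensity over a temporal boxcar of \code{boxcar_s} seconds, centered on
#' the frame by default and truncated (not padded) at the movie edges.
#' Truncation avoids phantom onsets at the movie start. SD is \code{NaN}
#' where the truncated window holds a single sample (possible only with
#' trailing alignment at the first frame).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param boxcar_s window length in seconds (default 5); must span >= 3
#'   frames and not exceed the movie.
#' @param align \code{"centered"} (default) or \code{"trailing"}.
#' @return list with 3D arrays \code{mean} and \code{sd} shaped like the
#'   movie frames.
#' @export
boxcarStats <- function(movie, boxcar_s = 5, align = c("centered",
                                                       "trailing")) {
  align <- match.arg(align)
  arr <- frames(movie)
  nT <- dim(arr)[1L]
  w <- round(boxcar_s * frameRate(movie))
  if (w < 3L) stop("boxcar window must span >= 3 frames (got ", w, ")")
  if (w > nT) stop("boxcar window (", w, " frames) longer than movie (",
                   nT, " frames)")
  if (align == "centered") {
    hl <- (w - 1L) %/% 2L
    lo <- pmax(seq_len(nT) - hl, 1L)
    hi <- pmin(seq_len(nT) + (w - 1L - hl), nT)
  } else {
    lo <- pmax(seq_len(nT) - w + 1L, 1L)
    hi <- seq_len(nT)
  }
  x <- matrix(arr, nT, prod(dim(arr)[2:3]))
  cs <- rbind(0, apply(x, 2L, cumsum))
  cs2 <- rbind(0, apply(x^2, 2L, cumsum))
  n <- hi - lo + 1L
  s1 <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  s2 <- cs2[hi + 1L, , drop = FALSE] - cs2[lo, , drop = FALSE]
  mu <- s1 / n
  v <- (s2 - s1^2 / n) / (n - 1L)
  v[n < 2L, ] <- NaN
  v[v < 0] <- 0  # guard tiny negative values from cancellation
  list(mean = array(mu, dim(arr)), sd = array(sqrt(v), dim(arr)))
}

#' Event-robust per-pixel noise SD
#'
#' Estimates each pixel's noise scale as
#' \code{median(|diff(trace)|) / (sqrt(2) * qnorm(0.75))}. Unlike the
#' within-window SD, this estimator is insensitive to a transient occupying
#' a minority of the samples, so an event does not inflate the very
#' threshold that must detect it (the amplitude criterion would otherwise
#' saturate below the 7x multiplier for any event amplitude). A constant
#' trace has zero estimated noise; together with the strict inequality in
#' \code{\link{detectActivePixels}} it can then never exceed its own
#' threshold.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @return Matrix (rows x cols) of noise SDs.
#' @export
pixelNoiseSd <- function(movie) {
  arr <- frames(movie)
  nT <- dim(arr)[1L]
  x <- matrix(arr, nT, prod(dim(arr)[2:3]))
  d <- abs(x[-1L, , drop = FALSE] - x[-nT, , drop = FALSE])
  med <- apply(d, 2L, stats::median)
  matrix(med / (sqrt(2) * stats::qnorm(0.75)), dim(arr)[2L], dim(arr)[3L])
}

#' Classify active pixels by amplitude and rise time
#'
#' A pixel-frame is active iff (1) its intensity strictly exceeds the
#' sliding boxcar mean plus \code{amp_sd_mult} times the pixel's noise SD,
#' and (2) the local event containing it has a peak rise time within
#' \code{rise_bounds_s}. The local event is the contiguous run of frames
#' above the boxcar mean containing the threshold crossing; its rise time is
#' the time from the last upward crossing of the boxcar mean to the run's
#' peak. (That operationalizes "peak rise time relative to the boxcar" as
#' the simplest definition consistent with the stated bounds.)
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param params a \linkS4class{DetectionParams}; pick with
#'   \code{\link{detectionParams}}.
#' @param stats optional precomputed \code{\link{boxcarStats}} result.
#' @return Logical 3D array (time x rows x cols) of active pixel-frames.
#' @export
detectActivePixels <- function(movie, params = detectionParams(),
                               stats = NULL) {
  methods::validObject(params)
  arr <- frames(movie)
  nT <- dim(arr)[1L]
  if (is.null(stats))
    stats <- boxcarStats(movie, params@boxcar_s, params@boxcar_align)
  sigma <- pixelNoiseSd(movie)
  nPix <- prod(dim(arr)[2:3])
  x <- matrix(arr, nT, nPix)
  mu <- matrix(stats$mean, nT, nPix)
  thr <- sweep(mu, 2L, params@amp_sd_mult * as.vector(sigma), "+")
  exceeded <- !is.na(thr) & x > thr
  mask <- matrix(FALSE, nT, nPix)
  fps <- frameRate(movie)
  for (p in which(colSums(exceeded) > 0L)) {
    above <- x[, p] > mu[, p]
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      if (!any(exceeded[run, p])) next
      peak <- run[which.max(x[run, p])]
      rise <- (peak - run[1L]) / fps
      if (rise >= params@rise_bounds_s[1L] &&
          rise <= params@rise_bounds_s[2L])
        mask[run, p] <- exceeded[run, p]
    }
  }
  array(mask, dim(arr))
}

## Connected-component labeling of a logical matrix; connectivity 4 or 8.
.labelConn <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nb <- integer()
      if (r > 1L) nb <- c(nb, p - 1L)
      if (r < nr) nb <- c(nb, p + 1L)
      if (cc > 1L) nb <- c(nb, p - nr)
      if (cc < nc) nb <- c(nb, p + nr)
      if (connectivity == 8L) {
        if (r > 1L && cc > 1L) nb <- c(nb, p - nr - 1L)
        if (r < nr && cc > 1L) nb <- c(nb, p - nr + 1L)
        if (r > 1L && cc < nc) nb <- c(nb, p + nr - 1L)
        if (r < nr && cc < nc) nb <- c(nb, p + nr + 1L)
      }
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Group active pixels into spatiotemporal components
#'
#' Two active pixel-frames are connected iff their spatial (Euclidean,
#' pixel-center) distance is at most \code{group_radius_um} and their
#' temporal separation is at most \code{group_time_s}; components are the
#' transitive closure of that relation (single linkage). For radii of at
#' least sqrt(2) px the per-frame clustering is accelerated by first taking
#' within-frame connected blobs (any two pixels of a blob are chained by
#' neighbor steps shorter than the radius, so the blob is always within one
#' component) and then single-linking blobs by their minimum pairwise
#' distance; the result is identical to the exact pairwise closure.
#'
#' @param mask logical 3D array from \code{\link{detectActivePixels}}.
#' @param group_radius_um spatial radius (default 4 um).
#' @param group_time_s temporal gap (s).
#' @param pixel_size_um,frame_rate_hz movie geometry.
#' @return Integer 3D array of component labels (0 = inactive), labels
#'   consecutive in order of first occurrence.
#' @export
groupActivePixels <- function(mask, group_radius_um = 4, group_time_s = 0.5,
                              pixel_size_um = 1, frame_rate_hz = 13.84) {
  dm <- dim(mask)
  nT <- dm[1L]; nr <- dm[2L]; nc <- dm[3L]
  out <- array(0L, dm)
  if (!any(mask)) return(out)
  rPx <- group_radius_um / pixel_size_um
  gapF <- floor(group_time_s * frame_rate_hz + 1e-9)
  conn <- if (rPx >= sqrt(2)) 8L else if (rPx >= 1) 4L else 0L
  ## blobs: per-frame connected sets (or singleton pixels when the radius
  ## is below the pixel pitch)
  blobT <- integer(); blobRows <- list(); blobCols <- list()
  for (t in seq_len(nT)) {
    m2 <- matrix(mask[t, , ], nr, nc)
    if (!any(m2)) next
    if (conn == 0L) {
      w <- which(m2, arr.ind = TRUE)
      for (i in seq_len(nrow(w))) {
        blobT <- c(blobT, t)
        blobRows <- c(blobRows, list(w[i, 1L]))
        blobCols <- c(blobCols, list(w[i, 2L]))
      }
    } else {
      lab <- .labelConn(m2, conn)
      for (k in seq_len(max(lab))) {
        w <- which(lab == k, arr.ind = TRUE)
        blobT <- c(blobT, t)
        blobRows <- c(blobRows, list(w[, 1L]))
        blobCols <- c(blobCols, list(w[, 2L]))
      }
    }
  }
  nB <- length(blobT)
  parent <- .ufNew(nB)
  ord <- order(blobT)
  for (ii in seq_len(nB - 1L)) {
    i <- ord[ii]
    for (jj in (ii + 1L):nB) {
      j <- ord[jj]
      if (blobT[j] - blobT[i] > gapF) break
      ## cheap bounding-box rejection before the exact minimum distance
      if (min(blobRows[[i]]) > max(blobRows[[j]]) + rPx ||
          min(blobRows[[j]]) > max(blobRows[[i]]) + rPx ||
          min(blobCols[[i]]) > max(blobCols[[j]]) + rPx ||
          min(blobCols[[j]]) > max(blobCols[[i]]) + rPx) next
      d2 <- outer(blobRows[[i]], blobRows[[j]], "-")^2 +
            outer(blobCols[[i]], blobCols[[j]], "-")^2
      if (min(d2) <= rPx^2) {
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(nB), function(i) .ufFind(parent, i), integer(1))
  ## consecutive labels in order of first (time, pixel) occurrence
  lab <- match(roots, unique(roots[ord]))
  for (b in seq_len(nB)) {
    idx <- (blobCols[[b]] - 1L) * nr + blobRows[[b]]
    out[(idx - 1L) * nT + blobT[b]] <- lab[b]
  }
  out
}

#' Collapse 3D components into 2D microdomain ROIs
#'
#' Each spatiotemporal component is projected along time by counting active
#' frames per pixel, normalized (by the component's maximum count, or the
#' global maximum when \code{normalization = "global"}), thresholded at
#' \code{roi_threshold_q}, and reduced to its largest 4-connected region.
#' Components whose thresholded footprint is empty are dropped with a log
#' entry. Footprints of temporally distinct components may overlap; each
#' keeps its own ROI id.
#'
#' @param components integer 3D label array from
#'   \code{\link{groupActivePixels}}.
#' @param pixel_size_um pixel size for ROI areas.
#' @param roi_threshold_q projection threshold (default 0.2).
#' @param normalization \code{"component"} (default) or \code{"global"}.
#' @param channel channel recorded per ROI.
#' @param verbose log dropped components.
#' @return An \linkS4class{ROISet}.
#' @export
buildRoiMask <- function(components, pixel_size_um = 1,
                         roi_threshold_q = 0.2,
                         normalization = c("component", "global"),
                         channel = "other", verbose = FALSE) {
  normalization <- match.arg(normalization)
  dm <- dim(components)
  nT <- dm[1L]; nr <- dm[2L]; nc <- dm[3L]
  nK <- max(components)
  labelImg <- matrix(0L, nr, nc)
  fps <- list(); act <- list(); rows <- list()
  globalMax <- if (nK > 0)
    max(apply(components > 0, c(2, 3), sum)) else 0
  keep <- 0L
  for (k in seq_len(nK)) {
    vox <- which(components == k)
    tIdx <- ((vox - 1L) %% nT) + 1L
    pIdx <- ((vox - 1L) %/% nT) + 1L
    counts <- table(pIdx)
    pix <- as.integer(names(counts))
    cnt <- as.integer(counts)
    norm <- if (normalization == "component") max(cnt) else globalMax
    sel <- pix[cnt / norm >= roi_threshold_q]
    if (!length(sel)) {
      .logStage("roi", sprintf(
        "component %d dropped: empty footprint after q-threshold", k),
        verbose = verbose)
      next
    }
    m2 <- matrix(FALSE, nr, nc)
    m2[sel] <- TRUE
    lab <- .label4(m2)
    sizes <- tabulate(lab[lab > 0L])
    footprint <- which(lab == which.max(sizes))
    keep <- keep + 1L
    fps[[keep]] <- footprint
    act[[keep]] <- sort(unique(tIdx))
    labelImg[footprint] <- keep
    rows[[keep]] <- data.frame(
      id = keep, area_px = length(footprint),
      area_um2 = length(footprint) * pixel_size_um^2,
      fp_pvalue = NA_real_, fp_flag = "", compartment = "unset",
      channel = channel)
  }
  info <- if (keep) do.call(rbind, rows) else .emptyRoiInfo()
  new("ROISet", labelImage = labelImg, footprints = fps, activeFrames = act,
      info = info, pixelSize = pixel_size_um)
}

.emptyRoiInfo <- function() {
  data.frame(id = integer(), area_px = integer(), area_um2 = numeric(),
             fp_pvalue = numeric(), fp_flag = character(),
             compartment = character(), channel = character())
}

## Rebuild an ROISet keeping rows `sel`, relabeling ids consecutively.
.subsetROISet <- function(rois, sel) {
  fps <- rois@footprints[sel]
  act <- rois@activeFrames[sel]
  info <- rois@info[sel, , drop = FALSE]
  n <- nrow(info)
  info$id <- seq_len(n)
  rownames(info) <- NULL
  labelImg <- matrix(0L, nrow(rois@labelImage), ncol(rois@labelImage))
  for (i in seq_len(n)) labelImg[fps[[i]]] <- i
  new("ROISet", labelImage = labelImg, footprints = fps, activeFrames = act,
      info = info, pixelSize = rois@pixelSize)
}

#' ANOVA false-positive filter
#'
#' For each ROI, the per-pixel mean raw intensity during the ROI's active
#' frames is compared between ROI pixels and a surround ring (a
#' \code{surround_width_um}-wide dilation of the footprint, excluding all
#' ROI pixels) by one-way ANOVA; the ROI is retained iff p <
#' \code{fp_alpha}. The sample unit is the pixel (temporal means), avoiding
#' temporal pseudo-replication. A ROI whose surround is entirely consumed by
#' neighboring ROIs is retained with flag \code{"untestable"} and a warning;
#' zero-variance degenerate comparisons get p = 1 and are removed.
#'
#' @param movie the raw \linkS4class{MovieStack}.
#' @param rois an \linkS4class{ROISet}.
#' @param fp_alpha significance level (default 0.05).
#' @param surround_width_um ring width (default 2 um).
#' @return The filtered \linkS4class{ROISet} with \code{fp_pvalue} recorded.
#' @export
filterFalsePositives <- function(movie, rois, fp_alpha = 0.05,
                                 surround_width_um = 2) {
  n <- nROIs(rois)
  if (n == 0L) return(rois)
  arr <- frames(movie)
  nT <- dim(arr)[1L]; nr <- dim(arr)[2L]; nc <- dim(arr)[3L]
  x <- matrix(arr, nT, nr * nc)
  allRoiPix <- unique(unlist(rois@footprints))
  widthPx <- surround_width_um / pixelSize(movie)
  pvals <- numeric(n)
  flags <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    pix <- rois@footprints[[i]]
    fr <- rois@activeFrames[[i]]
    ring <- setdiff(.ringAround(pix, nr, nc, widthPx), allRoiPix)
    if (!length(ring)) {
      pvals[i] <- NA_real_; flags[i] <- "untestable"; keep[i] <- TRUE
      warning("ROI ", i, " has no testable surround; retained untested")
      next
    }
    mRoi <- colMeans(x[fr, pix, drop = FALSE])
    mRing <- colMeans(x[fr, ring, drop = FALSE])
    vals <- c(mRoi, mRing)
    if (stats::var(vals) == 0) {
      pvals[i] <- 1; keep[i] <- FALSE; next
    }
    grp <- factor(rep(c("roi", "surround"), c(length(mRoi), length(mRing))))
    p <- stats::anova(stats::lm(vals ~ grp))[["Pr(>F)"]][1L]
    pvals[i] <- p
    keep[i] <- is.finite(p) && p < fp_alpha
  }
  rois@info$fp_pvalue <- pvals
  rois@info$fp_flag <- flags
  .subsetROISet(rois, which(keep))
}

#' Remove overlap between activity ROIs and manual compartment masks
#'
#' Pixels of automatically detected ROIs that fall inside any manual
#' compartment ROI are removed, so each ROI is unique; automatic ROIs left
#' empty are dropped. The surviving automatic ROIs are later classified as
#' processes (see \code{\link{assignCompartments}}).
#'
#' @param auto an \linkS4class{ROISet} from detection.
#' @param manual a \linkS4class{CompartmentMasks} on the same geometry.
#' @return The deduplicated \linkS4class{ROISet}.
#' @export
excludeManualOverlap <- function(auto, manual) {
  stopifnot(is(manual, "CompartmentMasks"))
  if (!identical(dim(auto@labelImage), dim(manual@labels)))
    stop("ROI set and manual masks have different geometry")
  manualPix <- which(manual@labels > 0)
  if (!length(manualPix) || nROIs(auto) == 0L) return(auto)
  newFps <- lapply(auto@footprints, setdiff, manualPix)
  keep <- lengths(newFps) > 0L
  auto@footprints <- newFps
  out <- .subsetROISet(auto, which(keep))
  out@info$area_px <- lengths(out@footprints)
  out@info$area_um2 <- out@info$area_px * out@pixelSize^2
  out
}

#' Full microdomain detection on one movie
#'
#' Runs the detection chain: boxcar statistics, active-pixel classification,
#' spatiotemporal grouping, 2D ROI construction, ANOVA false-positive
#' filtering and (optionally) deduplication against manual compartment
#' masks.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param params a \linkS4class{DetectionParams}.
#' @param manual optional \linkS4class{CompartmentMasks}.
#' @param verbose log stage progress.
#' @return list: \code{rois} (an \linkS4class{ROISet}), \code{active2d}
#'   (logical matrix, pixels active at any frame), \code{components}
#'   (the 3D label array).
#' @export
detectMicrodomains <- function(movie, params = detectionParams(),
                               manual = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  mask <- detectActivePixels(movie, params)
  .logStage("detect", sprintf("%d active pixel-frames", sum(mask)), t0,
            verbose = verbose)
  comps <- groupActivePixels(mask, params@group_radius_um,
                             params@group_time_s, pixelSize(movie),
                             frameRate(movie))
  rois <- buildRoiMask(comps, pixelSize(movie), params@roi_threshold_q,
                       params@normalization, channel = channel(movie),
                       verbose = verbose)
  rois <- filterFalsePositives(movie, rois, params@fp_alpha,
                               params@surround_width_um)
  if (!is.null(manual)) rois <- excludeManualOverlap(rois, manual)
  .logStage("detect", sprintf("%d ROIs retained", nROIs(rois)), t0,
            verbose = verbose)
  list(rois = rois, active2d = apply(mask, c(2L, 3L), any),
       components = comps)
}
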