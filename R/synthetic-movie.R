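#' @include AllClasses.R utils.R
NULL

#' Construct a SyntheticTruth specification
#'
#' @param events list of \linkS4class{PlantedEvent}.
#' @param baselineImage 2D baseline intensity grid.
#' @param noiseSd per-pixel noise SD in intensity units.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param frameRate,pixelSize acquisition geometry.
#' @param channel,context movie metadata.
#' @param seed integer seed; the generated movie is a pure function of
#'   (spec, seed).
#' @param noiseModel \code{"gaussian"} (default) or \code{"poisson"}.
#' @return A \linkS4class{SyntheticTruth}.
#' @export
SyntheticTruth <- function(events, baselineImage, noiseSd = 5,
                           protocol = TrialProtocol(), frameRate = 13.84,
                           pixelSize = 1, channel = "astro_lckgcamp6f",
                           context = "in_vivo", seed = 1L,
                           noiseModel = "gaussian") {
  new("SyntheticTruth", events = events, baselineImage = baselineImage,
      noiseSd = noiseSd, noiseModel = noiseModel, protocol = protocol,
      frameRate = frameRate, pixelSize = pixelSize, channel = channel,
      context = context, seed = as.numeric(seed))
}

#' Smoothed random baseline texture mimicking astropil fluorescence
#'
#' A Gaussian random field, smoothed by repeated box blurs and rescaled to
#' the requested mean and SD, then floored away from zero. A uniform
#' baseline (sd = 0) is allowed for oracle tests.
#'
#' @param ny,nx frame size in pixels.
#' @param mean,sd intensity mean and spatial SD.
#' @param smooth_px box-blur radius in pixels.
#' @param seed integer seed.
#' @return An ny x nx intensity matrix.
#' @export
baselineTexture <- function(ny, nx, mean = 100, sd = 10, smooth_px = 3,
                            seed = 1L) {
  if (sd == 0) return(matrix(mean, ny, nx))
  set.seed(as.integer(seed))
  img <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (i in 1:2) {
    img <- t(apply(img, 1L, .movingAverage, k = 2L * smooth_px + 1L))
    img <- apply(img, 2L, .movingAverage, k = 2L * smooth_px + 1L)
  }
  img <- (img - base::mean(img)) / stats::sd(img) * sd + mean
  pmax(img, mean * 0.2)
}


## Event time course sampled at frame times: linear rise from onset to peak
## over rise_s, then exponential decay with time constant decay_s.
.eventKernel <- function(times, onset_s, rise_s, decay_s) {
  g <- numeric(length(times))
  rising <- times >= onset_s & times < onset_s + rise_s
  g[rising] <- (times[rising] - onset_s) / rise_s
  decaying <- times >= onset_s + rise_s
  g[decaying] <- exp(-(times[decaying] - onset_s - rise_s) / decay_s)
  g
}

#' Generate a ground-truthed synthetic movie
#'
#' The movie is \code{baseline * (1 + sum of event kernels) + noise}: each
#' planted event rises linearly to its amplitude over \code{rise_s} and
#' decays exponentially with constant \code{decay_s}, applied
#' multiplicatively to the baseline within its footprint; noise is zero-mean
#' Gaussian of scale \code{noiseSd} (or Poisson shot noise when
#' \code{noiseModel = "poisson"}). Identical specs and seeds give
#' bit-identical movies.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return A list with elements \code{movie} (a \linkS4class{MovieStack})
#'   and \code{truth} (the spec, unchanged).
#' @examples
#' tr <- SyntheticTruth(
#'   events = list(PlantedEvent(diskFootprint(32, 32, 16, 16, 3),
#'                              onset_s = 6, rise_s = 0.4, decay_s = 0.8,
#'                              amplitude_dff = 2)),
#'   baselineImage = matrix(100, 32, 32), noiseSd = 0,
#'   protocol = TrialProtocol(trial_len_s = 15), seed = 7)
#' mv <- generateMovie(tr)$movie
#' range(frames(mv))
#' @export
generateMovie <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  methods::validObject(truth)
  ny <- nrow(truth@baselineImage); nx <- ncol(truth@baselineImage)
  nT <- max(2L, floor(truth@protocol@trial_len_s * truth@frameRate))
  times <- (seq_len(nT) - 1) / truth@frameRate
  ## accumulated multiplicative modulation per pixel and frame
  arr <- array(rep(truth@baselineImage, each = nT), c(nT, ny, nx))
  for (ev in truth@events) {
    g <- .eventKernel(times, ev@onset_s, ev@rise_s, ev@decay_s)
    pix <- which(ev@footprint)
    if (!length(pix)) next
    base <- truth@baselineImage[pix]
    add <- outer(g * ev@amplitude_dff, base)  # nT x npix
    flat <- matrix(arr, nT, ny * nx)
    flat[, pix] <- flat[, pix] + add
    arr <- array(flat, c(nT, ny, nx))
  }
  set.seed(as.integer(truth@seed))
  if (truth@noiseModel == "poisson") {
    ## shot noise: variance proportional to signal, scaled so a pixel at
    ## the baseline mean has SD = noiseSd
    if (truth@noiseSd > 0) {
      gain <- truth@noiseSd^2 / base::mean(truth@baselineImage)
      arr[] <- stats::rpois(length(arr), arr / gain) * gain
    }
  } else if (truth@noiseSd > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, truth@noiseSd)
  }
  movie <- MovieStack(arr, frameRate = truth@frameRate,
                      pixelSize = truth@pixelSize, channel = truth@channel,
                      context = truth@context)
  list(movie = movie, truth = truth)
}

#' Build a randomized synthetic truth under the default study conditions
#'
#' Samples disc-shaped event footprints with a minimum centroid separation
#' (so distinct planted events cannot be merged by the spatiotemporal
#' grouping radius), onsets either locked to the stimulation window,
#' spontaneous across the trial, or mixed, and uniform amplitudes across the
#' requested range. Defaults follow the in vivo acquisition: 128 x 128 px,
#' 13.84 fps, 25 s trials with 5 s baseline, 10 events of 1-4 dF/F.
#'
#' @param seed integer seed for placement and the movie noise.
#' @param nEvents number of planted events.
#' @param ny,nx frame size (px).
#' @param frameRate,pixelSize acquisition geometry.
#' @param protocol trial timing.
#' @param amplitudeRange (min, max) peak dF/F, sampled uniformly.
#' @param riseRange,decayRange (min, max) kinetics in seconds.
#' @param radiusRange (min, max) footprint disc radius in pixels.
#' @param minSeparationUm minimum centroid separation between events.
#' @param timing \code{"mixed"} (default), \code{"stim_locked"} or
#'   \code{"spontaneous"}.
#' @param noiseSd,baselineMean,baselineSd,noiseModel noise and texture
#'   settings; \code{baselineSd = 0} gives a uniform baseline.
#' @param channel,context movie metadata.
#' @return A \linkS4class{SyntheticTruth}.
#' @export
randomSyntheticTruth <- function(seed = 1L, nEvents = 10, ny = 128, nx = 128,
                                 frameRate = 13.84, pixelSize = 1,
                                 protocol = TrialProtocol(),
                                 amplitudeRange = c(1, 4),
                                 riseRange = c(0.3, 0.5),
                                 decayRange = c(0.6, 1.0),
                                 radiusRange = c(2, 4),
                                 minSeparationUm = 15, timing = "mixed",
                                 noiseSd = 5, baselineMean = 100,
                                 baselineSd = 10, noiseModel = "gaussian",
                                 channel = "astro_lckgcamp6f",
                                 context = "in_vivo") {
  set.seed(as.integer(seed))
  minSepPx <- minSeparationUm / pixelSize
  maxR <- ceiling(radiusRange[2L])
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < nEvents) {
    if ((tries <- tries + 1L) > 2000L)
      stop("could not place ", nEvents, " events with separation ",
           minSeparationUm, " um in a ", ny, "x", nx, " frame")
    cand <- c(stats::runif(1, maxR + 1, ny - maxR),
              stats::runif(1, maxR + 1, nx - maxR))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSepPx))
      centers <- rbind(centers, cand)
  }
  stimLocked <- switch(timing,
    stim_locked = rep(TRUE, nEvents),
    spontaneous = rep(FALSE, nEvents),
    mixed = seq_len(nEvents) %% 2L == 0L,
    stop("timing must be 'mixed', 'stim_locked' or 'spontaneous'"))
  events <- lapply(seq_len(nEvents), function(i) {
    radius <- stats::runif(1, radiusRange[1L], radiusRange[2L])
    rise <- stats::runif(1, riseRange[1L], riseRange[2L])
    decay <- stats::runif(1, decayRange[1L], decayRange[2L])
    tailLen <- rise + 3 * decay + 0.5
    onset <- if (stimLocked[i])
      stats::runif(1, protocol@stim_onset_s,
                   protocol@stim_onset_s + protocol@analysis_window_s - tailLen)
    else
      stats::runif(1, 1, protocol@trial_len_s - tailLen)
    PlantedEvent(
      footprint = diskFootprint(ny, nx, centers[i, 1L], centers[i, 2L],
                                 radius),
      onset_s = onset, rise_s = rise, decay_s = decay,
      amplitude_dff = stats::runif(1, amplitudeRange[1L],
                                   amplitudeRange[2L]),
      compartment = "process")
  })
  SyntheticTruth(
    events = events,
    baselineImage = baselineTexture(ny, nx, mean = baselineMean,
                                    sd = baselineSd,
                                    seed = as.integer(seed) + 1L),
    noiseSd = noiseSd, protocol = protocol, frameRate = frameRate,
    pixelSize = pixelSize, channel = channel, context = context,
    seed = seed, noiseModel = noiseModel)
}

#' Tabulate planted ground truth (one row per event)
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return data.frame with event id, centroid (0-based pixel coordinates),
#'   area, kinetics, amplitude and compartment.
#' @export
truthTable <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  rows <- lapply(seq_along(truth@events), function(i) {
    ev <- truth@events[[i]]
    pix <- which(ev@footprint, arr.ind = TRUE)
    data.frame(event_id = i, centroid_row = mean(pix[, 1L]) - 1,
               centroid_col = mean(pix[, 2L]) - 1, area_px = nrow(pix),
               onset_s = ev@onset_s, rise_s = ev@rise_s,
               decay_s = ev@decay_s, amplitude_dff = ev@amplitude_dff,
               compartment = ev@compartment)
  })
  if (!length(rows))
    return(data.frame(event_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      onset_s = numeric(), rise_s = numeric(),
                      decay_s = numeric(), amplitude_dff = numeric(),
                      compartment = character()))
  do.call(rbind, rows)
}
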