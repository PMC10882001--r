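#' @import methods
NULL

.CHANNELS <- c("astro_lckgcamp6f", "neuro_rcamp", "other")
.CONTEXTS <- c("in_vivo", "in_vitro")
.COMPARTMENTS <- c("soma", "endfoot", "process", "neuron", "neuron_soma",
                   "unset")

#' MovieStack: a time-lapse fluorescence movie with acquisition metadata
#'
#' The raw input to microdomain detection. Frames are stored time-major as a
#' \code{T x Y x X} numeric array in arbitrary fluorescence units. Frame rate
#' and pixel size are required metadata and are never guessed from file tags.
#'
#' @slot frames numeric array, \code{time x rows x cols}.
#' @slot frameRate frames per second (> 0).
#' @slot pixelSize micrometres per pixel edge (> 0).
#' @slot channel one of \code{"astro_lckgcamp6f"}, \code{"neuro_rcamp"},
#'   \code{"other"}.
#' @slot context one of \code{"in_vivo"}, \code{"in_vitro"}.
#'
#' @details Time for frame \eqn{k} (1-based in R) is
#'   \eqn{(k - 1) / \mathrm{frameRate}} seconds, i.e. the first frame sits at
#'   \eqn{t = 0}. All time windows in the package are half-open
#'   \eqn{[start, end)}.
#' @export
setClass("MovieStack",
  representation(frames = "array", frameRate = "numeric",
                 pixelSize = "numeric", channel = "character",
                 context = "character"))

setValidity("MovieStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3D array (time x rows x cols)")
  else if (dim(object@frames)[1L] < 2L)
    msg <- c(msg, "movie must have >=2 frames")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "all intensities must be finite")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!object@channel %in% .CHANNELS)
    msg <- c(msg, sprintf("channel must be one of: %s",
                          paste(.CHANNELS, collapse = ", ")))
  if (!object@context %in% .CONTEXTS)
    msg <- c(msg, sprintf("context must be one of: %s",
                          paste(.CONTEXTS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MovieStack
#'
#' @param frames numeric 3D array, time x rows x cols.
#' @param frameRate frames per second.
#' @param pixelSize micrometres per pixel.
#' @param channel indicator channel identity.
#' @param context acquisition context.
#' @return A \linkS4class{MovieStack}.
#' @examples
#' mov <- MovieStack(array(100, c(4, 8, 8)), frameRate = 13.84,
#'                   pixelSize = 1, channel = "astro_lckgcamp6f")
#' nFrames(mov)
#' @export
MovieStack <- function(frames, frameRate, pixelSize,
                       channel = c("astro_lckgcamp6f", "neuro_rcamp", "other"),
                       context = c("in_vivo", "in_vitro")) {
  channel <- match.arg(channel)
  context <- match.arg(context)
  new("MovieStack", frames = frames, frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize), channel = channel, context = context)
}

#' TrialProtocol: baseline / stimulation / analysis-window timing
#'
#' Anchors every latency computation. Defaults follow the standard whisker
#' stimulation trial: 5 s baseline, stimulus at 5 s, an 8 s analysis window
#' for "during stimulation" metrics, 25 s total.
#'
#' @slot baseline_s duration of the pre-stimulus baseline (s).
#' @slot stim_onset_s stimulus start time (s).
#' @slot analysis_window_s post-onset window for stimulation metrics (s).
#' @slot trial_len_s total trial duration (s).
#' @slot stim_present logical flag; FALSE for no-stimulation trials.
#' @export
setClass("TrialProtocol",
  representation(baseline_s = "numeric", stim_onset_s = "numeric",
                 analysis_window_s = "numeric", trial_len_s = "numeric",
                 stim_present = "logical"))

setValidity("TrialProtocol", function(object) {
  msg <- character()
  if (!(object@baseline_s > 0))
    msg <- c(msg, "baseline_s must be > 0")
  if (object@baseline_s > object@stim_onset_s)
    msg <- c(msg, "baseline_s must be <= stim_onset_s")
  if (object@stim_onset_s + object@analysis_window_s > object@trial_len_s)
    msg <- c(msg, "stim_onset_s + analysis_window_s must be <= trial_len_s")
  if (length(msg)) msg else TRUE
})

#' @rdname TrialProtocol-class
#' @param baseline_s,stim_onset_s,analysis_window_s,trial_len_s timing in
#'   seconds.
#' @param stim_present whether the stimulus was delivered.
#' @return A \linkS4class{TrialProtocol}.
#' @export
TrialProtocol <- function(baseline_s = 5, stim_onset_s = 5,
                          analysis_window_s = 8, trial_len_s = 25,
                          stim_present = TRUE) {
  new("TrialProtocol", baseline_s = as.numeric(baseline_s),
      stim_onset_s = as.numeric(stim_onset_s),
      analysis_window_s = as.numeric(analysis_window_s),
      trial_len_s = as.numeric(trial_len_s),
      stim_present = isTRUE(stim_present))
}

#' CompartmentMasks: manually drawn compartment ROIs
#'
#' A labeled image of hand-selected compartments (astrocyte somata, vascular
#' endfeet, neuronal somata) plus the role of each label.
#'
#' @slot labels integer matrix; 0 = background.
#' @slot roles named character vector mapping label -> role
#'   (\code{"soma"}, \code{"endfoot"}, \code{"neuron_soma"}).
#' @export
setClass("CompartmentMasks",
  representation(labels = "matrix", roles = "character"))

setValidity("CompartmentMasks", function(object) {
  msg <- character()
  lab <- object@labels
  if (any(lab < 0) || any(lab != round(lab)))
    msg <- c(msg, "labels must be nonnegative integers")
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (length(ids)) {
    if (is.null(names(object@roles)) ||
        !all(as.character(ids) %in% names(object@roles)))
      msg <- c(msg, "every nonzero label needs a role")
    if (!all(object@roles %in% c("soma", "endfoot", "neuron_soma")))
      msg <- c(msg, "roles must be soma, endfoot or neuron_soma")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CompartmentMasks-class
#' @param labels labeled matrix (0 = background).
#' @param roles named character vector, names are label ids.
#' @return A \linkS4class{CompartmentMasks}.
#' @export
CompartmentMasks <- function(labels, roles) {
  storage.mode(labels) <- "double"
  new("CompartmentMasks", labels = labels, roles = roles)
}

#' DetectionParams: tuning of the activity-based microdomain detector
#'
#' All knobs of the detection stage. Presets encode the channel-specific
#' parameter triples used for in vivo astrocyte (Lck-GCaMP6f), in vivo neuron
#' (RCaMP1.07) and in vitro astrocyte movies; see
#' \code{\link{detectionParams}}.
#'
#' @slot boxcar_s sliding temporal boxcar length in seconds (default 5).
#' @slot amp_sd_mult amplitude threshold in units of the pixel noise SD
#'   (7 in vivo, 5 in vitro).
#' @slot rise_bounds_s allowed peak rise time, seconds (min, max).
#' @slot group_radius_um spatial grouping radius, micrometres (4).
#' @slot group_time_s temporal grouping gap, seconds (0.2 RCaMP,
#'   0.5 Lck-GCaMP6f).
#' @slot roi_threshold_q threshold on the normalized temporal projection
#'   (0.2).
#' @slot fp_alpha significance level of the ANOVA false-positive filter.
#' @slot surround_width_um width of the surround ring used by the
#'   false-positive test.
#' @slot boxcar_align \code{"centered"} (default) or \code{"trailing"}.
#' @slot normalization projection normalization, \code{"component"} maximum
#'   (default) or \code{"global"} maximum.
#' @export
setClass("DetectionParams",
  representation(boxcar_s = "numeric", amp_sd_mult = "numeric",
                 rise_bounds_s = "numeric", group_radius_um = "numeric",
                 group_time_s = "numeric", roi_threshold_q = "numeric",
                 fp_alpha = "numeric", surround_width_um = "numeric",
                 boxcar_align = "character", normalization = "character"))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@boxcar_s <= 0) msg <- c(msg, "boxcar_s must be > 0")
  if (object@amp_sd_mult <= 0) msg <- c(msg, "amp_sd_mult must be > 0")
  if (length(object@rise_bounds_s) != 2L ||
      !(object@rise_bounds_s[1L] < object@rise_bounds_s[2L]))
    msg <- c(msg, "rise_bounds_s must be an ordered (min, max) pair")
  if (object@group_radius_um <= 0) msg <- c(msg, "group_radius_um must be > 0")
  if (object@group_time_s < 0) msg <- c(msg, "group_time_s must be >= 0")
  if (!(object@roi_threshold_q > 0 && object@roi_threshold_q < 1))
    msg <- c(msg, "roi_threshold_q must be in (0, 1)")
  if (!(object@fp_alpha > 0 && object@fp_alpha < 1))
    msg <- c(msg, "fp_alpha must be in (0, 1)")
  if (object@surround_width_um <= 0)
    msg <- c(msg, "surround_width_um must be > 0")
  if (!object@boxcar_align %in% c("centered", "trailing"))
    msg <- c(msg, "boxcar_align must be 'centered' or 'trailing'")
  if (!object@normalization %in% c("component", "global"))
    msg <- c(msg, "normalization must be 'component' or 'global'")
  if (length(msg)) msg else TRUE
})

#' EventParams: tuning of per-trace event metrics
#'
#' @slot onset_sd_mult onset threshold in baseline-SD units (2.5).
#' @slot smooth_frames moving-average length for onset latency (odd, 5).
#' @slot peak_min_prominence_sd minimum peak prominence in baseline-SD units.
#' @slot prominence_floor absolute prominence fallback used when the baseline
#'   SD is zero (dF/F units).
#' @slot adaptation_window_s window after stimulus onset for the decay slope,
#'   seconds (0.5, 1.0).
#' @slot auc_mode \code{"window"} (trapezoid over the analysis window,
#'   default) or \code{"event"} (per-event spans).
#' @export
setClass("EventParams",
  representation(onset_sd_mult = "numeric", smooth_frames = "numeric",
                 peak_min_prominence_sd = "numeric",
                 prominence_floor = "numeric",
                 adaptation_window_s = "numeric", auc_mode = "character"))

setValidity("EventParams", function(object) {
  msg <- character()
  if (object@onset_sd_mult <= 0) msg <- c(msg, "onset_sd_mult must be > 0")
  sf <- object@smooth_frames
  if (sf < 1 || sf != round(sf) || sf %% 2 != 1)
    msg <- c(msg, "smooth_frames must be odd and >= 1")
  if (length(object@adaptation_window_s) != 2L ||
      !(object@adaptation_window_s[1L] < object@adaptation_window_s[2L]))
    msg <- c(msg, "adaptation_window_s must be an ordered (start, end) pair")
  if (!object@auc_mode %in% c("window", "event"))
    msg <- c(msg, "auc_mode must be 'window' or 'event'")
  if (length(msg)) msg else TRUE
})

#' @rdname EventParams-class
#' @param onset_sd_mult,smooth_frames,peak_min_prominence_sd,prominence_floor
#'   see slots.
#' @param adaptation_window_s,auc_mode see slots.
#' @return An \linkS4class{EventParams}.
#' @export
EventParams <- function(onset_sd_mult = 2.5, smooth_frames = 5,
                        peak_min_prominence_sd = 2, prominence_floor = 0.05,
                        adaptation_window_s = c(0.5, 1), auc_mode = "window") {
  new("EventParams", onset_sd_mult = onset_sd_mult,
      smooth_frames = smooth_frames,
      peak_min_prominence_sd = peak_min_prominence_sd,
      prominence_floor = prominence_floor,
      adaptation_window_s = adaptation_window_s, auc_mode = auc_mode)
}

#' ClassificationParams: population-level classification settings
#'
#' @slot barrel_area_um2 reference whisker-barrel area used to normalize ROI
#'   counts across fields of view (32,000 um^2).
#' @slot amp_cutoff_mid,amp_cutoff_high neuronal tier boundaries in dF/F
#'   (1.92, 3.47): low < 1.92 <= mid < 3.47 <= high.
#' @slot neuron_median_latency_s reference median onset latency for the
#'   fast/delayed split; NA means compute it from the cohort's neuronal
#'   events.
#' @slot corr_alpha significance level of pair correlations.
#' @slot corr_window post-onset window (s) for synchrony, default (0, 8).
#' @slot corr_adjust \code{"none"} (default) or \code{"BH"}.
#' @slot corr_summary \code{"per_trial"} (mean within trial then across
#'   trials, default) or \code{"pooled"}.
#' @slot repeat_min_trials minimum trials for the repeated-response score (2).
#' @export
setClass("ClassificationParams",
  representation(barrel_area_um2 = "numeric", amp_cutoff_mid = "numeric",
                 amp_cutoff_high = "numeric",
                 neuron_median_latency_s = "numeric", corr_alpha = "numeric",
                 corr_window = "numeric", corr_adjust = "character",
                 corr_summary = "character", repeat_min_trials = "numeric"))

setValidity("ClassificationParams", function(object) {
  msg <- character()
  if (object@barrel_area_um2 <= 0) msg <- c(msg, "barrel_area_um2 must be > 0")
  if (!(object@amp_cutoff_mid < object@amp_cutoff_high))
    msg <- c(msg, "amplitude cutoffs must be ordered")
  if (!(object@corr_alpha > 0 && object@corr_alpha < 1))
    msg <- c(msg, "corr_alpha must be in (0, 1)")
  if (length(object@corr_window) != 2L ||
      !(object@corr_window[1L] < object@corr_window[2L]))
    msg <- c(msg, "corr_window must be an ordered (start, end) pair")
  if (!object@corr_adjust %in% c("none", "BH"))
    msg <- c(msg, "corr_adjust must be 'none' or 'BH'")
  if (!object@corr_summary %in% c("per_trial", "pooled"))
    msg <- c(msg, "corr_summary must be 'per_trial' or 'pooled'")
  if (object@repeat_min_trials < 1)
    msg <- c(msg, "repeat_min_trials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ClassificationParams-class
#' @param barrel_area_um2,amp_cutoff_mid,amp_cutoff_high see slots.
#' @param neuron_median_latency_s,corr_alpha,corr_window see slots.
#' @param corr_adjust,corr_summary,repeat_min_trials see slots.
#' @return A \linkS4class{ClassificationParams}.
#' @export
ClassificationParams <- function(barrel_area_um2 = 32000,
                                 amp_cutoff_mid = 1.92,
                                 amp_cutoff_high = 3.47,
                                 neuron_median_latency_s = NA_real_,
                                 corr_alpha = 0.05, corr_window = c(0, 8),
                                 corr_adjust = "none",
                                 corr_summary = "per_trial",
                                 repeat_min_trials = 2) {
  new("ClassificationParams", barrel_area_um2 = barrel_area_um2,
      amp_cutoff_mid = amp_cutoff_mid, amp_cutoff_high = amp_cutoff_high,
      neuron_median_latency_s = neuron_median_latency_s,
      corr_alpha = corr_alpha, corr_window = corr_window,
      corr_adjust = corr_adjust, corr_summary = corr_summary,
      repeat_min_trials = repeat_min_trials)
}

#' BehaviorParams: exploration-time criteria for the recognition tests
#'
#' @slot proximity_cm nose-to-object distance threshold (2 cm).
#' @slot facing_halfangle_deg half-angle between the body-to-nose axis and
#'   the nose-to-object bearing that still counts as "facing" (45 deg).
#' @slot min_total_exploration_s exclusion threshold on total investigation
#'   time (2 s).
#' @slot learning_duration_s,testing_duration_s phase lengths (300 s, 180 s).
#' @slot arena_size_cm square arena edge (40 cm).
#' @slot object_radius_cm object footprint radius for the climbing exclusion.
#' @slot likelihood_min keypoint confidence gate; frames with lower pose
#'   likelihood are treated as non-exploratory.
#' @export
setClass("BehaviorParams",
  representation(proximity_cm = "numeric", facing_halfangle_deg = "numeric",
                 min_total_exploration_s = "numeric",
                 learning_duration_s = "numeric",
                 testing_duration_s = "numeric", arena_size_cm = "numeric",
                 object_radius_cm = "numeric", likelihood_min = "numeric"))

setValidity("BehaviorParams", function(object) {
  msg <- character()
  if (object@proximity_cm <= 0) msg <- c(msg, "proximity_cm must be > 0")
  if (!(object@facing_halfangle_deg > 0 &&
        object@facing_halfangle_deg <= 90))
    msg <- c(msg, "facing_halfangle_deg must be in (0, 90]")
  if (object@min_total_exploration_s < 0)
    msg <- c(msg, "min_total_exploration_s must be >= 0")
  if (object@arena_size_cm <= 0) msg <- c(msg, "arena_size_cm must be > 0")
  if (object@object_radius_cm < 0)
    msg <- c(msg, "object_radius_cm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BehaviorParams-class
#' @param proximity_cm,facing_halfangle_deg,min_total_exploration_s see slots.
#' @param learning_duration_s,testing_duration_s,arena_size_cm see slots.
#' @param object_radius_cm,likelihood_min see slots.
#' @return A \linkS4class{BehaviorParams}.
#' @export
BehaviorParams <- function(proximity_cm = 2, facing_halfangle_deg = 45,
                           min_total_exploration_s = 2,
                           learning_duration_s = 300,
                           testing_duration_s = 180, arena_size_cm = 40,
                           object_radius_cm = 2, likelihood_min = 0.6) {
  new("BehaviorParams", proximity_cm = proximity_cm,
      facing_halfangle_deg = facing_halfangle_deg,
      min_total_exploration_s = min_total_exploration_s,
      learning_duration_s = learning_duration_s,
      testing_duration_s = testing_duration_s, arena_size_cm = arena_size_cm,
      object_radius_cm = object_radius_cm, likelihood_min = likelihood_min)
}

#' ROISet: labeled 2D microdomain ROIs with provenance
#'
#' Produced by the detection stage. Each ROI is a 2D footprint (a set of
#' pixels) plus the frames during which its parent spatiotemporal component
#' was active. Footprints from temporally distinct components may overlap;
#' \code{labelImage} renders them with higher ids painted last, while
#' \code{footprints} keeps each ROI's exact pixel set.
#'
#' @slot labelImage integer matrix of ROI labels (0 = background).
#' @slot footprints list of integer vectors of linear pixel indices
#'   (column-major, as returned by \code{which} on a matrix).
#' @slot activeFrames list of integer vectors of 1-based frame indices.
#' @slot info data.frame, one row per ROI: \code{id}, \code{area_px},
#'   \code{area_um2}, \code{fp_pvalue}, \code{fp_flag}, \code{compartment},
#'   \code{channel}.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("ROISet",
  representation(labelImage = "matrix", footprints = "list",
                 activeFrames = "list", info = "data.frame",
                 pixelSize = "numeric"))

setValidity("ROISet", function(object) {
  msg <- character()
  n <- nrow(object@info)
  if (length(object@footprints) != n || length(object@activeFrames) != n)
    msg <- c(msg, "footprints/activeFrames must match info rows")
  if (n > 0) {
    if (!identical(object@info$id, seq_len(n)))
      msg <- c(msg, "ROI ids must be consecutive positive integers")
    if (any(lengths(object@footprints) < 1L))
      msg <- c(msg, "ROI areas must be >= 1 px")
  }
  if (length(msg)) msg else TRUE
})

#' ROITrace: the dF/F signal vector of one ROI
#'
#' dF/F is computed against the mean raw ROI intensity over the baseline
#' window (the first seconds of the trial), so a flat trace at baseline level
#' maps to zero everywhere.
#'
#' @slot roiId ROI identifier.
#' @slot dff per-frame dF/F vector.
#' @slot frameRate frames per second.
#' @slot baselineMean,baselineSd statistics of dF/F over the baseline window.
#' @export
setClass("ROITrace",
  representation(roiId = "numeric", dff = "numeric", frameRate = "numeric",
                 baselineMean = "numeric", baselineSd = "numeric"))

setValidity("ROITrace", function(object) {
  if (length(object@dff) < 2L) return("dff must have >= 2 samples")
  if (object@baselineSd < 0) return("baselineSd must be >= 0")
  TRUE
})

#' PlantedEvent: one ground-truth synthetic microdomain event
#'
#' @slot footprint logical matrix the size of the frame; the contiguous
#'   (4-connected) set of pixels the event occupies.
#' @slot onset_s event start time (s).
#' @slot rise_s linear rise time from onset to peak (s).
#' @slot decay_s exponential decay time constant after the peak (s).
#' @slot amplitude_dff peak amplitude as a fraction of the local baseline.
#' @slot compartment one of soma, endfoot, process, neuron.
#' @export
setClass("PlantedEvent",
  representation(footprint = "matrix", onset_s = "numeric",
                 rise_s = "numeric", decay_s = "numeric",
                 amplitude_dff = "numeric", compartment = "character"))

setValidity("PlantedEvent", function(object) {
  msg <- character()
  fp <- object@footprint
  if (!is.logical(fp) || !any(fp))
    msg <- c(msg, "footprint must be a nonempty logical matrix")
  else if (!.isConnected4(fp))
    msg <- c(msg, "footprint must be 4-connected")
  if (object@rise_s <= 0) msg <- c(msg, "rise_s must be > 0")
  if (object@decay_s <= 0) msg <- c(msg, "decay_s must be > 0")
  if (object@amplitude_dff <= 0) msg <- c(msg, "amplitude_dff must be > 0")
  if (object@onset_s < 0) msg <- c(msg, "onset_s must be >= 0")
  if (!object@compartment %in% .COMPARTMENTS)
    msg <- c(msg, "unknown compartment")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedEvent-class
#' @param footprint,onset_s,rise_s,decay_s,amplitude_dff,compartment see
#'   slots.
#' @return A \linkS4class{PlantedEvent}.
#' @export
PlantedEvent <- function(footprint, onset_s, rise_s, decay_s, amplitude_dff,
                         compartment = "process") {
  new("PlantedEvent", footprint = footprint, onset_s = onset_s,
      rise_s = rise_s, decay_s = decay_s, amplitude_dff = amplitude_dff,
      compartment = compartment)
}

#' SyntheticTruth: the full specification of a ground-truthed movie
#'
#' Everything \code{\link{generateMovie}} needs, plus the seed, so a
#' synthetic movie is a pure function of this object.
#'
#' @slot events list of \linkS4class{PlantedEvent}.
#' @slot baselineImage 2D baseline fluorescence texture.
#' @slot noiseSd per-pixel noise scale (intensity units).
#' @slot noiseModel \code{"gaussian"} (default) or \code{"poisson"}.
#' @slot protocol a \linkS4class{TrialProtocol}.
#' @slot frameRate,pixelSize acquisition geometry.
#' @slot channel,context movie metadata.
#' @slot seed integer RNG seed recorded in all outputs.
#' @export
setClass("SyntheticTruth",
  representation(events = "list", baselineImage = "matrix",
                 noiseSd = "numeric", noiseModel = "character",
                 protocol = "TrialProtocol", frameRate = "numeric",
                 pixelSize = "numeric", channel = "character",
                 context = "character", seed = "numeric"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  dm <- dim(object@baselineImage)
  for (ev in object@events) {
    if (!is(ev, "PlantedEvent")) {
      msg <- c(msg, "events must be PlantedEvent objects"); break
    }
    if (!identical(dim(ev@footprint), dm)) {
      msg <- c(msg, "event footprints must match the frame geometry"); break
    }
    if (ev@onset_s >= object@protocol@trial_len_s) {
      msg <- c(msg, "event onset must lie within the trial"); break
    }
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@seed) != 1L || !is.finite(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' AmplitudeModel: log-normal neuronal event-amplitude distribution
#'
#' Amplitude \eqn{A} (dF/F) follows
#' \eqn{\log A \sim N(\mathrm{logMu}, \mathrm{logSigma}^2)}. Calibrated from
#' two printed quantiles by \code{\link{calibrateAmplitudeModel}}.
#'
#' @slot logMu,logSigma log-scale location and scale (logSigma > 0).
#' @export
setClass("AmplitudeModel",
  representation(logMu = "numeric", logSigma = "numeric"))

setValidity("AmplitudeModel", function(object) {
  if (!(object@logSigma > 0)) return("logSigma must be > 0")
  TRUE
})

#' RunConfig: one reproducible pipeline run
#'
#' Bundles the per-stage parameter objects, the synthetic-data specification,
#' the RNG seed and the output directory; see \code{\link{runPipeline}} and
#' \code{\link{readRunConfig}}.
#'
#' @slot synth named list describing the synthetic movies to generate
#'   (\code{n_movies}, \code{n_events}, \code{ny}, \code{nx},
#'   \code{frame_rate_hz}, \code{pixel_size_um}, \code{amplitude_range},
#'   \code{noise_sd}, ...).
#' @slot detection,events,classification,behavior stage parameter objects.
#' @slot protocol trial timing.
#' @slot seed integer seed recorded in all outputs.
#' @slot outDir output directory.
#' @export
setClass("RunConfig",
  representation(synth = "list", detection = "DetectionParams",
                 events = "EventParams",
                 classification = "ClassificationParams",
                 behavior = "BehaviorParams", protocol = "TrialProtocol",
                 seed = "numeric", outDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || !is.finite(object@seed) ||
      object@seed != round(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@outDir) != 1L || !nzchar(object@outDir))
    msg <- c(msg, "outDir must be a nonempty path")
  if (length(msg)) msg else TRUE
})
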