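#' @include AllClasses.R
NULL

#' Accessors for movie, ROI and trace objects
#'
#' Standard accessors; user code should use these rather than reaching into
#' slots.
#'
#' @param x an object.
#' @return The corresponding slot value (see details per method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("footprints", function(x) standardGeneric("footprints"))
#' @rdname accessors
#' @export
setGeneric("activeFrames", function(x) standardGeneric("activeFrames"))
#' @rdname accessors
#' @export
setGeneric("roiInfo", function(x) standardGeneric("roiInfo"))
#' @rdname accessors
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))
#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setMethod("frames", "MovieStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameRate", "MovieStack", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("pixelSize", "MovieStack", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("channel", "MovieStack", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@frames)[1L])

#' @rdname accessors
#' @export
setMethod("frameTimes", "MovieStack", function(x)
  (seq_len(dim(x@frames)[1L]) - 1) / x@frameRate)

#' @rdname accessors
#' @export
setMethod("labelImage", "ROISet", function(x) x@labelImage)
#' @rdname accessors
#' @export
setMethod("footprints", "ROISet", function(x) x@footprints)
#' @rdname accessors
#' @export
setMethod("activeFrames", "ROISet", function(x) x@activeFrames)
#' @rdname accessors
#' @export
setMethod("roiInfo", "ROISet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("nROIs", "ROISet", function(x) nrow(x@info))
#' @rdname accessors
#' @export
setMethod("pixelSize", "ROISet", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("dff", "ROITrace", function(x) x@dff)
#' @rdname accessors
#' @export
setMethod("frameRate", "ROITrace", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("truthEvents", "SyntheticTruth", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("frameRate", "SyntheticTruth", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SyntheticTruth", function(x) x@pixelSize)

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "MovieStack: %d frames of %d x %d px (%.3g fps, %.3g um/px)\n",
    d[1L], d[2L], d[3L], object@frameRate, object@pixelSize))
  cat(sprintf("  channel: %s  context: %s  duration: %.2f s\n",
              object@channel, object@context, d[1L] / object@frameRate))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROIs on a %d x %d px frame\n", nrow(object@info),
              nrow(object@labelImage), ncol(object@labelImage)))
  if (nrow(object@info)) {
    cat(sprintf("  area (px): median %.0f [%.0f, %.0f]\n",
                stats::median(object@info$area_px),
                min(object@info$area_px), max(object@info$area_px)))
    cmp <- table(object@info$compartment)
    cat("  compartments:",
        paste(sprintf("%s=%d", names(cmp), cmp), collapse = " "), "\n")
  }
})

setMethod("show", "ROITrace", function(object) {
  cat(sprintf(
    "ROITrace (roi %g): %d frames at %.3g fps; baseline sd %.4g dF/F\n",
    object@roiId, length(object@dff), object@frameRate, object@baselineSd))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d planted events on %d x %d px, %.3g fps, seed %d\n",
    length(object@events), nrow(object@baselineImage),
    ncol(object@baselineImage), object@frameRate, as.integer(object@seed)))
})

setMethod("show", "AmplitudeModel", function(object) {
  cat(sprintf("AmplitudeModel: log-normal(logMu = %.4g, logSigma = %.4g)\n",
              object@logMu, object@logSigma))
})

setMethod("show", "TrialProtocol", function(object) {
  cat(sprintf(
    "TrialProtocol: %gs baseline | stim at %gs%s | %gs analysis | %gs trial\n",
    object@baseline_s, object@stim_onset_s,
    if (object@stim_present) "" else " (absent)",
    object@analysis_window_s, object@trial_len_s))
})
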