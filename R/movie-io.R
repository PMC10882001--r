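#' @include AllClasses.R utils.R
NULL

.sidecarPath <- function(path) paste0(path, ".meta.yaml")

#' Read a multi-frame grayscale TIFF movie
#'
#' Frame rate and pixel size are required metadata: TIFF tags are unreliable
#' across microscopes, so absence is an error, never a guess. Movies written
#' by \code{\link{writeMovie}} carry a \code{<path>.meta.yaml} sidecar from
#' which metadata (and, for floating-point data, the intensity scale) is
#' recovered; explicit arguments override the sidecar.
#'
#' @param path path to a multi-frame grayscale TIFF.
#' @param frameRate frames per second.
#' @param pixelSize micrometres per pixel.
#' @param channel,context movie metadata; see \linkS4class{MovieStack}.
#' @return A \linkS4class{MovieStack}; integer input intensities are
#'   preserved bit-exactly.
#' @seealso \code{\link{writeMovie}}
#' @export
readMovie <- function(path, frameRate = NULL, pixelSize = NULL,
                      channel = NULL, context = NULL) {
  if (!file.exists(path))
    stop("movie file does not exist: ", path)
  meta <- if (file.exists(.sidecarPath(path)))
    yaml::read_yaml(.sidecarPath(path)) else list()
  frameRate <- frameRate %||% meta$frame_rate_hz
  pixelSize <- pixelSize %||% meta$pixel_size_um
  channel <- channel %||% meta$channel %||% "other"
  context <- context %||% meta$context %||% "in_vivo"
  if (is.null(frameRate))
    stop("frame rate metadata is required (no sidecar found and no ",
         "frameRate given)")
  if (is.null(pixelSize))
    stop("pixel size metadata is required (no sidecar found and no ",
         "pixelSize given)")
  imgs <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  if (length(imgs) < 2L)
    stop("movie must have >=2 frames (got ", length(imgs), ")")
  if (any(vapply(imgs, function(m) length(dim(m)) != 2L, logical(1))))
    stop("movie must be grayscale (single-channel frames)")
  bits <- attr(imgs[[1L]], "bits.per.sample") %||% 16L
  arr <- aperm(simplify2array(
    lapply(imgs, function(m) matrix(m, nrow(m), ncol(m)))), c(3L, 1L, 2L))
  if (bits <= 16L) {
    ## integer samples: undo the [0, 1] rescaling losslessly
    arr <- round(arr * (2^bits - 1))
  } else if (!is.null(meta$intensity_scale)) {
    arr <- arr * meta$intensity_scale
  }
  MovieStack(arr, frameRate = frameRate, pixelSize = pixelSize,
             channel = channel, context = context)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a movie as a multi-frame TIFF with a metadata sidecar
#'
#' Integer-valued movies within [0, 65535] are stored as 16-bit samples and
#' round-trip losslessly. Other movies are stored as 32-bit float after
#' division by a power-of-two scale recorded in the sidecar (so the mantissa
#' is unchanged by scaling; storage precision is that of single-precision
#' float).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "MovieStack"))
  arr <- frames(movie)
  meta <- list(frame_rate_hz = frameRate(movie),
               pixel_size_um = pixelSize(movie), channel = channel(movie),
               context = movie@context)
  isInt <- all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 65535
  nT <- dim(arr)[1L]
  if (isInt) {
    lst <- lapply(seq_len(nT), function(t) arr[t, , ] / 65535)
    tiff::writeTIFF(lst, path, bits.per.sample = 16L, compression = "none")
  } else {
    if (min(arr) < 0)
      stop("cannot store movies with negative intensities")
    scale <- 2^ceiling(log2(max(max(arr), 1)))
    meta$intensity_scale <- scale
    lst <- lapply(seq_len(nT), function(t) arr[t, , ] / scale)
    tiff::writeTIFF(lst, path, bits.per.sample = 32L, compression = "none")
  }
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

#' Read / write labeled mask images (16-bit single-frame TIFF)
#'
#' @param labels integer matrix of labels (0 = background, max 65535).
#' @param path TIFF path.
#' @return \code{writeLabelMask}: invisibly, the path;
#'   \code{readLabelMask}: an integer label matrix.
#' @export
writeLabelMask <- function(labels, path) {
  if (any(labels < 0) || any(labels != round(labels)) || max(labels) > 65535)
    stop("labels must be integers in [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  m <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(m, "bits.per.sample") %||% 16L
  m <- round(matrix(m, nrow(m), ncol(m)) * (2^bits - 1))
  storage.mode(m) <- "integer"
  m
}

#' Export event and ROI tables (plus mask and provenance sidecar)
#'
#' Writes \code{events.csv} (one row per event), \code{rois.csv} (one row
#' per ROI, with active-frame intervals), \code{roi_mask.tif} (the labeled
#' footprint image, lossless), and \code{run.yaml} recording the
#' configuration and seed. Output is deterministic given (inputs, config,
#' seed): floats are written at 9 significant digits.
#'
#' @param events an event table (data.frame as built by
#'   \code{\link{buildEventTable}}); may have zero rows.
#' @param rois a \linkS4class{ROISet}.
#' @param path output directory (created if needed).
#' @param config optional configuration to embed in the sidecar (a
#'   \linkS4class{RunConfig} or plain list).
#' @param seed optional seed to record.
#' @return Invisibly, the paths written.
#' @export
writeTables <- function(events, rois, path, config = NULL, seed = NULL) {
  if (is.null(events) || is.null(rois))
    stop("events and rois must be non-null")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  evPath <- file.path(path, "events.csv")
  roiPath <- file.path(path, "rois.csv")
  maskPath <- file.path(path, "roi_mask.tif")
  .writeCsv(events, evPath)
  info <- roiInfo(rois)
  info$active_frames <- vapply(activeFrames(rois),
                               function(f) paste(f, collapse = ";"),
                               character(1))
  .writeCsv(info, roiPath)
  writeLabelMask(labelImage(rois), maskPath)
  side <- list(seed = if (is.null(seed)) NA else as.integer(seed))
  if (!is.null(config))
    side$config <- if (is(config, "RunConfig")) .configToList(config)
                   else config
  yaml::write_yaml(side, file.path(path, "run.yaml"))
  invisible(c(evPath, roiPath, maskPath))
}

## ---- RunConfig YAML (de)serialisation ----

.paramsToList <- function(p) {
  sl <- methods::slotNames(class(p))
  stats::setNames(lapply(sl, function(s) methods::slot(p, s)), sl)
}

.configToList <- function(config) {
  list(seed = as.integer(config@seed), out_dir = config@outDir,
       synth = config@synth,
       protocol = .paramsToList(config@protocol),
       detection = .paramsToList(config@detection),
       events = .paramsToList(config@events),
       classification = .paramsToList(config@classification),
       behavior = .paramsToList(config@behavior))
}

.listToParams <- function(cls, lst, defaults) {
  known <- methods::slotNames(cls)
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop(sprintf("invalid %s keys: %s", cls, paste(bad, collapse = ", ")))
  for (nm in names(lst)) methods::slot(defaults, nm) <- .coerceLike(
    methods::slot(defaults, nm), lst[[nm]])
  methods::validObject(defaults)
  defaults
}

.coerceLike <- function(template, value) {
  if (is.numeric(template)) as.numeric(unlist(value))
  else if (is.logical(template)) as.logical(unlist(value))
  else as.character(unlist(value))
}

#' Assemble or load a run configuration
#'
#' \code{RunConfig} builds a validated configuration from stage parameter
#' objects; \code{readRunConfig}/\code{writeRunConfig} round-trip it through
#' YAML. Unknown keys in a YAML file are an error naming the offending
#' fields.
#'
#' @param synth named list describing synthetic input generation; see
#'   \linkS4class{RunConfig}.
#' @param detection,events,classification,behavior stage parameter objects.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param seed integer seed.
#' @param outDir output directory.
#' @return A \linkS4class{RunConfig}.
#' @export
RunConfig <- function(synth = list(), detection = detectionParams(),
                      events = EventParams(),
                      classification = ClassificationParams(),
                      behavior = BehaviorParams(),
                      protocol = TrialProtocol(), seed = 1L,
                      outDir = "camd-run") {
  new("RunConfig", synth = synth, detection = detection, events = events,
      classification = classification, behavior = behavior,
      protocol = protocol, seed = as.numeric(seed), outDir = outDir)
}

#' @rdname RunConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lst <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "synth", "protocol", "detection", "events",
             "classification", "behavior")
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  RunConfig(
    synth = lst$synth %||% list(),
    detection = .listToParams("DetectionParams", lst$detection %||% list(),
                              detectionParams()),
    events = .listToParams("EventParams", lst$events %||% list(),
                           EventParams()),
    classification = .listToParams("ClassificationParams",
                                   lst$classification %||% list(),
                                   ClassificationParams()),
    behavior = .listToParams("BehaviorParams", lst$behavior %||% list(),
                             BehaviorParams()),
    protocol = .listToParams("TrialProtocol", lst$protocol %||% list(),
                             TrialProtocol()),
    seed = lst$seed %||% 1L,
    outDir = lst$out_dir %||% "camd-run")
}

#' @rdname RunConfig
#' @param config a \linkS4class{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}
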