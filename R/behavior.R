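#' @include AllClasses.R utils.R
NULL

#' Read a pose-estimation keypoint table
#'
#' Expects the de-facto long layout: columns \code{frame}, \code{bodypart},
#' \code{x}, \code{y} and optionally \code{likelihood}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readKeypoints <- function(path) {
  if (!file.exists(path)) stop("keypoint file does not exist: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "bodypart", "x", "y")
  if (!all(need %in% names(d)))
    stop("keypoint table must have columns: ", paste(need, collapse = ", "))
  d
}

.trackWide <- function(track, part) {
  sub <- track[track$bodypart == part, , drop = FALSE]
  sub[order(sub$frame), , drop = FALSE]
}

#' Exploration time near each object
#'
#' A frame counts as investigating an object iff (1) the nose is within
#' \code{proximity_cm} of the object, (2) the animal faces it: the angle
#' between the body-center-to-nose axis and the nose-to-object bearing is
#' at most \code{facing_halfangle_deg}, and (3) the body center is not over
#' the object footprint (climbing is not investigation). Frames with
#' missing keypoints, or pose likelihood below \code{likelihood_min}, are
#' non-exploratory; more than 20\% missing frames is an error. If a frame
#' satisfies the criteria for both objects it is assigned to the nearer
#' one.
#'
#' @param track keypoint data.frame (see \code{\link{readKeypoints}}) with
#'   bodyparts \code{"nose"} and \code{"bodycentre"}.
#' @param objects data.frame with columns \code{name}, \code{x}, \code{y};
#'   two rows.
#' @param params a \linkS4class{BehaviorParams}.
#' @param frameRate video frame rate (fps).
#' @return Named numeric vector of exploration seconds, names =
#'   \code{objects$name}.
#' @export
explorationTime <- function(track, objects, params = BehaviorParams(),
                            frameRate = 30) {
  stopifnot(nrow(objects) == 2L)
  nose <- .trackWide(track, "nose")
  body <- .trackWide(track, "bodycentre")
  if (!nrow(nose) || !nrow(body))
    stop("track must contain 'nose' and 'bodycentre' keypoints")
  allFrames <- sort(unique(track$frame))
  nT <- length(allFrames)
  noseIdx <- match(allFrames, nose$frame)
  bodyIdx <- match(allFrames, body$frame)
  ok <- !is.na(noseIdx) & !is.na(bodyIdx)
  nx <- nose$x[noseIdx]; nyy <- nose$y[noseIdx]
  bx <- body$x[bodyIdx]; by <- body$y[bodyIdx]
  ok <- ok & is.finite(nx) & is.finite(nyy) & is.finite(bx) & is.finite(by)
  if ("likelihood" %in% names(track)) {
    ok <- ok & !is.na(nose$likelihood[noseIdx]) &
      nose$likelihood[noseIdx] >= params@likelihood_min &
      !is.na(body$likelihood[bodyIdx]) &
      body$likelihood[bodyIdx] >= params@likelihood_min
  }
  if (mean(!ok) > 0.2)
    stop(sprintf("missing keypoints in %.0f%% of frames (> 20%%)",
                 100 * mean(!ok)))
  counts <- stats::setNames(numeric(2L), objects$name)
  dists <- matrix(Inf, nT, 2L)
  eligible <- matrix(FALSE, nT, 2L)
  for (o in 1:2) {
    dx <- objects$x[o] - nx; dy <- objects$y[o] - nyy
    dObj <- sqrt(dx^2 + dy^2)
    vx <- nx - bx; vy <- nyy - by
    dotp <- vx * dx + vy * dy
    cosang <- dotp / (sqrt(vx^2 + vy^2) * pmax(dObj, .Machine$double.eps))
    cosang[dObj < 1e-9] <- 1  # nose on the object: facing by convention
    dBody <- sqrt((objects$x[o] - bx)^2 + (objects$y[o] - by)^2)
    eligible[, o] <- ok & dObj <= params@proximity_cm &
      cosang >= cos(params@facing_halfangle_deg * pi / 180) &
      dBody > params@object_radius_cm
    dists[, o] <- dObj
  }
  both <- eligible[, 1L] & eligible[, 2L]
  eligible[both, 1L] <- dists[both, 1L] <= dists[both, 2L]
  eligible[both, 2L] <- !eligible[both, 1L]
  counts[1L] <- sum(eligible[, 1L]) / frameRate
  counts[2L] <- sum(eligible[, 2L]) / frameRate
  counts
}

#' Discrimination index with exclusion rules
#'
#' \code{di = (t_novel - t_familiar) / (t_novel + t_familiar)}: 1 means
#' exclusive preference for the novel texture/object, 0 no preference.
#' A trial is excluded (di undefined) when the total investigation time is
#' below \code{min_total_exploration_s}, when only one (or neither) object
#' was explored in the testing phase, or when the learning phase had no
#' exploration (pass \code{learning_total_s} to apply that rule).
#'
#' @param t_novel_s,t_familiar_s exploration seconds (>= 0).
#' @param params a \linkS4class{BehaviorParams}.
#' @param learning_total_s optional total exploration in the learning
#'   phase.
#' @return One-row data.frame: \code{t_novel_s}, \code{t_familiar_s},
#'   \code{di}, \code{excluded}, \code{reason}.
#' @examples
#' discriminationIndex(45, 15)   # di = 0.5
#' discriminationIndex(1.5, 0.4) # excluded: total < 2 s
#' @export
discriminationIndex <- function(t_novel_s, t_familiar_s,
                                params = BehaviorParams(),
                                learning_total_s = NULL) {
  if (t_novel_s < 0 || t_familiar_s < 0)
    stop("exploration times must be >= 0")
  total <- t_novel_s + t_familiar_s
  excluded <- FALSE; reason <- ""
  if (!is.null(learning_total_s) && learning_total_s <= 0) {
    excluded <- TRUE; reason <- "no exploration in learning phase"
  } else if (total < params@min_total_exploration_s) {
    excluded <- TRUE
    reason <- sprintf("total exploration < %g s",
                      params@min_total_exploration_s)
  } else if (t_novel_s == 0 || t_familiar_s == 0) {
    excluded <- TRUE; reason <- "explored only one object in testing phase"
  }
  data.frame(t_novel_s = t_novel_s, t_familiar_s = t_familiar_s,
             di = if (excluded) NA_real_ else
               (t_novel_s - t_familiar_s) / total,
             excluded = excluded, reason = reason)
}
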