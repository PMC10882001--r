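#' @include AllClasses.R utils.R
NULL

#' Generate a ground-truthed keypoint trajectory for the recognition test
#'
#' Produces a pose-estimation-style keypoint table (one row per frame per
#' bodypart) in which the animal dwells near each object for a scheduled
#' number of seconds, in the exact geometry the exploration criteria demand
#' (nose within the proximity radius, body-to-nose axis facing the object,
#' body center off the object footprint), and wanders elsewhere otherwise.
#' By construction the exploration time recovered by
#' \code{\link{explorationTime}} equals the schedule to within one frame
#' duration. The trajectory is a pure function of (arguments, seed).
#'
#' @param objects data.frame with columns \code{name}, \code{x}, \code{y}
#'   (cm); exactly two rows, conventionally named \code{"novel"} and
#'   \code{"familiar"}.
#' @param schedule named numeric vector of intended exploration seconds,
#'   names matching \code{objects$name}.
#' @param params a \linkS4class{BehaviorParams}.
#' @param duration_s total trial length (s).
#' @param frameRate video frame rate (fps).
#' @param seed integer seed (controls the sub-threshold jitter).
#' @return data.frame with columns \code{frame} (0-based), \code{bodypart}
#'   (\code{"nose"}, \code{"bodycentre"}), \code{x}, \code{y},
#'   \code{likelihood}.
#' @export
generateTrajectory <- function(objects, schedule, params = BehaviorParams(),
                               duration_s = 180, frameRate = 30,
                               seed = 1L) {
  stopifnot(nrow(objects) == 2L, all(c("name", "x", "y") %in% names(objects)))
  if (!all(objects$name %in% names(schedule)))
    stop("schedule must name both objects")
  d <- sqrt(diff(objects$x)^2 + diff(objects$y)^2)
  if (d < 2 * params@proximity_cm)
    stop("objects closer than twice the proximity radius: ",
         "exploration assignment would be ambiguous")
  nT <- floor(duration_s * frameRate)
  dwellFrames <- round(schedule[objects$name] * frameRate)
  if (sum(dwellFrames) > nT)
    stop("schedule exceeds the trial duration")
  set.seed(as.integer(seed))
  arena <- params@arena_size_cm
  ## rest point: far corner-ward spot at least proximity + 3 cm from both
  rest <- c(arena / 2, arena * 0.875)
  noseDist <- min(params@proximity_cm * 0.5, params@proximity_cm - 0.3)
  bodyOffset <- max(params@object_radius_cm + 2 - noseDist, 2)
  nose <- matrix(NA_real_, nT, 2)
  body <- matrix(NA_real_, nT, 2)
  cursor <- 0L
  for (i in seq_len(2L)) {
    nf <- dwellFrames[i]
    if (nf == 0L) next
    obj <- c(objects$x[i], objects$y[i])
    ## approach bearing: from the rest point towards the object
    u <- obj - rest
    u <- u / sqrt(sum(u^2))
    jit <- matrix(stats::runif(nf * 2, -0.05, 0.05), nf, 2)
    nosePos <- matrix(obj - u * noseDist, nf, 2, byrow = TRUE) + jit
    bodyPos <- matrix(obj - u * (noseDist + bodyOffset), nf, 2, byrow = TRUE)
    rows <- cursor + seq_len(nf)
    nose[rows, ] <- nosePos
    body[rows, ] <- bodyPos
    cursor <- cursor + nf
  }
  if (cursor < nT) {
    rows <- (cursor + 1L):nT
    nf <- length(rows)
    jit <- matrix(stats::runif(nf * 2, -0.3, 0.3), nf, 2)
    nose[rows, ] <- matrix(rest, nf, 2, byrow = TRUE) + jit
    ## facing the arena wall, away from both objects
    body[rows, ] <- matrix(rest - c(0, 3), nf, 2, byrow = TRUE)
  }
  data.frame(
    frame = rep(seq_len(nT) - 1L, 2L),
    bodypart = rep(c("nose", "bodycentre"), each = nT),
    x = c(nose[, 1L], body[, 1L]),
    y = c(nose[, 2L], body[, 2L]),
    likelihood = 1)
}
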