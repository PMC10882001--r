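#' @include AllClasses.R
NULL

#' Calibrate the log-normal neuronal amplitude model from two quantiles
#'
#' Neuronal Ca2+ event amplitudes are well described by a log-normal
#' distribution; the responsiveness tiers are cut at its 88th and 98th
#' percentiles. Given those two printed quantile values this solves the
#' two-equation linear system \eqn{\log p_q = \mu + \sigma z_q} for
#' \eqn{(\mu, \sigma)} with standard-normal quantiles
#' \eqn{z_{0.88} \approx 1.1750} and \eqn{z_{0.98} \approx 2.0537}, so that
#' sampling from the model reproduces both quantiles asymptotically.
#'
#' @param p88_value the 88th-percentile amplitude (dF/F), default 1.92.
#' @param p98_value the 98th-percentile amplitude (dF/F), default 3.47.
#' @return An \linkS4class{AmplitudeModel}.
#' @examples
#' m <- calibrateAmplitudeModel(1.92, 3.47)
#' qlnorm(c(0.88, 0.98), m@logMu, m@logSigma)  # recovers the inputs
#' @export
calibrateAmplitudeModel <- function(p88_value = 1.92, p98_value = 3.47) {
  if (!(p88_value > 0 && p88_value < p98_value))
    stop("quantile values must satisfy 0 < p88_value < p98_value")
  z88 <- stats::qnorm(0.88)
  z98 <- stats::qnorm(0.98)
  logSigma <- (log(p98_value) - log(p88_value)) / (z98 - z88)
  logMu <- log(p88_value) - logSigma * z88
  new("AmplitudeModel", logMu = logMu, logSigma = logSigma)
}

#' Sample event amplitudes from an AmplitudeModel
#'
#' @param model an \linkS4class{AmplitudeModel}.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of amplitudes (dF/F).
#' @export
sampleAmplitudes <- function(model, n, seed = NULL) {
  stopifnot(is(model, "AmplitudeModel"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::rlnorm(n, meanlog = model@logMu, sdlog = model@logSigma)
}
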