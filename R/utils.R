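#' @include AllClasses.R
NULL

## 4-connected component labeling of a logical matrix (flood fill).
## Masks handled here are ROI-sized, so a plain BFS in R is adequate.
.label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
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
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

.isConnected4 <- function(mask) {
  lab <- .label4(mask)
  length(setdiff(unique(as.vector(lab)), 0L)) == 1L
}

## Disjoint-set forest with path halving.
.ufNew <- function(n) seq_len(n)

.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

## Centered moving average of length k (odd), truncated at the edges so the
## first and last samples average over fewer points instead of padded zeros.
.movingAverage <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Event-robust per-sample noise SD from median absolute first differences.
## For iid Gaussian noise, median(|x[t+1]-x[t]|) = sd * sqrt(2) * qnorm(3/4),
## and a transient occupying a minority of the samples barely moves the
## median -- unlike the classical SD, which the transient inflates.
.robustNoiseSd <- function(x) {
  d <- abs(diff(x))
  stats::median(d) / (sqrt(2) * stats::qnorm(0.75))
}

.olsSlope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Disk-shaped logical footprint
#'
#' Convenience builder for planted-event footprints: pixels within
#' \code{radius_px} of center \code{(r0, c0)} in an \code{nr x nc} frame.
#'
#' @param nr,nc frame size in pixels.
#' @param r0,c0 disc center (1-based row/col, may be fractional).
#' @param radius_px disc radius in pixels.
#' @return A logical matrix.
#' @export
diskFootprint <- function(nr, nc, r0, c0, radius_px) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - r0)^2 + (cols - c0)^2 <= radius_px^2
}

## Pixels within dist_px of any pixel in `pix` (linear indices), excluding
## `pix` itself. Search is restricted to the bounding box plus margin.
.ringAround <- function(pix, nr, nc, dist_px) {
  r <- ((pix - 1L) %% nr) + 1L
  cc <- ((pix - 1L) %/% nr) + 1L
  m <- ceiling(dist_px)
  rr <- max(1L, min(r) - m):min(nr, max(r) + m)
  ccr <- max(1L, min(cc) - m):min(nc, max(cc) + m)
  cand <- as.matrix(expand.grid(r = rr, c = ccr))
  d2 <- outer(cand[, 1L], r, "-")^2 + outer(cand[, 2L], cc, "-")^2
  near <- matrixStats_rowMins(d2) <= dist_px^2
  lin <- (cand[, 2L] - 1L) * nr + cand[, 1L]
  setdiff(lin[near], pix)
}

## Row minima without a matrixStats dependency.
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

## Deterministic, diffable CSV: numeric columns at 9 significant digits.
.writeCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 9, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Per-stage log line: stage, message, elapsed seconds, seed.
.logStage <- function(stage, msg, t0 = NULL, seed = NULL, verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  extra <- ""
  if (!is.null(t0))
    extra <- sprintf(" [%.2fs]", as.numeric(Sys.time()) - as.numeric(t0))
  if (!is.null(seed)) extra <- sprintf("%s seed=%d", extra, as.integer(seed))
  message(sprintf("[%s] %s%s", stage, msg, extra))
}

## Derive a per-stage substream seed from the run seed (kept below 2^31).
.subSeed <- function(seed, stage) {
  offs <- c(synth = 11L, detect = 23L, events = 37L, metrics = 53L,
            behave = 71L, evaluate = 89L)
  k <- offs[[stage]]
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}
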