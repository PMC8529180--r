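# Derived quantities: windowed firing rates, pairwise and distance-binned
# correlations, ON/OFF segmentation with burst statistics, simulated LFP,
# and ATP-rate phase trajectories.

#' Windowed instantaneous firing rates
#'
#' Per-neuron spike counts in centered rectangular moving windows (50 ms by
#' default), divided by the window length, on a regular grid covering the
#' post-discard epoch. Accepts a \linkS4class{SimulationResult} or a raw
#' raster data.frame (columns \code{neuron}, \code{timeMs}) plus epoch
#' bounds.
#'
#' @param x a \linkS4class{SimulationResult} or raster data.frame
#' @param windowMs rectangular window length, ms (default 50)
#' @param strideMs grid stride, ms (default 10)
#' @param n neuron count (required for a raw raster)
#' @param t0,t1 epoch bounds for a raw raster, ms
#' @return an \linkS4class{IFRMatrix}
#' @examples
#' r <- data.frame(neuron = c(1, 2), timeMs = c(500, 700))
#' ifr <- computeIFR(r, n = 2, t0 = 0, t1 = 1000)
#' max(popRate(ifr))
#' @export
computeIFR <- function(x, windowMs = 50, strideMs = 10, n = NULL,
                       t0 = NULL, t1 = NULL) {
  if (windowMs <= 0 || strideMs <= 0)
    stop("windowMs and strideMs must be positive")
  if (is(x, "SimulationResult")) {
    raster <- spikeTrain(x)
    n <- nNeurons(x)
    t0 <- x@discardMs
    t1 <- x@durationMs
  } else {
    raster <- x
    if (is.null(n)) stop("neuron count n is required for a raw raster")
    if (is.null(t0)) t0 <- 0
    if (is.null(t1)) t1 <- if (nrow(raster)) max(raster$timeMs) else
      stop("cannot infer the epoch of an empty raster; give t1")
  }
  raw <- cpp_ifr_matrix(as.integer(raster$neuron), as.numeric(raster$timeMs),
                        as.integer(n), t0, t1, windowMs, strideMs)
  new("IFRMatrix", timesMs = raw$centersMs, rates = raw$rates,
      windowMs = windowMs, strideMs = strideMs)
}

standardizeColumns <- function(rates) {
  # columns scaled to zero mean / unit SD; zero-variance columns become NA
  mu <- colMeans(rates)
  sd <- sqrt(colSums(rates^2) / nrow(rates) - mu^2) *
    sqrt(nrow(rates) / (nrow(rates) - 1))
  sd[sd < .Machine$double.eps^0.5] <- NA
  sweep(sweep(rates, 2, mu, "-"), 2, sd, "/")
}

pearsonPairs <- function(Z, ii, jj, chunk = 512L) {
  # Pearson r from pre-standardized columns; NA where a member had zero
  # variance. Chunked to bound the temporary matrix size.
  nT <- nrow(Z)
  r <- numeric(length(ii))
  for (lo in seq(1, length(ii), by = chunk)) {
    hi <- min(lo + chunk - 1, length(ii))
    r[lo:hi] <- colSums(Z[, ii[lo:hi], drop = FALSE] *
                          Z[, jj[lo:hi], drop = FALSE]) / (nT - 1)
  }
  r
}

#' Distance-binned pairwise rate correlation
#'
#' Pearson correlation of the per-neuron iFR series for neuron pairs,
#' averaged within distance bins (200 micrometres by default). Pairs are
#' subsampled uniformly per bin up to \code{maxPairsPerBin}; zero-variance
#' series are excluded from the averages and counted. Bins without pairs
#' are kept with \code{NA} mean.
#'
#' @param ifr an \linkS4class{IFRMatrix}
#' @param positions a \linkS4class{PositionSet} or coordinate matrix
#'   covering the same neurons
#' @param binUm bin width in micrometres (default 200)
#' @param maxPairsPerBin subsampling cap per bin (default 2000)
#' @param seed seed for the pair subsample
#' @return data.frame with columns \code{binCenterUm}, \code{meanR},
#'   \code{nPairs}, \code{nExcluded}
#' @export
distanceBinnedCorrelation <- function(ifr, positions, binUm = 200,
                                      maxPairsPerBin = 2000, seed = 1) {
  co <- if (is(positions, "PositionSet")) positions@coords else positions
  n <- ncol(ifr@rates)
  if (nrow(co) != n)
    stop("positions and rate matrix cover different neuron counts")
  set.seed(seed)
  # distances of all pairs are needed only binwise; sample pairs lazily by
  # drawing a generous pool and binning it, topping up small bins from the
  # exhaustive set when n is small
  maxD <- sqrt(diff(range(co[, 1]))^2 + diff(range(co[, 2]))^2) * 1000
  breaks <- seq(0, ceiling(maxD / binUm) * binUm, by = binUm)
  centers <- breaks[-1] - binUm / 2
  if (n <= 300) {
    pr <- t(utils::combn(n, 2))
    ii <- pr[, 1]; jj <- pr[, 2]
  } else {
    m <- min(as.double(n) * (n - 1) / 2,
             length(centers) * maxPairsPerBin * 6)
    ii <- sample.int(n, m, replace = TRUE)
    jj <- sample.int(n, m, replace = TRUE)
    keep <- ii < jj
    ii <- ii[keep]; jj <- jj[keep]
    dup <- duplicated(ii * as.double(n) + jj)
    ii <- ii[!dup]; jj <- jj[!dup]
  }
  d <- sqrt((co[ii, 1] - co[jj, 1])^2 + (co[ii, 2] - co[jj, 2])^2) * 1000
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  Z <- standardizeColumns(ifr@rates)
  out <- data.frame(binCenterUm = centers, meanR = NA_real_, nPairs = 0L,
                    nExcluded = 0L)
  for (b in seq_along(centers)) {
    sel <- which(bin == b)
    if (!length(sel)) next
    if (length(sel) > maxPairsPerBin) sel <- sample(sel, maxPairsPerBin)
    r <- pearsonPairs(Z, ii[sel], jj[sel])
    out$nExcluded[b] <- sum(is.na(r))
    r <- r[!is.na(r)]
    out$nPairs[b] <- length(r)
    if (length(r)) out$meanR[b] <- mean(r)
  }
  nex <- sum(out$nExcluded)
  if (nex > 0)
    message(sprintf("%d pairs excluded for zero-variance rate series", nex))
  out
}

#' Mean pairwise rate correlation
#'
#' Average Pearson correlation over distinct neuron pairs of the iFR
#' series - the global synchrony summary. Pairs are subsampled uniformly up
#' to \code{maxPairs}; zero-variance series are excluded.
#'
#' @param ifr an \linkS4class{IFRMatrix}
#' @param maxPairs subsampling cap (default 20000)
#' @param seed seed for the subsample
#' @return mean Pearson r (scalar)
#' @export
meanPairwiseCorrelation <- function(ifr, maxPairs = 20000, seed = 1) {
  n <- ncol(ifr@rates)
  Z <- standardizeColumns(ifr@rates)
  if (sum(!is.na(colSums(Z))) < 2)
    stop("need at least two non-constant rate series")
  set.seed(seed)
  tot <- as.double(n) * (n - 1) / 2
  if (tot <= maxPairs) {
    pr <- t(utils::combn(n, 2))
    ii <- pr[, 1]; jj <- pr[, 2]
  } else {
    ii <- sample.int(n, 3 * maxPairs, replace = TRUE)
    jj <- sample.int(n, 3 * maxPairs, replace = TRUE)
    keep <- ii < jj
    ii <- ii[keep][seq_len(min(sum(keep), maxPairs))]
    jj <- jj[keep][seq_len(length(ii))]
  }
  r <- pearsonPairs(Z, ii, jj)
  mean(r, na.rm = TRUE)
}

#' Threshold segmentation into ON and OFF periods
#'
#' Applies a rate threshold (1 Hz by default) to the population iFR series:
#' maximal sub-threshold intervals are OFF, the rest ON. Segments shorter
#' than \code{minSegmentMs} are merged into their neighbours (shortest
#' first) so labels alternate and the intervals tile the epoch exactly.
#' Each ON interval carries its peak population rate.
#'
#' @param x an \linkS4class{IFRMatrix} (its population mean is used) or a
#'   numeric rate series
#' @param thresholdHz OFF threshold (default 1 Hz)
#' @param minSegmentMs minimal segment length (default 50 ms)
#' @param timesMs grid times when \code{x} is a numeric series
#' @param strideMs grid stride when \code{x} is a numeric series
#' @return an \linkS4class{OnOffSegmentation}
#' @examples
#' pop <- rep(c(0, 30), each = 100)
#' seg <- detectOnOff(pop, timesMs = seq(5, by = 10, length.out = 200),
#'                    strideMs = 10)
#' intervals(seg)
#' @export
detectOnOff <- function(x, thresholdHz = 1, minSegmentMs = 50,
                        timesMs = NULL, strideMs = NULL) {
  if (thresholdHz <= 0) stop("thresholdHz must be positive")
  if (is(x, "IFRMatrix")) {
    pop <- popRate(x)
    timesMs <- x@timesMs
    strideMs <- x@strideMs
  } else {
    pop <- as.numeric(x)
    if (is.null(timesMs) || is.null(strideMs))
      stop("timesMs and strideMs are required for a raw series")
  }
  off <- pop < thresholdHz
  r <- rle(off)
  # merge short segments, shortest first, until all reach the minimum
  while (length(r$lengths) > 1 &&
         min(r$lengths) * strideMs < minSegmentMs) {
    k <- which.min(r$lengths)
    r$values[k] <- !r$values[k]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  # interval edges: half a stride around the covered grid points
  startMs <- timesMs[starts] - strideMs / 2
  endMs <- timesMs[ends] + strideMs / 2
  peak <- vapply(seq_along(starts), function(k) {
    if (r$values[k]) NA_real_ else max(pop[starts[k]:ends[k]])
  }, numeric(1))
  iv <- data.frame(label = ifelse(r$values, "OFF", "ON"),
                   startMs = startMs, endMs = endMs,
                   durationMs = endMs - startMs, peakHz = peak)
  new("OnOffSegmentation", intervals = iv, thresholdHz = thresholdHz,
      minSegmentMs = minSegmentMs)
}

#' OFF-duration / ON-peak correlations
#'
#' Pairs each OFF period with the following ON period's peak rate
#' ("OFF pre vs. ON post") and each ON peak with the following OFF duration
#' ("ON pre vs. OFF post"), and returns the two Pearson coefficients. The
#' first and last intervals are excluded (their extent is censored by the
#' epoch edges). At least 3 complete adjacencies of each kind are required.
#'
#' @param seg an \linkS4class{OnOffSegmentation}
#' @return list with \code{rOffPreOnPost}, \code{rOnPreOffPost},
#'   \code{nOffOn}, \code{nOnOff} and the paired samples
#' @export
offOnPeakStatistics <- function(seg) {
  iv <- intervals(seg)
  m <- nrow(iv)
  offDur <- c(); onPeak <- c(); onPeakPre <- c(); offDurPost <- c()
  for (k in seq_len(m)) {
    if (k == 1 || k >= m) next  # censored boundary intervals
    if (iv$label[k] == "OFF" && iv$label[k + 1] == "ON" && k + 1 < m) {
      offDur <- c(offDur, iv$durationMs[k])
      onPeak <- c(onPeak, iv$peakHz[k + 1])
    }
    if (iv$label[k] == "ON" && iv$label[k + 1] == "OFF" && k + 1 < m) {
      onPeakPre <- c(onPeakPre, iv$peakHz[k])
      offDurPost <- c(offDurPost, iv$durationMs[k + 1])
    }
  }
  if (length(offDur) < 3 || length(onPeakPre) < 3)
    stop(sprintf(
      "too few complete ON/OFF cycles for correlation (%d OFF->ON, %d ON->OFF; need 3)",
      length(offDur), length(onPeakPre)))
  list(rOffPreOnPost = stats::cor(offDur, onPeak),
       rOnPreOffPost = stats::cor(onPeakPre, offDurPost),
       nOffOn = length(offDur), nOnOff = length(onPeakPre),
       offDurationMs = offDur, onPeakHz = onPeak,
       onPeakPreHz = onPeakPre, offDurationPostMs = offDurPost)
}

#' Distance weighting of a neuron's LFP contribution
#'
#' Flat within 100 micrometres of the electrode, inverse-square beyond:
#' \eqn{f(l) = 1} for \eqn{l \le 100\,\mu m}, \eqn{(l/100)^{-2}} beyond,
#' continuous at the break.
#'
#' @param lUm distance in micrometres (vectorized)
#' @return weight in (0, 1]
#' @examples
#' shapeFunction(c(50, 100, 200))
#' @export
shapeFunction <- function(lUm) {
  if (any(lUm < 0)) stop("distance must be non-negative")
  ifelse(lUm <= 100, 1, (lUm / 100)^-2)
}

#' Simulated local field potential
#'
#' Negative sum of all neurons' incoming excitatory postsynaptic currents,
#' weighted by the distance shape function between each neuron and the
#' electrode: \eqn{sLFP(t) = -\sum_i f(l_i)\, EPSC_i(t)}. High firing
#' produces large negative deflections. Requires per-neuron synaptic-current
#' traces for all neurons (simulate with \code{traceNeurons = "all"}).
#'
#' @param result a \linkS4class{SimulationResult} with full synaptic traces
#' @param network the \linkS4class{SpatialNetwork} that was simulated
#' @param electrodeXy electrode position, mm (default: sheet centre)
#' @return data.frame with columns \code{timeMs}, \code{slfp}
#' @export
simulateLFP <- function(result, network,
                        electrodeXy = c(network@positions@widthMm / 2,
                                        network@positions@heightMm / 2)) {
  tr <- result@traces
  if (is.null(tr) || is.null(tr$syn) || ncol(tr$syn) < nNeurons(network))
    stop("per-neuron synaptic traces missing: rerun simulateNetwork with ",
         "traceStrideMs > 0 and traceNeurons = \"all\"")
  co <- positions(network)[tr$neurons, , drop = FALSE]
  lUm <- sqrt((co[, 1] - electrodeXy[1])^2 +
              (co[, 2] - electrodeXy[2])^2) * 1000
  w <- shapeFunction(lUm)
  data.frame(timeMs = tr$timeMs, slfp = -as.numeric(tr$syn %*% w))
}

#' ATP-rate phase trajectory
#'
#' Population-mean ATP paired with the population iFR, both smoothed on a
#' common moving window (50 ms default), tracing the slow orbit of the
#' collective state: a point-like cloud in the continuous regime, a closed
#' loop touching zero rate under burst suppression. Requires population
#' traces (\code{traceStrideMs > 0}).
#'
#' @param result a \linkS4class{SimulationResult} with population traces
#' @param windowMs moving-average window, ms (default 50)
#' @return data.frame with columns \code{timeMs}, \code{atp}, \code{ifrHz}
#' @export
phaseTrajectory <- function(result, windowMs = 50) {
  tr <- result@traces
  if (is.null(tr) || is.null(tr$popAtp))
    stop("population ATP trace missing: rerun simulateNetwork with ",
         "traceStrideMs > 0 and recordPopulation = TRUE")
  ifr <- computeIFR(result, windowMs = windowMs, strideMs = tr$strideMs)
  pop <- popRate(ifr)
  # align the ATP trace (sampled at strideMs from t = 0) on the iFR grid
  # and smooth it with the same window
  k <- max(1L, round(windowMs / tr$strideMs))
  atpSm <- as.numeric(stats::filter(tr$popAtp, rep(1 / k, k), sides = 2))
  okTr <- !is.na(atpSm)
  atpOnGrid <- stats::approx(tr$timeMs[okTr], atpSm[okTr],
                             xout = ifr@timesMs, rule = 2)$y
  data.frame(timeMs = ifr@timesMs, atp = atpOnGrid, ifrHz = pop)
}
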