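# Independent oracles and small fixtures shared across the test files.

# feasible small geometry at the standard density of 50 / mm^2
tinyNet <- function(n = 200, widthMm = 2, heightMm = 2, seed = 1, ...) {
  buildNetwork(n = n, widthMm = widthMm, heightMm = heightMm, seed = seed, ...)
}

# brute-force windowed spike counting (centered rectangular windows)
bruteForceIFR <- function(raster, n, t0, t1, windowMs, strideMs) {
  centers <- seq(t0 + windowMs / 2, t1 - windowMs / 2, by = strideMs)
  rates <- matrix(0, length(centers), n)
  for (g in seq_along(centers)) {
    lo <- centers[g] - windowMs / 2
    hi <- centers[g] + windowMs / 2
    inWin <- raster$timeMs >= lo & raster$timeMs < hi
    cnt <- tabulate(raster$neuron[inWin], nbins = n)
    rates[g, ] <- cnt * 1000 / windowMs
  }
  list(centers = centers, rates = rates)
}

# naive mean pairwise Pearson over all distinct pairs
naiveMeanPairwiseCor <- function(M) {
  keep <- apply(M, 2, stats::sd) > 0
  C <- stats::cor(M[, keep, drop = FALSE])
  mean(C[upper.tri(C)])
}

# synthetic MeanFieldTrace from a rate series (for the classifier)
syntheticTrace <- function(ifrHz, dt = 10, tauATP = 10000, discardMs = 0) {
  t <- seq(0, by = dt, length.out = length(ifrHz))
  p <- meanFieldParams(tauATP = tauATP, dt = dt)
  new("MeanFieldTrace", timeMs = t, v = numeric(length(t)),
      atp = rep(1, length(t)), ifrHz = ifrHz, spikeTimesMs = numeric(0),
      params = p, discardMs = discardMs)
}

# synthetic SimulationResult carrying hand-made traces (for the sLFP tests)
syntheticResultWithTraces <- function(net, synMatrix, timeMs, strideMs) {
  new("SimulationResult",
      spikes = data.frame(neuron = integer(0), timeMs = numeric(0)),
      nNeurons = nNeurons(net), durationMs = max(timeMs) + strideMs,
      discardMs = 0, params = dynamicsParams(), seed = 0,
      traces = list(timeMs = timeMs, strideMs = strideMs,
                    neurons = seq_len(nNeurons(net)), syn = synMatrix,
                    v = synMatrix * 0, atp = synMatrix * 0 + 1),
      provenance = list())
}
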