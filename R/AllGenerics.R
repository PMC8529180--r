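#' @rdname positions
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname weightMatrix
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname spikeTrain
#' @export
setGeneric("spikeTrain", function(x, ...) standardGeneric("spikeTrain"))

#' @rdname popRate
#' @export
setGeneric("popRate", function(x) standardGeneric("popRate"))

#' @rdname intervals
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname nNeurons
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Neuron coordinates
#'
#' Accessor for the coordinate matrix of a \linkS4class{PositionSet} or the
#' embedded positions of a \linkS4class{SpatialNetwork}.
#'
#' @param x a \linkS4class{PositionSet} or \linkS4class{SpatialNetwork}
#' @return two-column matrix of x/y coordinates in mm
#' @rdname positions
#' @export
setMethod("positions", "PositionSet", function(x) x@coords)

#' @rdname positions
#' @export
setMethod("positions", "SpatialNetwork", function(x) x@positions@coords)

#' Synaptic weight matrix
#'
#' The directed sparse weight matrix \code{C} of a network;
#' \code{C[i, j]} is the strength of the link from neuron \code{j} to
#' neuron \code{i}.
#'
#' @param x a \linkS4class{SpatialNetwork}
#' @return a \code{dgCMatrix}
#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "SpatialNetwork", function(x) x@weights)

#' Spike raster
#'
#' The spike raster of a simulation as a data.frame with columns
#' \code{neuron} and \code{timeMs}, ordered by time. By default the
#' transient (\code{discardMs}) is dropped.
#'
#' @param x a \linkS4class{SimulationResult}
#' @param discard drop spikes before \code{discardMs}? (default TRUE)
#' @param ... unused
#' @return data.frame with columns neuron, timeMs
#' @rdname spikeTrain
#' @export
setMethod("spikeTrain", "SimulationResult", function(x, discard = TRUE, ...) {
  sp <- x@spikes
  if (discard) sp <- sp[sp$timeMs > x@discardMs, , drop = FALSE]
  rownames(sp) <- NULL
  sp
})

#' Population-mean firing rate series
#'
#' Row means of the per-neuron iFR matrix: the population-averaged
#' instantaneous firing rate in Hz on the window-center grid.
#'
#' @param x an \linkS4class{IFRMatrix}
#' @return numeric vector, one value per grid time
#' @rdname popRate
#' @export
setMethod("popRate", "IFRMatrix", function(x) rowMeans(x@rates))

#' ON/OFF intervals
#'
#' The alternating interval table of a segmentation.
#'
#' @param x an \linkS4class{OnOffSegmentation}
#' @return data.frame of intervals
#' @rdname intervals
#' @export
setMethod("intervals", "OnOffSegmentation", function(x) x@intervals)

#' Number of neurons
#'
#' @param x a \linkS4class{PositionSet}, \linkS4class{SpatialNetwork} or
#'   \linkS4class{SimulationResult}
#' @return integer count
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "PositionSet", function(x) nrow(x@coords))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpatialNetwork", function(x) nrow(x@positions@coords))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SimulationResult", function(x) x@nNeurons)

setMethod("show", "PositionSet", function(object) {
  cat(sprintf("PositionSet: %d neurons on a %g x %g mm rectangle\n",
              nrow(object@coords), object@widthMm, object@heightMm))
})

setMethod("show", "SpatialNetwork", function(object) {
  n <- nNeurons(object)
  nl <- length(object@weights@x)
  cat(sprintf("SpatialNetwork: %d neurons, %d directed links (mean in-degree %.2f)\n",
              n, nl, if (n) nl / n else 0))
  pr <- object@provenance
  if (length(pr))
    cat(sprintf("  sigma = %g mm, peak prob = %.3f, total in-strength = %g, beta = %g\n",
                pr$sigmaMm, pr$peakProb, pr$totalIn, pr$beta))
})

setMethod("show", "DynamicsParams", function(object) {
  cat("DynamicsParams:\n")
  cat(sprintf("  I_app0 = %g (SD %g), tau_leak = %g ms, alpha = %g\n",
              object@iApp0, object@sigmaI, object@tauLeak, object@alpha))
  cat(sprintf("  epsilon = %g per spike, ATP_max = %g, tau_ATP = %g ms\n",
              object@epsilon, object@atpMax, object@tauATP))
  cat(sprintf("  lambda_syn = %g ms, dt = %g ms, ATP floor = %g\n",
              object@lambdaSyn, object@dt, object@atpFloor))
})

setMethod("show", "MeanFieldParams", function(object) {
  callNextMethod()
  cat(sprintf("  C_feedback = %g, Hann window = %g ms\n",
              object@cFeedback, object@windowMs))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d neurons, %g s simulated (%g s discarded), %d spikes\n",
              object@nNeurons, object@durationMs / 1000,
              object@discardMs / 1000, nrow(object@spikes)))
  keep <- object@spikes$timeMs > object@discardMs
  secs <- (object@durationMs - object@discardMs) / 1000
  cat(sprintf("  mean rate after discard: %.2f Hz (tau_ATP = %g s, seed %g)\n",
              sum(keep) / object@nNeurons / secs, object@params@tauATP / 1000,
              object@seed))
})

setMethod("show", "MeanFieldTrace", function(object) {
  keep <- object@timeMs > object@discardMs
  cat(sprintf("MeanFieldTrace: %g s at dt = %g ms, tau_ATP = %g s\n",
              max(object@timeMs) / 1000, object@params@dt,
              object@params@tauATP / 1000))
  cat(sprintf("  mean iFR after discard: %.2f Hz (SD %.3f), %d spikes\n",
              mean(object@ifrHz[keep]), stats::sd(object@ifrHz[keep]),
              length(object@spikeTimesMs)))
})

setMethod("show", "IFRMatrix", function(object) {
  cat(sprintf("IFRMatrix: %d neurons x %d grid points (%g ms window, %g ms stride)\n",
              ncol(object@rates), nrow(object@rates), object@windowMs,
              object@strideMs))
})

setMethod("show", "OnOffSegmentation", function(object) {
  iv <- object@intervals
  cat(sprintf("OnOffSegmentation: %d intervals (%d OFF), threshold %g Hz\n",
              nrow(iv), sum(iv$label == "OFF"), object@thresholdHz))
})
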