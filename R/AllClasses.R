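#' @import methods
#' @importFrom Matrix rowSums colSums diag t sparseMatrix
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Neuron positions on a rectangular sheet
#'
#' Coordinates (in mm) of neurons scattered uniformly at random on a
#' rectangle, together with the rectangle extents. The default geometry is a
#' 5 x 20 mm sheet holding 5,000 neurons (density 50 per square mm).
#'
#' @slot coords two-column numeric matrix (\code{x_mm}, \code{y_mm})
#' @slot widthMm,heightMm rectangle extents in mm
#' @export
setClass("PositionSet",
  representation(coords = "matrix", widthMm = "numeric", heightMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@coords) != 2)
      msg <- c(msg, "coords must have two columns (x_mm, y_mm)")
    if (object@widthMm <= 0 || object@heightMm <= 0)
      msg <- c(msg, "rectangle extents must be positive")
    if (nrow(object@coords) > 0) {
      x <- object@coords[, 1]; y <- object@coords[, 2]
      bad <- which(x < 0 | x > object@widthMm | y < 0 | y > object@heightMm)
      if (length(bad))
        msg <- c(msg, sprintf("coordinate outside the rectangle at row %d",
                              bad[1]))
    }
    if (is.null(msg)) TRUE else msg
  })

#' Spatially embedded synaptic network
#'
#' Directed weight matrix \eqn{C} over neurons placed in 2D, with
#' \eqn{C_{ij}} the strength of the link from neuron \eqn{j} to neuron
#' \eqn{i}. After in-strength normalization every neuron with at least one
#' afferent has its incoming strengths summing to a common total (0.4 by
#' default).
#'
#' @slot positions a \linkS4class{PositionSet}
#' @slot weights a \code{dgCMatrix}; \code{weights[i, j]} is the strength of
#'   the link j -> i
#' @slot provenance list of builder settings (sigmaMm, peakProb, totalIn,
#'   beta, seed)
#' @export
setClass("SpatialNetwork",
  representation(positions = "PositionSet", weights = "Matrix",
                 provenance = "list"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@positions@coords)
    if (!all(dim(object@weights) == c(n, n)))
      msg <- c(msg, "weights must be n x n for n positioned neurons")
    if (n > 0) {
      if (any(object@weights@x < 0))
        msg <- c(msg, "negative synaptic weights")
      if (any(Matrix::diag(object@weights) != 0))
        msg <- c(msg, "self-links are not allowed")
      total <- object@provenance$totalIn
      if (!is.null(total)) {
        rs <- Matrix::rowSums(object@weights)
        dev <- abs(rs[rs > 0] - total)
        if (length(dev) && max(dev) > 1e-9)
          msg <- c(msg, "incoming strengths of a non-isolated neuron do not sum to totalIn")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Parameters of the ATP-gated leaky integrate-and-fire model
#'
#' Scalar constants of the membrane/ATP dynamics. Voltage is dimensionless
#' (0 = reset, 1 = threshold), currents are in voltage units per ms, the
#' membrane capacitance is fixed at 1.
#'
#' @slot iApp0 mean applied current (default 0.03)
#' @slot sigmaI SD of the applied current noise, redrawn independently per
#'   neuron and per time step (default 0.006)
#' @slot tauLeak membrane leak time constant, ms (default 38.75)
#' @slot alpha conductance of the ATP-gated potassium current (default 0.002)
#' @slot epsilon ATP consumed per spike (default 0.005)
#' @slot atpMax ATP saturation level (default 1)
#' @slot tauATP ATP production time constant, ms; the proxy for the cerebral
#'   metabolic rate (larger = slower ATP recovery)
#' @slot lambdaSyn EPSP time constant of the alpha-function synapse, ms
#'   (default 2); one spike through a unit-strength link injects a voltage
#'   integral of \code{2 * lambdaSyn / 2 = lambdaSyn}
#' @slot dt integration step, ms (default 0.5)
#' @slot atpFloor lower clamp on ATP, keeps the hyperpolarizing current
#'   finite during deep bursts (default 0.01)
#' @export
setClass("DynamicsParams",
  representation(iApp0 = "numeric", sigmaI = "numeric", tauLeak = "numeric",
                 alpha = "numeric", epsilon = "numeric", atpMax = "numeric",
                 tauATP = "numeric", lambdaSyn = "numeric", dt = "numeric",
                 atpFloor = "numeric"),
  validity = function(object) {
    msg <- NULL
    for (nm in c("tauLeak", "tauATP", "lambdaSyn", "dt"))
      if (slot(object, nm) <= 0)
        msg <- c(msg, sprintf("%s must be strictly positive", nm))
    if (object@sigmaI < 0) msg <- c(msg, "sigmaI must be non-negative")
    if (object@atpFloor <= 0 || object@atpFloor >= object@atpMax)
      msg <- c(msg, "atpFloor must lie in (0, atpMax)")
    if (is.null(msg)) TRUE else msg
  })

#' Parameters of the single-neuron mean-field feedback model
#'
#' Extends \linkS4class{DynamicsParams} with the rate-feedback coupling: the
#' synaptic input is replaced by the neuron's own instantaneous firing rate,
#' measured with a trailing Hann window, times \code{2 * cFeedback}. The
#' noise SD is forced to zero: the mean-field model is deterministic.
#'
#' @slot cFeedback feedback coupling, the stand-in for the summed incoming
#'   synaptic strength (default 0.4)
#' @slot windowMs Hann window length L in ms (default 200)
#' @export
setClass("MeanFieldParams", contains = "DynamicsParams",
  representation(cFeedback = "numeric", windowMs = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@cFeedback < 0) msg <- c(msg, "cFeedback must be non-negative")
    if (object@windowMs <= 0) msg <- c(msg, "windowMs must be positive")
    if (object@sigmaI != 0) msg <- c(msg, "the mean-field model is noiseless (sigmaI must be 0)")
    if (is.null(msg)) TRUE else msg
  })

#' Result of a network simulation
#'
#' Spike raster plus optional state traces of an RK2 integration of the full
#' network. Analysis functions exclude the first \code{discardMs}
#' milliseconds (20 s by default) as transient.
#'
#' @slot spikes data.frame with columns \code{neuron} (1-based id) and
#'   \code{timeMs}, ordered by time
#' @slot nNeurons number of neurons simulated
#' @slot durationMs,discardMs simulated and discarded time, ms
#' @slot params the \linkS4class{DynamicsParams} used
#' @slot seed integrator seed
#' @slot traces either NULL or a list with \code{timeMs} and population and/or
#'   per-neuron \code{v}, \code{atp}, \code{syn} series at the trace stride
#' @slot provenance builder provenance carried over from the network
#' @export
setClass("SimulationResult",
  representation(spikes = "data.frame", nNeurons = "integer",
                 durationMs = "numeric", discardMs = "numeric",
                 params = "DynamicsParams", seed = "numeric",
                 traces = "listOrNULL", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (!all(c("neuron", "timeMs") %in% names(object@spikes)))
      msg <- c(msg, "spikes needs columns neuron, timeMs")
    if (nrow(object@spikes) > 0) {
      if (is.unsorted(object@spikes$timeMs))
        msg <- c(msg, "spike times must be ordered")
      if (min(object@spikes$timeMs) < 0 ||
          max(object@spikes$timeMs) > object@durationMs)
        msg <- c(msg, "spike times outside [0, durationMs]")
    }
    if (object@discardMs >= object@durationMs)
      msg <- c(msg, "durationMs must exceed discardMs")
    if (is.null(msg)) TRUE else msg
  })

#' Trajectory of the mean-field feedback model
#'
#' Deterministic time course of voltage, ATP and the Hann-windowed firing
#' rate of the single-neuron mean-field model, sampled every integration
#' step.
#'
#' @slot timeMs,v,atp,ifrHz aligned numeric vectors
#' @slot spikeTimesMs spike times, ms
#' @slot params the \linkS4class{MeanFieldParams} used
#' @slot discardMs transient cut used by summaries
#' @export
setClass("MeanFieldTrace",
  representation(timeMs = "numeric", v = "numeric", atp = "numeric",
                 ifrHz = "numeric", spikeTimesMs = "numeric",
                 params = "MeanFieldParams", discardMs = "numeric"),
  validity = function(object) {
    n <- length(object@timeMs)
    if (length(object@v) != n || length(object@atp) != n ||
        length(object@ifrHz) != n)
      return("timeMs, v, atp, ifrHz must have equal length")
    if (any(object@ifrHz < 0)) return("negative firing rate")
    TRUE
  })

#' Windowed instantaneous firing rates
#'
#' Per-neuron instantaneous firing rate (iFR): spike count in a centered
#' rectangular window divided by the window length, evaluated on a regular
#' grid. The population mean series is available through \code{popRate}.
#'
#' @slot timesMs grid of window centers, ms
#' @slot rates numeric matrix, one column per neuron, in Hz
#' @slot windowMs,strideMs window length and grid stride, ms
#' @export
setClass("IFRMatrix",
  representation(timesMs = "numeric", rates = "matrix", windowMs = "numeric",
                 strideMs = "numeric"),
  validity = function(object) {
    if (nrow(object@rates) != length(object@timesMs))
      return("rates must have one row per grid time")
    if (any(object@rates < 0)) return("negative rates")
    TRUE
  })

#' Threshold segmentation of population firing into ON and OFF periods
#'
#' Maximal intervals of the population iFR below the threshold are OFF,
#' the rest ON; segments shorter than \code{minSegmentMs} are merged into
#' their neighbours so that labels strictly alternate and the intervals tile
#' the analyzed epoch.
#'
#' @slot intervals data.frame with columns \code{label} ("ON"/"OFF"),
#'   \code{startMs}, \code{endMs}, \code{durationMs}, \code{peakHz} (NA for
#'   OFF intervals)
#' @slot thresholdHz,minSegmentMs segmentation settings
#' @export
setClass("OnOffSegmentation",
  representation(intervals = "data.frame", thresholdHz = "numeric",
                 minSegmentMs = "numeric"),
  validity = function(object) {
    iv <- object@intervals
    if (!all(c("label", "startMs", "endMs", "durationMs", "peakHz") %in%
             names(iv)))
      return("intervals is missing required columns")
    if (nrow(iv) > 1) {
      if (any(iv$label[-1] == iv$label[-nrow(iv)]))
        return("interval labels must alternate")
      if (any(abs(iv$startMs[-1] - iv$endMs[-nrow(iv)]) > 1e-9))
        return("intervals must tile the epoch without gaps")
    }
    TRUE
  })
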