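# Single-neuron mean-field feedback model: the synaptic input is replaced by
# the neuron's own Hann-windowed firing rate, removing all network structure.

#' Construct mean-field parameters
#'
#' Same cell constants as \code{\link{dynamicsParams}} with the noise
#' removed (the mean-field model is deterministic) plus the feedback
#' coupling \code{cFeedback} and the Hann window length.
#'
#' @inheritParams dynamicsParams
#' @param cFeedback feedback coupling replacing the summed synaptic
#'   strength (default 0.4)
#' @param windowMs Hann window length L, ms (default 200)
#' @return a \linkS4class{MeanFieldParams}
#' @examples
#' meanFieldParams(tauATP = 4000)
#' @export
meanFieldParams <- function(iApp0 = 0.03, tauLeak = 38.75, alpha = 0.002,
                            epsilon = 0.005, atpMax = 1, tauATP = 10000,
                            lambdaSyn = 2, dt = 0.5, atpFloor = 0.01,
                            cFeedback = 0.4, windowMs = 200) {
  new("MeanFieldParams", iApp0 = iApp0, sigmaI = 0, tauLeak = tauLeak,
      alpha = alpha, epsilon = epsilon, atpMax = atpMax, tauATP = tauATP,
      lambdaSyn = lambdaSyn, dt = dt, atpFloor = atpFloor,
      cFeedback = cFeedback, windowMs = windowMs)
}

#' Hann-windowed instantaneous firing rate
#'
#' Causal rate estimate: spikes inside the trailing window \eqn{(t-L, t]}
#' are weighted by the Hann window
#' \eqn{w_0(u) = \tfrac12 (1 - \cos(2\pi u / L))}, \eqn{u = t' - t + L},
#' and the weighted sum is divided by the full-window integral \eqn{L/2}.
#' A solitary spike at the window centre therefore reads \eqn{2/L} spikes
#' per ms (10 Hz at L = 200 ms); the newest and oldest spikes in the window
#' carry weight near zero.
#'
#' @param spikeTimes spike times, ms
#' @param t evaluation times, ms (vectorized)
#' @param windowMs window length L, ms
#' @return rate in spikes/ms at each \code{t}
#' @examples
#' hannFeedbackRate(100, t = 200, windowMs = 200) * 1000  # 10 Hz
#' @export
hannFeedbackRate <- function(spikeTimes, t, windowMs = 200) {
  if (windowMs <= 0) stop("windowMs must be positive")
  vapply(t, function(tt) {
    u <- spikeTimes - tt + windowMs
    u <- u[u > 0 & u <= windowMs]
    sum(0.5 * (1 - cos(2 * pi * u / windowMs))) / (windowMs / 2)
  }, numeric(1))
}

#' Simulate the mean-field feedback model
#'
#' Deterministic RK2 integration of
#' \deqn{dv/dt = I_{app0} + I_{leak} + I_{ATP} + 2\,C_{feedback}\,iFR_{MF}(t)}
#' with the same threshold/reset/ATP-consumption rules as the network. The
#' factor 2 is the voltage integral a unit-strength alpha synapse delivers
#' per spike, making the feedback term commensurate with the network's
#' synaptic drive (incoming strength 0.4 times integral 2 per spike). The
#' rate \eqn{iFR_{MF}} is recomputed every step from the trailing Hann
#' window.
#'
#' After each spike the voltage is held at reset for one integration step;
#' the methods vignette motivates this convention.
#'
#' @param params a \linkS4class{MeanFieldParams}
#' @param durationMs simulated time, ms
#' @param discardMs transient cut used by summaries, ms
#' @return a \linkS4class{MeanFieldTrace}
#' @examples
#' tr <- simulateMeanField(meanFieldParams(tauATP = 4000), durationMs = 30000)
#' tr
#' @export
simulateMeanField <- function(params = meanFieldParams(),
                              durationMs = 120000, discardMs = 20000) {
  stopifnot(is(params, "MeanFieldParams"))
  if (durationMs <= discardMs) stop("durationMs must exceed discardMs")
  raw <- cpp_simulate_meanfield(paramsAsList(params), params@cFeedback,
                                params@windowMs, durationMs)
  new("MeanFieldTrace", timeMs = raw$timeMs, v = raw$v, atp = raw$atp,
      ifrHz = raw$ifrPerMs * 1000, spikeTimesMs = raw$spikeTimesMs,
      params = params, discardMs = discardMs)
}

#' Signed spike-generation margin at threshold
#'
#' Net current at \eqn{v = 1}:
#' \deqn{I_{app0} - 1/\tau_{leak} - \alpha\,ATP_{max}/ATP +
#'       2\,C_{feedback}\,iFR.}
#' A negative margin means a neuron arriving at threshold cannot cross it -
#' spike generation fails and an OFF period begins. At zero rate the margin
#' vanishes at \eqn{ATP^* = \alpha / (I_{app0} - 1/\tau_{leak})} (about
#' 0.477 at the defaults): below that ATP level a silent neuron stays
#' silent until ATP recovers.
#'
#' @param atp ATP concentration (vectorized)
#' @param ifr firing rate in spikes/ms (vectorized)
#' @param params a \linkS4class{MeanFieldParams}
#' @return signed current margin
#' @examples
#' failureMargin(1, 0)       # positive: rest firing possible
#' failureMargin(0.3, 0)     # negative: silence persists
#' @export
failureMargin <- function(atp, ifr, params = meanFieldParams()) {
  if (any(atp <= 0)) stop("atp must be positive")
  params@iApp0 - 1 / params@tauLeak - params@alpha * params@atpMax / atp +
    2 * params@cFeedback * ifr
}

#' Classify a mean-field trace as continuous or ON/OFF
#'
#' A trace is \code{"on_off"} when, after the discard, it contains at least
#' two maximal intervals of length \code{minOffMs} or more with the rate
#' below \code{offThresholdHz}; otherwise \code{"continuous"}.
#'
#' @param trace a \linkS4class{MeanFieldTrace}
#' @param offThresholdHz OFF threshold (default 1 Hz)
#' @param minOffMs minimal OFF interval length (default 200 ms)
#' @return \code{"continuous"} or \code{"on_off"}
#' @export
classifyRegime <- function(trace, offThresholdHz = 1, minOffMs = 200) {
  stopifnot(is(trace, "MeanFieldTrace"))
  keep <- trace@timeMs > trace@discardMs
  if (sum(keep) * trace@params@dt < 20000)
    stop("trace must cover at least 20 s beyond the discard")
  below <- trace@ifrHz[keep] < offThresholdHz
  r <- rle(below)
  nOff <- sum(r$values & r$lengths * trace@params@dt >= minOffMs)
  if (nOff >= 2) "on_off" else "continuous"
}

#' Sweep the mean-field model across ATP production time constants
#'
#' Runs \code{\link{simulateMeanField}} for each \code{tauATP} and tabulates
#' the post-discard mean rate, its SD across time, and the regime label.
#'
#' @param tauATPMs vector of ATP time constants, ms
#' @param durationMs,discardMs simulation protocol
#' @param ... further arguments to \code{\link{meanFieldParams}}
#' @return data.frame with columns tauATPMs, meanRateHz, sdRateHz, regime
#' @examples
#' \donttest{
#' mfSweep(c(4000, 6700, 6800), durationMs = 60000)
#' }
#' @export
mfSweep <- function(tauATPMs, durationMs = 120000, discardMs = 20000, ...) {
  rows <- lapply(tauATPMs, function(tau) {
    tr <- simulateMeanField(meanFieldParams(tauATP = tau, ...),
                            durationMs = durationMs, discardMs = discardMs)
    keep <- tr@timeMs > discardMs
    data.frame(tauATPMs = tau,
               meanRateHz = mean(tr@ifrHz[keep]),
               sdRateHz = stats::sd(tr@ifrHz[keep]),
               regime = classifyRegime(tr))
  })
  do.call(rbind, rows)
}
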