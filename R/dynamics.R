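# Full-network dynamics: the ATP-gated leaky integrate-and-fire model
# integrated with a fixed-step second-order Runge-Kutta (Heun) scheme.

#' Construct dynamics parameters
#'
#' All defaults are the standard model constants; \code{tauATP} is the
#' experimental dial (4,000-10,000 ms spans the continuum from continuous
#' firing to burst suppression).
#'
#' @param iApp0 mean applied current (voltage units/ms)
#' @param sigmaI applied-current noise SD
#' @param tauLeak leak time constant, ms
#' @param alpha ATP-gated potassium conductance
#' @param epsilon ATP consumed per spike
#' @param atpMax ATP saturation level
#' @param tauATP ATP production time constant, ms
#' @param lambdaSyn EPSP time constant, ms
#' @param dt integration step, ms
#' @param atpFloor lower clamp on ATP
#' @return a \linkS4class{DynamicsParams}
#' @examples
#' dynamicsParams(tauATP = 4000)
#' @export
dynamicsParams <- function(iApp0 = 0.03, sigmaI = 0.006, tauLeak = 38.75,
                           alpha = 0.002, epsilon = 0.005, atpMax = 1,
                           tauATP = 10000, lambdaSyn = 2, dt = 0.5,
                           atpFloor = 0.01) {
  new("DynamicsParams", iApp0 = iApp0, sigmaI = sigmaI, tauLeak = tauLeak,
      alpha = alpha, epsilon = epsilon, atpMax = atpMax, tauATP = tauATP,
      lambdaSyn = lambdaSyn, dt = dt, atpFloor = atpFloor)
}

paramsAsList <- function(p) {
  list(iApp0 = p@iApp0, sigmaI = p@sigmaI, tauLeak = p@tauLeak,
       alpha = p@alpha, epsilon = p@epsilon, atpMax = p@atpMax,
       tauATP = p@tauATP, lambdaSyn = p@lambdaSyn, dt = p@dt,
       atpFloor = p@atpFloor)
}

#' ATP-dependent hyperpolarizing current
#'
#' The stand-in for the ATP-gated potassium channel:
#' \eqn{I_{ATP} = -\alpha\, v\, ATP_{max} / ATP}. The current is
#' proportional to the voltage and strengthens as intracellular ATP falls,
#' so sustained firing under slow ATP production self-limits. ATP values
#' below the configured floor are clamped with a warning.
#'
#' @param v membrane voltage (vectorized)
#' @param atp ATP concentration (vectorized)
#' @param params a \linkS4class{DynamicsParams}
#' @return current, always <= 0 for v >= 0
#' @examples
#' atpCurrent(1, 1, dynamicsParams())   # -alpha
#' atpCurrent(1, 0.5, dynamicsParams()) # twice as strong
#' @export
atpCurrent <- function(v, atp, params = dynamicsParams()) {
  if (any(atp < params@atpFloor)) {
    warning(sprintf("ATP below floor %g clamped", params@atpFloor))
    atp <- pmax(atp, params@atpFloor)
  }
  -params@alpha * v * params@atpMax / atp
}

#' One Heun step of the synaptic cascade
#'
#' The alpha-function EPSC is realized as a two-stage linear cascade
#' \eqn{a' = -a/\lambda}, \eqn{s' = (a - s)/\lambda} whose unit-impulse
#' response is \eqn{s(t) = (t/\lambda) e^{-t/\lambda}}: it peaks at
#' \eqn{t = \lambda} with value \eqn{e^{-1}} and carries time integral
#' \eqn{\lambda}. Impulses (spike weights landing this step) are added to
#' \code{a} before the step.
#'
#' @param a,s cascade state vectors
#' @param impulses summed incoming spike weights to add to \code{a}
#' @param dt step, ms
#' @param lambdaSyn synaptic time constant, ms
#' @return list with updated \code{a} and \code{s}
#' @examples
#' st <- synapticDriveUpdate(0, 0, impulses = 1, dt = 0.5, lambdaSyn = 2)
#' @export
synapticDriveUpdate <- function(a, s, impulses = 0, dt = 0.5, lambdaSyn = 2) {
  if (dt <= 0) stop("dt must be positive")
  a <- a + impulses
  da1 <- -a / lambdaSyn
  ds1 <- (a - s) / lambdaSyn
  aP <- a + dt * da1
  sP <- s + dt * ds1
  da2 <- -aP / lambdaSyn
  ds2 <- (aP - sP) / lambdaSyn
  list(a = a + dt / 2 * (da1 + da2), s = s + dt / 2 * (ds1 + ds2))
}

#' One RK2 step of the coupled network state (reference implementation)
#'
#' Plain-R mirror of one step of the compiled integrator, operating on a
#' state list. Useful for stepwise inspection and as the comparison point in
#' tests; \code{\link{simulateNetwork}} runs the same scheme compiled.
#'
#' Semantics: impulses queued by spikes of the previous step are delivered
#' to the cascade first; the noise draw is frozen across both stages;
#' neurons at or above threshold after the step are reset to 0, lose
#' \code{epsilon} ATP, and their outgoing weights are queued for the next
#' step. No refractory period.
#'
#' @param state list with numeric vectors \code{v}, \code{atp}, \code{a},
#'   \code{s}, \code{pending} and scalar \code{timeMs}
#' @param params a \linkS4class{DynamicsParams}
#' @param weights sparse weight matrix C (targets in rows)
#' @param noise per-neuron applied current for this step (mean + noise)
#' @return list with the updated state and \code{spiked}, the integer ids
#'   of neurons that fired
#' @export
rk2Step <- function(state, params, weights, noise) {
  dt <- params@dt
  a <- state$a + state$pending
  pending <- numeric(length(a))
  casc <- synapticDriveUpdate(a, state$s, 0, dt, params@lambdaSyn)

  f <- function(v, atp, s)
    noise - v / params@tauLeak - params@alpha * v * params@atpMax / atp + s
  g <- function(atp) (params@atpMax - atp) / params@tauATP

  dv1 <- f(state$v, state$atp, state$s)
  dp1 <- g(state$atp)
  vP <- state$v + dt * dv1
  pP <- state$atp + dt * dp1
  sP <- state$s + dt * ((a - state$s) / params@lambdaSyn)  # predictor of s
  dv2 <- f(vP, pP, sP)
  dp2 <- g(pP)
  v <- state$v + dt / 2 * (dv1 + dv2)
  atp <- state$atp + dt / 2 * (dp1 + dp2)

  spiked <- which(v >= 1)
  if (length(spiked)) {
    v[spiked] <- 0
    atp[spiked] <- atp[spiked] - params@epsilon
    pending <- as.numeric(weights[, spiked, drop = FALSE] %*%
                            rep(1, length(spiked)))
  }
  atp <- pmin(pmax(atp, params@atpFloor), params@atpMax)
  if (any(!is.finite(v)) || any(!is.finite(atp)))
    stop(sprintf("non-finite state for neuron %d at t = %g ms",
                 which(!is.finite(v) | !is.finite(atp))[1],
                 state$timeMs + dt))
  list(v = v, atp = atp, a = casc$a, s = casc$s, pending = pending,
       timeMs = state$timeMs + dt, spiked = spiked)
}

#' Simulate the full spatial network
#'
#' Integrates the coupled voltage/ATP/synaptic dynamics of all neurons with
#' the fixed-step Heun scheme at \code{params@dt} (0.5 ms default),
#' i.i.d. Gaussian applied current per neuron per step, threshold/reset
#' spiking with per-spike ATP consumption, and one-step synaptic delivery.
#' Deterministic for a fixed seed.
#'
#' State traces can be recorded at a stride: population means are cheap and
#' on by default whenever \code{traceStrideMs > 0}; per-neuron traces of
#' selected neurons (or all, for the simulated LFP) are optional.
#'
#' @param network a \linkS4class{SpatialNetwork}
#' @param params a \linkS4class{DynamicsParams}
#' @param durationMs simulated time, ms (default 120000)
#' @param seed integrator seed
#' @param discardMs transient dropped by analyses, ms (default 20000)
#' @param traceStrideMs 0 for no traces, else recording stride in ms
#' @param traceNeurons integer ids whose v/ATP/EPSC are recorded, or
#'   \code{"all"}
#' @param recordPopulation record population-mean v/ATP/EPSC series?
#' @return a \linkS4class{SimulationResult}
#' @examples
#' net <- buildNetwork(n = 50, widthMm = 1, heightMm = 1, seed = 1)
#' res <- simulateNetwork(net, dynamicsParams(tauATP = 4000),
#'                        durationMs = 3000, discardMs = 1000, seed = 1)
#' nrow(spikeTrain(res))
#' @export
simulateNetwork <- function(network, params = dynamicsParams(),
                            durationMs = 120000, seed = 1,
                            discardMs = 20000, traceStrideMs = 0,
                            traceNeurons = integer(0),
                            recordPopulation = TRUE) {
  stopifnot(is(network, "SpatialNetwork"), is(params, "DynamicsParams"))
  if (durationMs <= discardMs) stop("durationMs must exceed discardMs")
  W <- as(network@weights, "CsparseMatrix")
  n <- nrow(W)
  if (identical(traceNeurons, "all")) traceNeurons <- seq_len(n)
  traceEvery <- if (traceStrideMs > 0) {
    ev <- round(traceStrideMs / params@dt)
    if (abs(ev * params@dt - traceStrideMs) > 1e-9)
      stop("traceStrideMs must be a multiple of dt")
    as.integer(ev)
  } else 0L
  raw <- cpp_simulate_network(W@p, W@i, W@x, n, paramsAsList(params),
                              durationMs, seed, traceEvery,
                              as.integer(traceNeurons),
                              recordPopulation && traceEvery > 0)
  traces <- if (traceEvery > 0) {
    tr <- list(timeMs = raw$traceTimeMs, strideMs = traceStrideMs)
    if (recordPopulation) {
      tr$popV <- raw$popV; tr$popAtp <- raw$popAtp; tr$popSyn <- raw$popSyn
    }
    if (length(traceNeurons)) {
      tr$neurons <- as.integer(traceNeurons)
      tr$v <- raw$traceV; tr$atp <- raw$traceAtp; tr$syn <- raw$traceSyn
    }
    tr
  } else NULL
  new("SimulationResult",
      spikes = data.frame(neuron = raw$spikeNeuron, timeMs = raw$spikeTimeMs),
      nNeurons = as.integer(n), durationMs = durationMs,
      discardMs = discardMs, params = params, seed = seed, traces = traces,
      provenance = network@provenance)
}
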