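test_that("ATP current has the inverse-ATP form and clamps at the floor", {
  p <- dynamicsParams()
  expect_equal(atpCurrent(1, 1, p), -0.002)
  expect_equal(atpCurrent(0, 0.3, p), 0)
  expect_equal(atpCurrent(1, 0.5, p), -0.004)
  expect_warning(out <- atpCurrent(1, 0.001, p), "clamped")
  expect_equal(out, -0.002 / p@atpFloor)
})

test_that("the synaptic cascade realizes the alpha kernel", {
  # unit impulse at fine dt: peak exp(-1) at t = lambda, integral = lambda
  dt <- 0.01
  st <- list(a = 0, s = 0)
  s <- numeric(2000)
  st <- synapticDriveUpdate(st$a, st$s, impulses = 1, dt = dt, lambdaSyn = 2)
  s[1] <- st$s
  for (k in 2:2000) {
    st <- synapticDriveUpdate(st$a, st$s, 0, dt = dt, lambdaSyn = 2)
    s[k] <- st$s
  }
  expect_equal(max(s), exp(-1), tolerance = 1e-3)
  expect_equal(which.max(s) * dt, 2, tolerance = 0.02)
  expect_equal(sum(s) * dt, 2, tolerance = 1e-3)

  # zero input stays zero
  z <- synapticDriveUpdate(0, 0, 0, 0.5, 2)
  expect_identical(c(z$a, z$s), c(0, 0))
})

test_that("compiled and reference RK2 steps agree on a deterministic net", {
  net <- tinyNet(n = 30, widthMm = 1, heightMm = 1, seed = 2, peakProb = 0.6)
  p <- dynamicsParams(sigmaI = 0, tauATP = 4000, iApp0 = 0.035)
  res <- simulateNetwork(net, p, durationMs = 200, discardMs = 100, seed = 5,
                         traceStrideMs = 0.5, traceNeurons = "all")
  tr <- res@traces
  state <- list(v = tr$v[1, ], atp = tr$atp[1, ], a = numeric(30),
                s = tr$syn[1, ], pending = numeric(30), timeMs = 0)
  W <- weightMatrix(net)
  spikes <- data.frame(neuron = integer(0), timeMs = numeric(0))
  for (k in 1:400) {
    out <- rk2Step(state, p, W, noise = rep(p@iApp0, 30))
    if (length(out$spiked))
      spikes <- rbind(spikes, data.frame(neuron = out$spiked,
                                         timeMs = out$timeMs))
    state <- out
    expect_equal(state$v, unname(tr$v[k + 1, ]), tolerance = 1e-12)
    expect_equal(state$atp, unname(tr$atp[k + 1, ]), tolerance = 1e-12)
  }
  expect_equal(spikes$neuron, spikeTrain(res, discard = FALSE)$neuron)
  expect_equal(spikes$timeMs, spikeTrain(res, discard = FALSE)$timeMs)
})

test_that("subthreshold voltage decays at the closed-form effective rate", {
  # leak + ATP conductance at full ATP give 1/tau_eff = 1/tau_leak + alpha
  net <- buildNetwork(n = 1, widthMm = 1, heightMm = 1, seed = 1,
                      peakProb = 0)
  p <- dynamicsParams(iApp0 = 0, sigmaI = 0, tauATP = 4000)
  res <- simulateNetwork(net, p, durationMs = 200, discardMs = 100, seed = 3,
                         traceStrideMs = 10, traceNeurons = 1L)
  v <- res@traces$v[, 1]
  t <- res@traces$timeMs
  rate <- 1 / p@tauLeak + p@alpha
  expect_equal(v, v[1] * exp(-t * rate), tolerance = 1e-4)
})

test_that("spikes reset the voltage, burn ATP, and ATP recovers with tauATP", {
  net <- buildNetwork(n = 1, widthMm = 1, heightMm = 1, seed = 1,
                      peakProb = 0)
  p <- dynamicsParams(iApp0 = 0.05, sigmaI = 0, tauATP = 3000)
  res <- simulateNetwork(net, p, durationMs = 4000, discardMs = 1000,
                         seed = 2, traceStrideMs = 0.5, traceNeurons = 1L)
  sp <- spikeTrain(res, discard = FALSE)
  expect_gt(nrow(sp), 5)
  tr <- res@traces
  k <- match(round(sp$timeMs[1], 6), round(tr$timeMs, 6))
  expect_equal(tr$v[k, 1], 0)                     # reset to 0
  drop <- tr$atp[k - 1, 1] - tr$atp[k, 1]
  expect_equal(drop, p@epsilon, tolerance = 1e-2)  # epsilon per spike

  # between two spikes ATP relaxes toward atpMax with time constant tauATP
  gaps <- diff(sp$timeMs)
  g <- which.max(gaps)
  k1 <- match(round(sp$timeMs[g], 6), round(tr$timeMs, 6)) + 1
  k2 <- match(round(sp$timeMs[g + 1], 6), round(tr$timeMs, 6)) - 1
  seg <- tr$atp[k1:k2, 1]
  tt <- tr$timeMs[k1:k2] - tr$timeMs[k1]
  pred <- 1 - (1 - seg[1]) * exp(-tt / p@tauATP)
  expect_equal(seg, pred, tolerance = 1e-6)
})

test_that("an uncoupled noiseless neuron fires at the closed-form period", {
  # with epsilon = 0 the ATP stays at 1 and the cell is a plain LIF with
  # 1/tau_eff = 1/tau_leak + alpha; T = tau_eff log(I tau_eff/(I tau_eff - 1))
  net <- buildNetwork(n = 1, widthMm = 1, heightMm = 1, seed = 1,
                      peakProb = 0)
  p <- dynamicsParams(sigmaI = 0, epsilon = 0, tauATP = 4000)
  res <- simulateNetwork(net, p, durationMs = 20000, discardMs = 1000,
                         seed = 4)
  isi <- diff(spikeTrain(res)$timeMs)
  tauEff <- 1 / (1 / p@tauLeak + p@alpha)
  Ttheory <- tauEff * log(p@iApp0 * tauEff / (p@iApp0 * tauEff - 1))
  expect_lt(stats::sd(isi), 1e-9)                      # strictly periodic
  expect_lt(abs(mean(isi) - Ttheory) / Ttheory, 0.005) # within 0.5%
})

test_that("zero drive produces zero spikes", {
  net <- tinyNet(n = 30, widthMm = 1, heightMm = 1, seed = 1, peakProb = 0.6)
  p <- dynamicsParams(iApp0 = 0, sigmaI = 0)
  res <- simulateNetwork(net, p, durationMs = 3000, discardMs = 1000)
  expect_equal(nrow(spikeTrain(res, discard = FALSE)), 0L)
})

test_that("simulation is seed-deterministic and respects ATP bounds", {
  net <- tinyNet(n = 60, widthMm = 1.2, heightMm = 1, seed = 6)
  p <- dynamicsParams(tauATP = 5000)
  a <- simulateNetwork(net, p, durationMs = 3000, discardMs = 500, seed = 42,
                       traceStrideMs = 10, traceNeurons = "all")
  b <- simulateNetwork(net, p, durationMs = 3000, discardMs = 500, seed = 42)
  d <- simulateNetwork(net, p, durationMs = 3000, discardMs = 500, seed = 43)
  expect_identical(spikeTrain(a, FALSE), spikeTrain(b, FALSE))
  expect_false(identical(spikeTrain(a, FALSE), spikeTrain(d, FALSE)))
  expect_true(all(a@traces$atp >= p@atpFloor - 1e-12))
  expect_true(all(a@traces$atp <= p@atpMax + 1e-12))
})

test_that("halving dt leaves the mean rate nearly unchanged (RK2 order)", {
  net <- tinyNet(n = 100, widthMm = 2, heightMm = 1, seed = 8)
  r1 <- simulateNetwork(net, dynamicsParams(tauATP = 4000, dt = 0.5),
                        durationMs = 12000, discardMs = 2000, seed = 1)
  r2 <- simulateNetwork(net, dynamicsParams(tauATP = 4000, dt = 0.25),
                        durationMs = 12000, discardMs = 2000, seed = 1)
  f1 <- nrow(spikeTrain(r1)) / 100 / 10
  f2 <- nrow(spikeTrain(r2)) / 100 / 10
  expect_lt(abs(f1 - f2) / f2, 0.01)
})
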