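test_that("windowed rates equal brute-force window counting", {
  # empty raster
  empty <- data.frame(neuron = integer(0), timeMs = numeric(0))
  ifr0 <- computeIFR(empty, n = 3, t0 = 0, t1 = 1000)
  expect_true(all(ifr0@rates == 0))
  expect_error(computeIFR(empty, n = 3), "epoch")

  # a single spike contributes 1/window to every covering window
  one <- data.frame(neuron = 2L, timeMs = 500)
  ifr1 <- computeIFR(one, n = 3, t0 = 0, t1 = 1000, windowMs = 50,
                     strideMs = 10)
  expect_setequal(unique(as.numeric(ifr1@rates)), c(0, 20))
  expect_equal(sum(ifr1@rates[, 2] == 20), 5)  # window/stride grid points

  # random raster vs brute force
  set.seed(4)
  r <- data.frame(neuron = sample.int(8, 400, TRUE),
                  timeMs = round(stats::runif(400, 0, 2000), 1))
  r <- r[order(r$timeMs), ]
  ifr <- computeIFR(r, n = 8, t0 = 0, t1 = 2000, windowMs = 50, strideMs = 10)
  bf <- bruteForceIFR(r, 8, 0, 2000, 50, 10)
  expect_equal(ifr@timesMs, bf$centers)
  expect_equal(unname(ifr@rates), bf$rates)
  expect_equal(popRate(ifr), rowMeans(bf$rates))
})

test_that("pairwise correlations match naive Pearson computation", {
  set.seed(7)
  M <- matrix(stats::rnorm(50 * 12), 50, 12)
  ifr <- new("IFRMatrix", timesMs = seq_len(50) * 10, rates = abs(M),
             windowMs = 50, strideMs = 10)
  expect_equal(meanPairwiseCorrelation(ifr),
               naiveMeanPairwiseCor(abs(M)), tolerance = 1e-10)

  # identical series -> 1; independent noise -> near 0
  same <- matrix(rep(abs(stats::rnorm(60)), 5), 60, 5)
  ifrSame <- new("IFRMatrix", timesMs = seq_len(60), rates = same,
                 windowMs = 50, strideMs = 10)
  expect_equal(meanPairwiseCorrelation(ifrSame), 1, tolerance = 1e-12)

  indep <- matrix(abs(stats::rnorm(400 * 20)), 400, 20)
  ifrInd <- new("IFRMatrix", timesMs = seq_len(400), rates = indep,
                windowMs = 50, strideMs = 10)
  expect_lt(abs(meanPairwiseCorrelation(ifrInd)),
            3 / sqrt(400) )  # 3 SE of a single pair, conservative for a mean

  flat <- matrix(1, 10, 3)
  ifrFlat <- new("IFRMatrix", timesMs = 1:10, rates = flat,
                 windowMs = 50, strideMs = 10)
  expect_error(meanPairwiseCorrelation(ifrFlat), "non-constant")
})

test_that("distance-binned correlation agrees with exhaustive enumeration", {
  net <- tinyNet(n = 120, widthMm = 1.6, heightMm = 1.5, seed = 9)
  set.seed(1)
  shared <- abs(stats::rnorm(80))
  rates <- sapply(seq_len(120), function(i) shared + abs(stats::rnorm(80)))
  ifr <- new("IFRMatrix", timesMs = seq_len(80) * 10, rates = rates,
             windowMs = 50, strideMs = 10)
  dc <- distanceBinnedCorrelation(ifr, net@positions, binUm = 200,
                                  maxPairsPerBin = 1e9, seed = 1)
  # exhaustive oracle
  co <- positions(net)
  C <- stats::cor(rates)
  pr <- t(utils::combn(120, 2))
  d <- sqrt((co[pr[, 1], 1] - co[pr[, 2], 1])^2 +
            (co[pr[, 1], 2] - co[pr[, 2], 2])^2) * 1000
  for (b in which(dc$nPairs > 0)) {
    sel <- d > dc$binCenterUm[b] - 100 & d <= dc$binCenterUm[b] + 100
    expect_equal(dc$meanR[b], mean(C[pr[sel, , drop = FALSE]]),
                 tolerance = 1e-10)
    expect_equal(dc$nPairs[b], sum(sel))
  }

  # identical series give r = 1 in every occupied bin
  same <- matrix(rep(shared, 120), 80, 120)
  ifrS <- new("IFRMatrix", timesMs = seq_len(80) * 10, rates = same,
              windowMs = 50, strideMs = 10)
  dcS <- distanceBinnedCorrelation(ifrS, net@positions, maxPairsPerBin = 1e9)
  expect_true(all(abs(dcS$meanR[dcS$nPairs > 0] - 1) < 1e-12))
})

test_that("threshold segmentation tiles the epoch and recovers square waves", {
  t <- seq(5, by = 10, length.out = 600)
  # constant rate -> one ON segment
  segOn <- detectOnOff(rep(5, 600), timesMs = t, strideMs = 10)
  expect_equal(intervals(segOn)$label, "ON")
  # silence -> one OFF segment
  segOff <- detectOnOff(rep(0, 600), timesMs = t, strideMs = 10)
  expect_equal(intervals(segOff)$label, "OFF")

  # 1-s square wave recovered exactly on the grid
  pop <- rep(rep(c(0, 30), each = 100), 3)
  seg <- detectOnOff(pop, timesMs = t, strideMs = 10)
  iv <- intervals(seg)
  expect_equal(iv$label, rep(c("OFF", "ON"), 3))
  expect_equal(iv$startMs, seq(0, 5000, by = 1000))
  expect_equal(iv$durationMs, rep(1000, 6))
  expect_equal(iv$peakHz[iv$label == "ON"], rep(30, 3))
  # tiling is exact
  expect_equal(sum(iv$durationMs), 6000)
  expect_equal(iv$startMs[-1], iv$endMs[-nrow(iv)])

  # sub-minimum blips are merged away
  blip <- rep(5, 600); blip[300] <- 0
  segB <- detectOnOff(blip, timesMs = t, strideMs = 10, minSegmentMs = 50)
  expect_equal(nrow(intervals(segB)), 1L)
})

test_that("OFF-duration/ON-peak statistics behave on constructed cycles", {
  mkSeg <- function(offDur, peaks) {
    labs <- rep(c("OFF", "ON"), length(offDur))
    dur <- as.numeric(rbind(offDur, rep(500, length(offDur))))
    start <- cumsum(c(0, utils::head(dur, -1)))
    iv <- data.frame(label = labs, startMs = start, endMs = start + dur,
                     durationMs = dur,
                     peakHz = as.numeric(rbind(NA, peaks)))
    new("OnOffSegmentation", intervals = iv, thresholdHz = 1,
        minSegmentMs = 50)
  }
  offs <- c(300, 900, 500, 1400, 700, 1100, 800)
  # peak exactly proportional to the preceding OFF duration -> r = 1
  seg1 <- mkSeg(offs, offs * 0.05)
  st <- offOnPeakStatistics(seg1)
  expect_equal(st$rOffPreOnPost, 1, tolerance = 1e-12)
  # interior pairing only: first and last intervals are censored
  expect_equal(st$nOffOn, 5)

  # permuted peaks decorrelate
  set.seed(2)
  rs <- replicate(200, {
    offs2 <- stats::runif(12, 200, 1500)
    offOnPeakStatistics(mkSeg(offs2, sample(offs2) * 0.05))$rOffPreOnPost
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(200 * 8))

  expect_error(offOnPeakStatistics(mkSeg(c(400, 700), c(10, 20))),
               "too few")
})

test_that("the LFP shape function is flat then inverse-square", {
  expect_equal(shapeFunction(c(0, 50, 100)), c(1, 1, 1))
  expect_equal(shapeFunction(200), 0.25)
  expect_equal(shapeFunction(1000), 0.01)
  expect_equal(shapeFunction(100 + 1e-9), 1, tolerance = 1e-6)
  expect_error(shapeFunction(-1), "non-negative")
})

test_that("simulated LFP weights, sums and sign-flips synaptic currents", {
  co <- cbind(x_mm = c(0.6, 0.7), y_mm = c(0.5, 0.5))
  ps <- new("PositionSet", coords = co, widthMm = 1, heightMm = 1)
  W <- Matrix::sparseMatrix(i = 2L, j = 1L, x = 0.4, dims = c(2, 2),
                            repr = "C")
  net <- new("SpatialNetwork", positions = ps, weights = W,
             provenance = list(sigmaMm = 0.25, peakProb = 1, totalIn = 0.4,
                               beta = 0, seed = 1))
  tMs <- seq(0, 90, by = 10)
  epsc <- matrix(rep(c(0, 1, 2, 1, 0, 0, 0, 0, 0, 0), 2), ncol = 2)
  res <- syntheticResultWithTraces(net, epsc, tMs, 10)
  # electrode at the sheet centre: distances 100 um and 200 um
  lfp <- simulateLFP(res, net, electrodeXy = c(0.5, 0.5))
  expect_equal(lfp$slfp, -(epsc[, 1] * 1 + epsc[, 2] * 0.25))
  expect_true(all(lfp$slfp <= 0))

  # linearity: doubling the currents doubles the trace
  res2 <- syntheticResultWithTraces(net, 2 * epsc, tMs, 10)
  expect_equal(simulateLFP(res2, net, c(0.5, 0.5))$slfp, 2 * lfp$slfp)

  # silent network -> identically zero
  res0 <- syntheticResultWithTraces(net, 0 * epsc, tMs, 10)
  expect_true(all(simulateLFP(res0, net, c(0.5, 0.5))$slfp == 0))

  # missing traces are reported with the remedy
  bare <- simulateNetwork(net, dynamicsParams(iApp0 = 0, sigmaI = 0),
                          durationMs = 100, discardMs = 50)
  expect_error(simulateLFP(bare, net), "traceNeurons")
})

test_that("phase trajectory equals direct recomputation of windowed means", {
  net <- tinyNet(n = 60, widthMm = 1.2, heightMm = 1, seed = 4)
  res <- simulateNetwork(net, dynamicsParams(tauATP = 4000),
                         durationMs = 4000, discardMs = 1000, seed = 2,
                         traceStrideMs = 10)
  ph <- phaseTrajectory(res, windowMs = 50)
  expect_error(phaseTrajectory(simulateNetwork(net,
    dynamicsParams(tauATP = 4000), durationMs = 2000, discardMs = 500)),
    "recordPopulation|trace")

  # iFR column: brute-force population windowed rate
  bf <- bruteForceIFR(spikeTrain(res), 60, 1000, 4000, 50, 10)
  expect_equal(ph$ifrHz, rowMeans(bf$rates), tolerance = 1e-12)
  # ATP column: moving average of the recorded population ATP
  k <- 5
  sm <- as.numeric(stats::filter(res@traces$popAtp, rep(1 / k, k), sides = 2))
  onGrid <- stats::approx(res@traces$timeMs[!is.na(sm)], sm[!is.na(sm)],
                          xout = ph$timeMs, rule = 2)$y
  expect_equal(ph$atp, onGrid, tolerance = 1e-12)
  expect_true(all(ph$atp > 0 & ph$atp <= 1))
})
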