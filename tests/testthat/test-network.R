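test_that("placement is uniform, bounded and reproducible", {
  expect_equal(nNeurons(placeNeurons(0, 20, 5, seed = 1)), 0L)

  ps <- placeNeurons(5000, 20, 5, seed = 3)
  co <- positions(ps)
  expect_equal(nrow(co), 5000)
  expect_true(all(co[, 1] >= 0 & co[, 1] <= 20))
  expect_true(all(co[, 2] >= 0 & co[, 2] <= 5))

  # count in a fixed 1 mm^2 sub-square is Binomial(10000, 1/100)
  ps2 <- placeNeurons(10000, 20, 5, seed = 11)
  co2 <- positions(ps2)
  cnt <- sum(co2[, 1] >= 7 & co2[, 1] < 8 & co2[, 2] >= 2 & co2[, 2] < 3)
  expect_lt(abs(cnt - 100), 4 * sqrt(10000 * 0.01 * 0.99))

  expect_identical(positions(placeNeurons(50, 2, 2, seed = 9)),
                   positions(placeNeurons(50, 2, 2, seed = 9)))
  expect_error(placeNeurons(-1, 2, 2), "non-negative")
  expect_error(placeNeurons(5, 0, 2), "positive")
})

test_that("peak-probability calibration matches the analytic kernel integral", {
  expect_equal(calibratePeakProbability(50, 0.25, 10),
               10 / (50 * 2 * pi * 0.25^2), tolerance = 1e-12)
  expect_equal(calibratePeakProbability(3, 1, 0), 0)
  expect_error(calibratePeakProbability(50, 0.25, 30), "infeasible")
  # boundary correction raises p0 and stays feasible
  p0c <- calibratePeakProbability(50, 0.25, 10, widthMm = 20, heightMm = 5)
  expect_gt(p0c, calibratePeakProbability(50, 0.25, 10))
  expect_lt(p0c, 1)
})

test_that("link sampling follows the Gaussian kernel", {
  # no pairs -> empty adjacency
  one <- new("PositionSet", coords = cbind(x_mm = 0.5, y_mm = 0.5),
             widthMm = 1, heightMm = 1)
  A1 <- sampleConnectivity(one, peakProb = 0.5, seed = 1)
  expect_equal(length(A1@i), 0L)

  # two neurons held at distance sigma: empirical link frequency over many
  # seeds approaches peakProb * exp(-1/2)
  two <- new("PositionSet", coords = cbind(x_mm = c(0.4, 0.65),
                                           y_mm = c(0.5, 0.5)),
             widthMm = 1, heightMm = 1)
  hits <- vapply(1:1500, function(s)
    length(sampleConnectivity(two, sigmaMm = 0.25, peakProb = 0.6,
                              seed = s)@i), numeric(1))
  pHat <- mean(hits) / 2  # two ordered pairs per draw
  pTheory <- 0.6 * exp(-0.5)
  se <- sqrt(pTheory * (1 - pTheory) / 3000)
  expect_lt(abs(pHat - pTheory), 4 * se)

  # no self-links, determinism
  net <- tinyNet(seed = 5)
  A <- weightMatrix(net)
  expect_true(all(Matrix::diag(A) == 0))
  expect_identical(weightMatrix(tinyNet(seed = 5)), A)
})

test_that("interior mean in-degree matches the calibration target", {
  # neurons far from the boundary should average the target degree; the
  # placement itself contributes variance, so average over independent
  # placements and use the across-replicate spread
  ms <- vapply(1:6, function(rep) {
    ps <- placeNeurons(1800, 6, 6, seed = rep)
    A <- sampleConnectivity(ps, sigmaMm = 0.25,
                            peakProb = calibratePeakProbability(50, 0.25, 10),
                            seed = 100 + rep)
    deg <- Matrix::rowSums(A)
    co <- positions(ps)
    interior <- co[, 1] > 1 & co[, 1] < 5 & co[, 2] > 1 & co[, 2] < 5
    mean(deg[interior])
  }, numeric(1))
  expect_lt(abs(mean(ms) - 10), 3 * stats::sd(ms) / sqrt(6))
})

test_that("in-strength normalization gives exact, equal row sums", {
  # ten afferents -> each weight 0.04
  A <- Matrix::sparseMatrix(i = rep(1L, 10), j = 2:11, dims = c(11, 11))
  W <- normalizeInStrength(A, 0.4)
  expect_equal(unname(W[1, 2]), 0.04)
  expect_equal(unname(Matrix::rowSums(W)[1]), 0.4, tolerance = 1e-15)

  # single afferent carries the whole budget; isolated rows stay zero
  A2 <- Matrix::sparseMatrix(i = 1L, j = 2L, dims = c(3, 3))
  W2 <- normalizeInStrength(A2, 0.4)
  expect_equal(unname(W2[1, 2]), 0.4)
  expect_equal(unname(Matrix::rowSums(W2)[3]), 0)

  # exactness on a sampled network
  W3 <- weightMatrix(tinyNet(seed = 7))
  rs <- Matrix::rowSums(W3)
  expect_lt(max(abs(rs[rs > 0] - 0.4)), 1e-12)
})

test_that("rewiring preserves link count and hits the requested fraction", {
  net <- tinyNet(n = 400, widthMm = 4, heightMm = 2, seed = 3)
  A <- weightMatrix(net) != 0

  expect_identical(as(rewireLinks(A, 0, seed = 1), "CsparseMatrix") != 0, A)

  T0 <- as(as(A, "TsparseMatrix"), "generalMatrix")
  m <- length(T0@i)
  B <- rewireLinks(A, 0.5, seed = 9)
  TB <- as(as(B, "TsparseMatrix"), "generalMatrix")
  expect_equal(length(TB@i), m)            # link count preserved
  expect_true(all(TB@i != TB@j))           # no self-links
  key0 <- sort(as.double(T0@i) * 1e6 + T0@j)
  keyB <- sort(as.double(TB@i) * 1e6 + TB@j)
  changed <- length(setdiff(keyB, key0))
  # each link selected w.p. 0.5; a reselected link keeps its source w.p. ~1/n
  expect_lt(abs(changed / m - 0.5), 4 * sqrt(0.25 / m) + 1 / 400)

  # beta = 1: link lengths indistinguishable from uniformly random pairs
  C <- rewireLinks(A, 1, seed = 4)
  TC <- as(as(C, "TsparseMatrix"), "generalMatrix")
  co <- positions(net)
  lenC <- sqrt((co[TC@i + 1, 1] - co[TC@j + 1, 1])^2 +
               (co[TC@i + 1, 2] - co[TC@j + 1, 2])^2)
  set.seed(8)
  ii <- sample.int(400, 4000, TRUE); jj <- sample.int(400, 4000, TRUE)
  ok <- ii != jj
  lenR <- sqrt((co[ii[ok], 1] - co[jj[ok], 1])^2 +
               (co[ii[ok], 2] - co[jj[ok], 2])^2)
  expect_gt(suppressWarnings(stats::ks.test(lenC, lenR)$p.value), 1e-3)

  # builder re-normalizes after rewiring
  netB <- tinyNet(n = 400, widthMm = 4, heightMm = 2, seed = 3, beta = 0.3)
  rs <- Matrix::rowSums(weightMatrix(netB))
  expect_lt(max(abs(rs[rs > 0] - 0.4)), 1e-12)
  expect_error(rewireLinks(A, 1.5), "beta")
})
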