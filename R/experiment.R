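# Reproducible experiment runner and deterministic fixture presets.

#' Run a configured experiment end to end
#'
#' Builds the network, simulates it, runs the requested analyses and writes
#' every artifact (positions, weights, raster, traces, analysis tables)
#' plus a JSON manifest with the resolved configuration, the derived stage
#' seeds, and md5 checksums of every file - enough to re-run the
#' deterministic stages bit-identically.
#'
#' @param config nested list as returned by \code{\link{readRunConfig}} or
#'   \code{\link{defaultRunConfig}} (missing entries are filled with the
#'   defaults)
#' @param analyses character vector of analysis stages to run; any of
#'   \code{"ifr"}, \code{"distcorr"}, \code{"synchrony"}, \code{"onoff"},
#'   \code{"offon-stats"}, \code{"phase"}
#' @param quiet suppress stage messages?
#' @return the manifest, invisibly (also written to \code{manifest.json})
#' @examples
#' cfg <- defaultRunConfig()
#' cfg$network[c("n", "widthMm", "heightMm")] <- list(60, 1.5, 1.5)
#' cfg$dynamics[c("tauATP", "durationMs", "discardMs")] <-
#'   list(4000, 4000, 1000)
#' cfg$run$outDir <- file.path(tempdir(), "demo-run")
#' man <- runExperiment(cfg, analyses = "ifr", quiet = TRUE)
#' names(man$files)
#' @export
runExperiment <- function(config = defaultRunConfig(),
                          analyses = c("ifr", "synchrony", "onoff"),
                          quiet = FALSE) {
  config <- utils::modifyList(defaultRunConfig(), config)
  out <- config$run$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  seeds <- deriveSeeds(config$run$seed, 4)

  nw <- config$network
  say("building network (n = %d, beta = %g)", nw$n, nw$beta)
  net <- buildNetwork(n = nw$n, widthMm = nw$widthMm, heightMm = nw$heightMm,
                      sigmaMm = nw$sigmaMm, peakProb = nw$peakProb,
                      targetDegree = nw$targetDegree, totalIn = nw$totalIn,
                      beta = nw$beta, seed = seeds[1])
  writePositions(net@positions, file.path(out, "positions.tsv"))
  writeWeights(weightMatrix(net), file.path(out, "weights.tsv"))

  dy <- config$dynamics
  pars <- dynamicsParams(iApp0 = dy$iApp0, sigmaI = dy$sigmaI,
                         tauLeak = dy$tauLeak, alpha = dy$alpha,
                         epsilon = dy$epsilon, atpMax = dy$atpMax,
                         tauATP = dy$tauATP, lambdaSyn = dy$lambdaSyn,
                         dt = dy$dt, atpFloor = dy$atpFloor)
  say("simulating %g s at tau_ATP = %g s", dy$durationMs / 1000,
      dy$tauATP / 1000)
  traceNeurons <- if (identical(dy$traceNeurons, "all")) "all" else integer(0)
  res <- simulateNetwork(net, pars, durationMs = dy$durationMs,
                         seed = seeds[2], discardMs = dy$discardMs,
                         traceStrideMs = dy$traceStrideMs,
                         traceNeurons = traceNeurons)
  writeRaster(spikeTrain(res, discard = FALSE), file.path(out, "raster.tsv"))
  if (!is.null(res@traces) && !is.null(res@traces$popAtp))
    writeTraceTable(data.frame(t_ms = res@traces$timeMs,
                               pop_v = res@traces$popV,
                               pop_atp = res@traces$popAtp,
                               pop_epsc = res@traces$popSyn),
                    file.path(out, "pop-traces.tsv"))

  an <- config$analysis
  ifr <- NULL
  needIFR <- length(intersect(
    analyses, c("ifr", "distcorr", "synchrony", "onoff", "offon-stats")))
  if (needIFR) {
    say("computing iFR (%g ms window)", an$windowMs)
    ifr <- computeIFR(res, windowMs = an$windowMs, strideMs = an$strideMs)
    writeTraceTable(data.frame(t_ms = ifr@timesMs, pop_ifr_hz = popRate(ifr)),
                    file.path(out, "pop-ifr.tsv"))
  }
  if ("distcorr" %in% analyses) {
    say("distance-binned correlation")
    dc <- distanceBinnedCorrelation(ifr, net@positions, binUm = an$binUm,
                                    maxPairsPerBin = an$maxPairsPerBin,
                                    seed = seeds[3])
    writeHeadedTable(dc, file.path(out, "distcorr.tsv"),
                     paste(names(dc), collapse = "\t"))
  }
  if ("synchrony" %in% analyses) {
    mpc <- meanPairwiseCorrelation(ifr, maxPairs = an$maxPairs,
                                   seed = seeds[4])
    writeHeadedTable(data.frame(mean_pairwise_r = mpc),
                     file.path(out, "synchrony.tsv"), "mean_pairwise_r")
  }
  seg <- NULL
  if (length(intersect(analyses, c("onoff", "offon-stats")))) {
    seg <- detectOnOff(ifr, thresholdHz = an$thresholdHz,
                       minSegmentMs = an$minSegmentMs)
    writeHeadedTable(intervals(seg), file.path(out, "onoff.tsv"),
                     paste(names(intervals(seg)), collapse = "\t"))
  }
  if ("offon-stats" %in% analyses) {
    st <- tryCatch(offOnPeakStatistics(seg), error = function(e) e)
    df <- if (inherits(st, "error")) {
      data.frame(r_off_pre_on_post = NA, r_on_pre_off_post = NA,
                 n_off_on = 0, n_on_off = 0)
    } else {
      data.frame(r_off_pre_on_post = st$rOffPreOnPost,
                 r_on_pre_off_post = st$rOnPreOffPost,
                 n_off_on = st$nOffOn, n_on_off = st$nOnOff)
    }
    writeHeadedTable(df, file.path(out, "offon-stats.tsv"),
                     paste(names(df), collapse = "\t"))
  }
  if ("phase" %in% analyses) {
    ph <- phaseTrajectory(res, windowMs = an$windowMs)
    writeTraceTable(stats::setNames(ph, c("t_ms", "pop_atp", "pop_ifr_hz")),
                    file.path(out, "phase.tsv"))
  }

  files <- list.files(out, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    config = config,
    stageSeeds = list(build = seeds[1], simulate = seeds[2],
                      pairSubsampleDistcorr = seeds[3],
                      pairSubsampleSynchrony = seeds[4]),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)),
    elapsedSec = round(proc.time()[["elapsed"]] - t0, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    packageVersion = as.character(utils::packageVersion("atpnet")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done in %.1f s", manifest$elapsedSec)
  invisible(manifest)
}

#' Deterministic fixture presets
#'
#' Small inputs for tests and demos, written as the standard text
#' artifacts:
#' \describe{
#'   \item{tiny-net}{50 neurons on 1 x 1 mm with normalized weights
#'     (positions.tsv, weights.tsv).}
#'   \item{toy-raster}{a square-wave population raster alternating 1-s
#'     silent and 1-s active (30 Hz, 20 neurons) phases over 10 s
#'     (raster.tsv) - segmentation ground truth.}
#'   \item{two-neuron-lfp}{two neurons at 100 um and 200 um from the centre
#'     of a 1 x 1 mm sheet, one link between them (positions.tsv,
#'     weights.tsv) - the 4:1 shape-function toy.}
#' }
#'
#' @param preset one of \code{"tiny-net"}, \code{"toy-raster"},
#'   \code{"two-neuron-lfp"}
#' @param dir output directory
#' @param seed RNG seed
#' @return named list of written file paths, invisibly
#' @export
makeFixture <- function(preset, dir = ".", seed = 1) {
  presets <- c("tiny-net", "toy-raster", "two-neuron-lfp")
  if (!preset %in% presets)
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(presets, collapse = ", ")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (preset == "tiny-net") {
    net <- buildNetwork(n = 50, widthMm = 1, heightMm = 1, seed = seed)
    out$positions <- writePositions(net@positions,
                                    file.path(dir, "positions.tsv"))
    out$weights <- writeWeights(weightMatrix(net),
                                file.path(dir, "weights.tsv"))
  } else if (preset == "toy-raster") {
    set.seed(seed)
    spikes <- do.call(rbind, lapply(seq(0, 8000, by = 2000), function(on0) {
      t <- sort(stats::runif(600, on0 + 1000, on0 + 2000))
      data.frame(neuron = sample.int(20, 600, replace = TRUE), timeMs = t)
    }))
    spikes <- spikes[order(spikes$timeMs), ]
    out$raster <- writeRaster(spikes, file.path(dir, "raster.tsv"))
  } else {
    co <- cbind(x_mm = c(0.6, 0.7), y_mm = c(0.5, 0.5))
    ps <- new("PositionSet", coords = co, widthMm = 1, heightMm = 1)
    W <- Matrix::sparseMatrix(i = 2L, j = 1L, x = 0.4, dims = c(2, 2),
                              repr = "C")
    out$positions <- writePositions(ps, file.path(dir, "positions.tsv"))
    out$weights <- writeWeights(W, file.path(dir, "weights.tsv"))
  }
  invisible(out)
}
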