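# Plain-text interchange: tab-separated tables with a '#'-prefixed header
# line, and the [section] key = value run configuration dialect.

writeHeadedTable <- function(df, path, header) {
  writeLines(paste0("# ", header), path)
  if (nrow(df))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  invisible(path)
}

readHeadedTable <- function(path, colNames, colClasses) {
  emptyDf <- function() stats::setNames(as.data.frame(
    lapply(colClasses, function(cl) vector(cl, 0))), colNames)
  if (length(readLines(path, n = 2)) < 2) return(emptyDf())
  df <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, skip = 1,
                      col.names = colNames, colClasses = colClasses,
                      data.table = FALSE),
    error = function(e) {
      first <- readLines(path, n = 50)
      bad <- which(!startsWith(first, "#") & nzchar(first))
      stop(sprintf("malformed table %s near line %d: %s", path,
                   if (length(bad)) bad[1] else 1L, conditionMessage(e)),
           call. = FALSE)
    })
  if (nrow(df) == 0) df <- emptyDf()
  df
}

#' Write / read neuron positions
#'
#' Tab-separated text with columns \code{neuron_id} (0-based), \code{x_mm},
#' \code{y_mm} and a commented header carrying the rectangle extents.
#' Reading validates that every coordinate lies inside the rectangle and
#' names the offending row otherwise.
#'
#' @param positions a \linkS4class{PositionSet}
#' @param path file path
#' @return \code{writePositions} the path; \code{readPositions} a
#'   \linkS4class{PositionSet}
#' @export
writePositions <- function(positions, path) {
  co <- positions(positions)
  df <- data.frame(neuron_id = seq_len(nrow(co)) - 1L,
                   x_mm = co[, 1], y_mm = co[, 2])
  writeHeadedTable(df, path,
                   sprintf("neuron_id\tx_mm\ty_mm\twidth_mm=%g\theight_mm=%g",
                           positions@widthMm, positions@heightMm))
}

#' @rdname writePositions
#' @export
readPositions <- function(path) {
  hdr <- readLines(path, n = 1)
  w <- as.numeric(sub(".*width_mm=([0-9.eE+-]+).*", "\\1", hdr))
  h <- as.numeric(sub(".*height_mm=([0-9.eE+-]+).*", "\\1", hdr))
  if (!is.finite(w) || !is.finite(h))
    stop("positions file lacks width_mm/height_mm in its header")
  df <- readHeadedTable(path, c("neuron_id", "x_mm", "y_mm"),
                        c("integer", "numeric", "numeric"))
  df <- df[order(df$neuron_id), ]
  bad <- which(df$x_mm < 0 | df$x_mm > w | df$y_mm < 0 | df$y_mm > h)
  if (length(bad))
    stop(sprintf("coordinate outside the %g x %g mm rectangle at row %d (neuron_id %d)",
                 w, h, bad[1], df$neuron_id[bad[1]]))
  new("PositionSet", coords = cbind(x_mm = df$x_mm, y_mm = df$y_mm),
      widthMm = w, heightMm = h)
}

#' Write / read synaptic weights
#'
#' Sparse triplet text: columns \code{target_id}, \code{source_id},
#' \code{weight} (0-based ids; target = i, source = j for \eqn{C_{ij}}).
#'
#' @param weights a sparse weight matrix (\code{dgCMatrix})
#' @param path file path
#' @param n neuron count (needed on read)
#' @return \code{writeWeights} the path; \code{readWeights} a
#'   \code{dgCMatrix}
#' @export
writeWeights <- function(weights, path) {
  T <- as(as(weights, "TsparseMatrix"), "generalMatrix")
  df <- data.frame(target_id = T@i, source_id = T@j, weight = T@x)
  df <- df[order(df$target_id, df$source_id), ]
  writeHeadedTable(df, path,
                   sprintf("target_id\tsource_id\tweight\tn=%d", nrow(weights)))
}

#' @rdname writeWeights
#' @export
readWeights <- function(path, n = NULL) {
  if (is.null(n)) {
    hdr <- readLines(path, n = 1)
    n <- suppressWarnings(as.integer(sub(".*n=([0-9]+).*", "\\1", hdr)))
    if (!isTRUE(is.finite(n))) stop("weights file lacks n= in its header")
  }
  df <- readHeadedTable(path, c("target_id", "source_id", "weight"),
                        c("integer", "integer", "numeric"))
  Matrix::sparseMatrix(i = df$target_id + 1L, j = df$source_id + 1L,
                       x = df$weight, dims = c(n, n), repr = "C")
}

#' Write / read a spike raster
#'
#' Tab-separated text with columns \code{neuron_id} (0-based) and
#' \code{spike_time_ms}, ordered by time.
#'
#' @param raster data.frame with columns \code{neuron}, \code{timeMs} (as
#'   returned by \code{\link{spikeTrain}})
#' @param path file path
#' @return \code{writeRaster} the path; \code{readRaster} a raster
#'   data.frame with columns \code{neuron}, \code{timeMs}
#' @export
writeRaster <- function(raster, path) {
  df <- data.frame(neuron_id = raster$neuron - 1L,
                   spike_time_ms = raster$timeMs)
  df <- df[order(df$spike_time_ms), ]
  writeHeadedTable(df, path, "neuron_id\tspike_time_ms")
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  df <- readHeadedTable(path, c("neuron_id", "spike_time_ms"),
                        c("integer", "numeric"))
  data.frame(neuron = df$neuron_id + 1L, timeMs = df$spike_time_ms)
}

#' Write / read population trace tables
#'
#' Columnar text for time series (first column \code{t_ms}, remaining
#' columns named in the header).
#'
#' @param df data.frame whose first column is \code{t_ms}
#' @param path file path
#' @return \code{writeTraceTable} the path; \code{readTraceTable} a
#'   data.frame
#' @export
writeTraceTable <- function(df, path) {
  writeHeadedTable(df, path, paste(names(df), collapse = "\t"))
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1)), "\t")[[1]]
  readHeadedTable(path, hdr, rep("numeric", length(hdr)))
}

#' Read / write a run configuration
#'
#' Structured plain text: \code{[section]} headers with \code{key = value}
#' lines. Sections mirror the module surfaces (\code{network},
#' \code{dynamics}, \code{meanfield}, \code{analysis}, \code{run}). Unknown
#' keys are rejected so silent typos cannot change a run. Values are parsed
#' as numeric where possible, \code{TRUE}/\code{FALSE} as logical, anything
#' else as character.
#'
#' @param path file path
#' @param config nested named list (section -> key -> value)
#' @return \code{readRunConfig} a nested named list
#' @seealso \code{\link{defaultRunConfig}} for all defaults
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  cfg <- list()
  section <- NULL
  known <- defaultRunConfig()
  for (k in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[k]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(known))
        stop(sprintf("unknown config section [%s] (line %d)", section, k))
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    if (!grepl("=", ln) || is.null(section))
      stop(sprintf("malformed config line %d: '%s'", k, lines[k]))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(known[[section]]))
      stop(sprintf("unknown key '%s' in section [%s] (line %d)",
                   key, section, k))
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <-
      if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  utils::modifyList(known, cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  out <- character(0)
  for (sec in names(config)) {
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(config[[sec]]))
      out <- c(out, sprintf("%s = %s", key, format(config[[sec]][[key]])))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Default run configuration
#'
#' Every tunable of the pipeline with its default value; the defaults are
#' the standard study conditions (5,000 neurons on 20 x 5 mm, sigma = 0.25
#' mm, incoming strength 0.4, dt = 0.5 ms, 120 s simulated with 20 s
#' discarded, 50-ms analysis windows, 1-Hz ON/OFF threshold, 200-um
#' distance bins).
#'
#' @return nested named list
#' @export
defaultRunConfig <- function() {
  list(
    run = list(id = "run", outDir = "atpnet-out", seed = 1),
    network = list(n = 5000, widthMm = 20, heightMm = 5, sigmaMm = 0.25,
                   peakProb = "auto", targetDegree = 10, totalIn = 0.4,
                   beta = 0),
    dynamics = list(iApp0 = 0.03, sigmaI = 0.006, tauLeak = 38.75,
                    alpha = 0.002, epsilon = 0.005, atpMax = 1,
                    tauATP = 10000, lambdaSyn = 2, dt = 0.5,
                    atpFloor = 0.01, durationMs = 120000,
                    discardMs = 20000, traceStrideMs = 10,
                    traceNeurons = "none"),
    meanfield = list(cFeedback = 0.4, windowMs = 200, tauATP = 10000,
                     durationMs = 120000, discardMs = 20000),
    analysis = list(windowMs = 50, strideMs = 10, binUm = 200,
                    thresholdHz = 1, minSegmentMs = 50,
                    maxPairsPerBin = 2000, maxPairs = 20000,
                    electrodeX = 10, electrodeY = 2.5)
  )
}
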