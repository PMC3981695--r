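#' Read a depth trace from delimited text
#'
#' Reads the two-column trace format written by [writeDepthTrace()]
#' (elapsed seconds, depth in metres, with a header line and
#' \code{# key: value} metadata comments), or any two-column CSV/TSV
#' with a header whose first column is elapsed seconds and second
#' column depth.
#'
#' @param path file path.
#' @param animal animal id to use if the file carries none.
#' @param dt sampling interval to use if the file carries none;
#'   inferred from the time column when NULL.
#' @return A [DepthTrace-class] object.
#' @seealso [writeDepthTrace()]
#' @export
readDepthTrace <- function(path, animal = NULL, dt = NULL) {
  lines <- readLines(path, n = 50)
  meta <- grep("^# ", lines, value = TRUE)
  getMeta <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^# ", key, ":"), "", hit[1])) else NULL
  }
  sepChar <- if (any(grepl("\t", grep("^[^#]", lines, value = TRUE)[1])))
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sepChar,
                          comment.char = "#", stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 2, "trace file must have time and depth columns")
  tm <- as.numeric(df[[1]])
  dp <- as.numeric(df[[2]])
  if (is.null(animal)) animal <- getMeta("animal") %||% "A1"
  if (is.null(dt)) {
    dtMeta <- getMeta("dt")
    dt <- if (!is.null(dtMeta)) as.numeric(dtMeta) else stats::median(diff(tm))
  }
  startMeta <- getMeta("start")
  start <- if (!is.null(startMeta))
    as.POSIXct(startMeta, tz = "UTC") else as.POSIXct("2007-04-01", tz = "UTC")
  depthTrace(dp, dt = dt, animal = animal, start = start, time = tm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a depth trace as delimited text
#'
#' Two columns (elapsed seconds, depth in metres) with metadata
#' comments recording the animal id, sampling interval and absolute
#' start time, so [readDepthTrace()] round-trips losslessly.
#'
#' @param trace a [DepthTrace-class] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDepthTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# animal: ", trace@animal),
    paste0("# dt: ", format(trace@dt, digits = 12)),
    paste0("# start: ", format(trace@start, "%Y-%m-%d %H:%M:%S",
                               tz = "UTC")),
    "elapsed_s,depth_m"), con)
  writeLines(paste(format(trace@time, trim = TRUE, digits = 12),
                   format(round(trace@depth, 4), trim = TRUE, digits = 12),
                   sep = ","), con)
  invisible(path)
}

#' Zero-offset correction of a depth trace
#'
#' Removes pressure-transducer surface drift by subtracting a rolling
#' surface baseline: the lower \code{prob} quantile of depth within a
#' moving window. Corrected depths are clamped at zero. After
#' correction, surface samples lie within the transducer resolution
#' (0.5 m) of zero provided the animal surfaces regularly within each
#' window.
#'
#' @param trace a [DepthTrace-class] object.
#' @param window window width in seconds (default 2 h); must cover at
#'   least 10 samples.
#' @param prob baseline quantile (default 0.05).
#' @return A corrected [DepthTrace-class] object.
#' @examples
#' tr <- depthTrace(rep(1.5, 20), dt = 10)
#' range(depths(zeroOffsetCorrect(tr, window = 150)))
#' @export
zeroOffsetCorrect <- function(trace, window = 7200, prob = 0.05) {
  stopIfNot(is(trace, "DepthTrace"), "trace must be a DepthTrace")
  wSamples <- floor(window / trace@dt)
  if (wSamples < 10)
    stop("correction window must cover at least 10 samples", call. = FALSE)
  baseline <- rollingQuantile(trace@depth, wSamples, prob = prob)
  corrected <- pmax(trace@depth - baseline, 0)
  methods::initialize(trace, depth = corrected)
}

#' Detect dives in a corrected depth trace
#'
#' Finds maximal runs of consecutive samples deeper than
#' \code{surfaceThreshold}, then keeps runs whose maximum depth exceeds
#' \code{minDepth} (exclusive) and whose length is at least
#' \code{minSamples}. The defaults implement the standard filters for
#' harbor-seal TDR records: dives of 5 m or less, or with fewer than
#' five depth readings, are excluded because their sampled shape is
#' unreliable.
#'
#' @param trace a zero-offset-corrected [DepthTrace-class] object.
#' @param surfaceThreshold submergence threshold in metres (default
#'   2 m, separating splashing/noise from diving).
#' @param minDepth minimum maximum-depth in metres, exclusive (default
#'   5 m).
#' @param minSamples minimum run length in samples (default 5).
#' @return data.frame with one row per dive window: \code{start},
#'   \code{end} (1-based inclusive sample indices), \code{start_s},
#'   \code{end_s} (elapsed seconds) and \code{max_depth} (m). Empty on
#'   an all-surface trace.
#' @examples
#' tr <- depthTrace(c(0, 0, 3, 8, 12, 12, 8, 3, 0, 0), dt = 10)
#' detectDives(tr)
#' @export
detectDives <- function(trace, surfaceThreshold = 2, minDepth = 5,
                        minSamples = 5) {
  stopIfNot(is(trace, "DepthTrace"), "trace must be a DepthTrace")
  below <- trace@depth > surfaceThreshold
  if (!any(below))
    return(data.frame(start = integer(), end = integer(),
                      start_s = numeric(), end_s = numeric(),
                      max_depth = numeric()))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  maxd <- vapply(seq_along(starts), function(i)
    max(trace@depth[starts[i]:ends[i]]), numeric(1))
  len <- ends - starts + 1L
  ok <- maxd > minDepth & len >= minSamples
  data.frame(start = starts[ok], end = ends[ok],
             start_s = trace@time[starts[ok]],
             end_s = trace@time[ends[ok]],
             max_depth = maxd[ok])
}
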