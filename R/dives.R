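#' Compute per-dive shape metrics
#'
#' For each detected dive window, computes the classification
#' variables: maximum depth, duration, bottom time (time spent at or
#' below \code{bottomFraction} of the dive's maximum depth), wiggle
#' count (shallowing reversals in the bottom portion whose rise and
#' fall both exceed \code{wiggleMinExcursion}), average descent and
#' ascent rates, skew (ascent/descent rate ratio and its reciprocal)
#' and the derived ratios BTD (bottom time / duration), BTM (bottom
#' time / max depth) and MDD (max depth / duration).
#'
#' Conventions fixed for reproducibility: a dive spans consecutive
#' submerged samples (inclusive indices); duration is the number of
#' samples in the window times \code{dt}; bottom time is the number of
#' bottom-phase samples times \code{dt}; the descent rate is the depth
#' of the first bottom-phase sample divided by the elapsed time from
#' the first window sample to it (one \code{dt} if they coincide), and
#' the ascent rate symmetrically from the last bottom-phase sample to
#' the window end. Wiggles are counted over the span from the first to
#' the last bottom-phase sample.
#'
#' @param trace a [DepthTrace-class] object.
#' @param windows data.frame of dive windows from [detectDives()].
#' @param bottomFraction bottom-phase threshold as a fraction of
#'   maximum depth (default 0.85).
#' @param wiggleMinExcursion minimum excursion in metres for a
#'   reversal to count as a wiggle (default 1 m, twice the transducer
#'   resolution).
#' @return data.frame with one row per dive: \code{animal},
#'   \code{start_s}, \code{end_s}, \code{max_depth}, \code{duration},
#'   \code{bottom_time}, \code{wiggles}, \code{skew1}, \code{skew2},
#'   \code{btd}, \code{btm}, \code{mdd}, \code{descent_rate},
#'   \code{ascent_rate}, \code{is_wiggle}, \code{shape} (square/V via
#'   [labelShape()]) and \code{depth_class} (deep >= 20 m).
#' @examples
#' tr <- depthTrace(c(0, 10, 20, 20, 20, 10, 0), dt = 10)
#' computeDiveMetrics(tr, detectDives(tr, minSamples = 4))
#' @export
computeDiveMetrics <- function(trace, windows, bottomFraction = 0.85,
                               wiggleMinExcursion = 1) {
  stopIfNot(is(trace, "DepthTrace"), "trace must be a DepthTrace")
  dt <- trace@dt
  n <- nrow(windows)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- windows$start[i]
    e <- windows$end[i]
    d <- trace@depth[s:e]
    maxd <- max(d)
    botIdx <- which(d >= bottomFraction * maxd)
    b1 <- botIdx[1]
    b2 <- botIdx[length(botIdx)]
    bottomTime <- length(botIdx) * dt
    duration <- length(d) * dt
    descT <- max((b1 - 1) * dt, dt)
    ascT <- max((length(d) - b2) * dt, dt)
    descRate <- d[b1] / descT
    ascRate <- d[b2] / ascT
    wig <- countWiggles(d[b1:b2], wiggleMinExcursion)
    out[[i]] <- data.frame(
      animal = trace@animal,
      start_s = trace@time[s], end_s = trace@time[e],
      max_depth = maxd, duration = duration, bottom_time = bottomTime,
      wiggles = wig,
      skew1 = ascRate / descRate, skew2 = descRate / ascRate,
      btd = bottomTime / duration, btm = bottomTime / maxd,
      mdd = maxd / duration,
      descent_rate = descRate, ascent_rate = ascRate,
      is_wiggle = wig > 0,
      stringsAsFactors = FALSE)
  }
  res <- if (n) do.call(rbind, out) else data.frame()
  if (n) {
    res$shape <- labelShape(res)
    res$depth_class <- ifelse(res$max_depth >= 20, "deep", "shallow")
    rownames(res) <- NULL
  }
  res
}

#' Label dives as square or V-shaped
#'
#' A dive is square when its bottom-time-to-duration ratio (BTD) is at
#' least the threshold (boundary inclusive), otherwise V-shaped.
#' Square dives spend a large share of the dive at depth and proxy
#' foraging; V dives proxy travel or exploration.
#'
#' @param records data.frame with a \code{btd} column, or a numeric
#'   vector of BTD values.
#' @param squareBtdThreshold BTD threshold (default 0.5).
#' @return character vector, \code{"square"} or \code{"V"}.
#' @examples
#' labelShape(c(0.95, 0.26, 0.5))
#' @export
labelShape <- function(records, squareBtdThreshold = 0.5) {
  btd <- if (is.data.frame(records)) records$btd else records
  ifelse(btd >= squareBtdThreshold, "square", "V")
}

#' Default monthly sunrise/sunset table
#'
#' Mean sunrise and sunset hours (local solar time) per month computed
#' from day length at the given latitude, for use by
#' [assignContext()] when no observed table is supplied.
#'
#' @param lat latitude in decimal degrees (default 48.48, the San Juan
#'   Islands study area).
#' @return data.frame with columns \code{month} (1-12),
#'   \code{sunrise}, \code{sunset} (decimal hours).
#' @export
solarTable <- function(lat = 48.48) {
  months <- 1:12
  midDoy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  dl <- vapply(midDoy, function(doy) geosphere::daylength(lat, doy),
               numeric(1))
  data.frame(month = months, sunrise = 12 - dl / 2, sunset = 12 + dl / 2)
}

#' Assign season and light context to dives
#'
#' Adds \code{season} (breeding vs non-breeding by calendar month of
#' the dive start) and \code{light} (day vs night by comparison of the
#' dive start hour against the monthly mean sunrise and sunset; the
#' day interval is half-open, \code{[sunrise, sunset)}, so a dive at
#' exactly mean sunset is night). Months missing from the supplied
#' table fall back to a solar day-length approximation at the
#' configured latitude, with a message.
#'
#' @param records dive (or bout) data.frame with a \code{start_s}
#'   column of elapsed seconds.
#' @param start POSIXct absolute time of second 0 of the record.
#' @param sunriseSunset data.frame with columns \code{month},
#'   \code{sunrise}, \code{sunset} (decimal hours); defaults to
#'   [solarTable()].
#' @param breedingMonths months counted as the breeding season
#'   (default July-October; November-June is non-breeding).
#' @param lat latitude for the solar fallback.
#' @return \code{records} with \code{season} and \code{light} columns
#'   added.
#' @examples
#' recs <- data.frame(start_s = c(0, 3600 * 12))
#' assignContext(recs, start = as.POSIXct("2007-07-15", tz = "UTC"))
#' @export
assignContext <- function(records, start,
                          sunriseSunset = solarTable(),
                          breedingMonths = 7:10, lat = 48.48) {
  stopIfNot(!is.null(records$start_s), "records need a start_s column")
  when <- as.POSIXct(start, tz = "UTC") + records$start_s
  month <- as.integer(format(when, "%m"))
  hour <- as.numeric(format(when, "%H")) +
    as.numeric(format(when, "%M")) / 60 +
    as.numeric(format(when, "%S")) / 3600
  missing <- setdiff(unique(month), sunriseSunset$month)
  if (length(missing)) {
    message("months ", paste(missing, collapse = ", "),
            " missing from sunrise/sunset table; using solar ",
            "approximation at latitude ", lat)
    fb <- solarTable(lat)
    sunriseSunset <- rbind(sunriseSunset,
                           fb[fb$month %in% missing, , drop = FALSE])
  }
  idx <- match(month, sunriseSunset$month)
  rise <- sunriseSunset$sunrise[idx]
  set <- sunriseSunset$sunset[idx]
  records$season <- ifelse(month %in% breedingMonths,
                           "breeding", "nonbreeding")
  records$light <- ifelse(hour >= rise & hour < set, "day", "night")
  records
}
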