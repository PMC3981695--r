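#' Bout-detection configuration
#'
#' @param startMinDives minimum run of consecutive qualifying dives to
#'   open a bout (default 4, >= 2).
#' @param startMinDepth minimum maximum-depth (m) for each opening dive
#'   (default 6 m).
#' @param alpha significance level of the one-sided sequential t-test
#'   (default 0.05), in (0, 1).
#' @return list of class \code{"boutConfig"}.
#' @export
boutConfig <- function(startMinDives = 4, startMinDepth = 6, alpha = 0.05) {
  stopIfNot(startMinDives >= 2, "startMinDives must be >= 2")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(startMinDives = as.integer(startMinDives),
                 startMinDepth = startMinDepth, alpha = alpha),
            class = "boutConfig")
}

#' Group dives into bouts by the iterative sequential t-test
#'
#' Implements the modified iterative bout criterion: scanning the
#' time-ordered dive sequence of one animal left to right, a bout
#' opens at the first run of \code{startMinDives} consecutive dives
#' each reaching \code{startMinDepth}. Each subsequent dive joins the
#' open bout unless its preceding surface interval is significantly
#' greater than the mean of the surface intervals already inside the
#' bout: with k previous intervals of mean m and sample SD s, the
#' statistic is \deqn{t = (x - m) / (s \sqrt{1 + 1/k})} referred to a
#' Student-t distribution with k - 1 degrees of freedom (one-sided,
#' single-new-observation prediction form). If the test is significant
#' at \code{alpha} the bout closes before that interval and scanning
#' resumes at the dive that failed to join. With zero-variance history
#' (s = 0) the bout closes iff the next interval strictly exceeds the
#' mean; a non-positive statistic can never close a bout.
#'
#' @param dives time-ordered dive data.frame for one animal, with
#'   \code{start_s} and \code{end_s} columns; the surface interval
#'   before dive i+1 is \code{start_s[i + 1] - end_s[i]}.
#' @param config a [boutConfig()] bundle.
#' @return list with \code{assignment} (integer bout id per dive, NA
#'   outside bouts), \code{bouts} (list of integer index vectors) and
#'   \code{unassigned} (indices outside any bout).
#' @examples
#' dv <- data.frame(start_s = c(0, 100, 200, 300, 400, 5000),
#'                  end_s   = c(40, 140, 240, 340, 440, 5040),
#'                  max_depth = rep(10, 6))
#' detectBouts(dv)$assignment
#' @export
detectBouts <- function(dives, config = boutConfig()) {
  n <- nrow(dives)
  assignment <- rep(NA_integer_, n)
  bouts <- list()
  if (n < config$startMinDives)
    return(list(assignment = assignment, bouts = bouts,
                unassigned = seq_len(n)))
  stopIfNot(!is.unsorted(dives$start_s),
            "dives must be ordered by start time")
  intervals <- dives$start_s[-1] - dives$end_s[-n]  # interval i precedes dive i+1
  deepEnough <- dives$max_depth >= config$startMinDepth
  q <- config$startMinDives
  boutId <- 0L
  i <- 1L
  while (i <= n - q + 1L) {
    if (!all(deepEnough[i:(i + q - 1L)])) {
      i <- i + 1L
      next
    }
    members <- i:(i + q - 1L)
    j <- i + q - 1L  # last member
    while (j < n) {
      hist <- intervals[members[-length(members)]]
      x <- intervals[j]
      m <- mean(hist)
      s <- stats::sd(hist)
      k <- length(hist)
      significant <- if (s == 0) {
        x > m
      } else {
        tstat <- (x - m) / (s * sqrt(1 + 1 / k))
        tstat > stats::qt(1 - config$alpha, df = k - 1L)
      }
      if (significant) break
      members <- c(members, j + 1L)
      j <- j + 1L
    }
    boutId <- boutId + 1L
    bouts[[boutId]] <- members
    assignment[members] <- boutId
    i <- j + 1L
  }
  list(assignment = assignment, bouts = bouts,
       unassigned = which(is.na(assignment)))
}

#' Summarise bouts into the eight classification variables
#'
#' For each detected bout, computes: number of dives, mean dive depth,
#' mean dive duration, mean within-bout surface interval, bout
#' duration (first dive start to last dive end), percent of time at
#' depth (total bottom time / bout duration), and the percent of
#' square- and V-shaped member dives (from [labelShape()] classes;
#' they sum to 1). Covariate columns (\code{site}, \code{season},
#' \code{sex}, \code{light}) present on the dive table are carried to
#' the bout by majority over member dives, ties resolved by the first
#' dive's value.
#'
#' @param dives dive data.frame with metrics (and optionally context)
#'   computed.
#' @param detection result of [detectBouts()] on \code{dives}.
#' @return data.frame with one row per bout.
#' @export
summarizeBouts <- function(dives, detection) {
  majority <- function(v) {
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else as.character(v[1])
  }
  covCols <- intersect(c("site", "season", "sex", "light"), names(dives))
  rows <- lapply(seq_along(detection$bouts), function(b) {
    idx <- detection$bouts[[b]]
    d <- dives[idx, ]
    n <- nrow(d)
    surf <- d$start_s[-1] - d$end_s[-n]
    boutDur <- d$end_s[n] - d$start_s[1]
    out <- data.frame(
      bout = b,
      animal = if (!is.null(d$animal)) d$animal[1] else NA_character_,
      n_dives = n,
      mean_depth = mean(d$max_depth),
      mean_duration = mean(d$duration),
      mean_surface_interval = mean(surf),
      bout_duration = boutDur,
      pct_time_at_depth = sum(d$bottom_time) / boutDur,
      pct_square = mean(d$shape == "square"),
      pct_v = mean(d$shape == "V"),
      start_s = d$start_s[1],
      stringsAsFactors = FALSE)
    for (cc in covCols) out[[cc]] <- majority(d[[cc]])
    out
  })
  if (!length(rows))
    return(data.frame())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fraction of dives occurring outside bouts
#'
#' @param dives dive data.frame (or anything with a row count).
#' @param detection result of [detectBouts()].
#' @return proportion of dives not assigned to any bout.
#' @export
fractionOutsideBouts <- function(dives, detection) {
  n <- if (is.data.frame(dives)) nrow(dives) else length(dives)
  if (n == 0) stop("no dives: fraction outside bouts is undefined",
                   call. = FALSE)
  length(detection$unassigned) / n
}
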