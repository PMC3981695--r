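#' Published dive-type parameterization
#'
#' Mean and SD of the dive shape variables for the six harbor-seal dive
#' types: four square-shaped (1, 2, 3, 6) and two V-shaped (4, 5)
#' types, with deep types (1, 3) reaching >= 20 m. Types 1 and 2 are
#' wiggle dives; types 3 and 6 their non-wiggle counterparts; types 4
#' and 5 differ in skew direction.
#'
#' @param sdScale multiplier applied to every SD column; 0.5 gives the
#'   well-separated half-dispersion regime used for recovery checks.
#' @return data.frame with one row per dive type and columns
#'   \code{type}, \code{shape}, and mean/SD pairs for max depth (m),
#'   duration (s), bottom time (s), wiggle count, skew (ascent/descent
#'   rate ratio) and descent/ascent rates (m/s).
#' @examples
#' diveTypeParams()[, 1:6]
#' @export
diveTypeParams <- function(sdScale = 1) {
  p <- data.frame(
    type = 1:6,
    shape = c("square", "square", "square", "V", "V", "square"),
    depth_mean    = c(62, 13.36, 56.23, 17.55, 16.13, 13.57),
    depth_sd      = c(30.65, 7.19, 23.51, 12.8, 12.68, 7.71),
    duration_mean = c(310.14, 219.27, 304.58, 148.73, 166.45, 241.79),
    duration_sd   = c(107.69, 99.57, 78.48, 73.77, 73.92, 106.89),
    bottom_mean   = c(181.62, 152.81, 192.14, 39.51, 60.03, 179.79),
    bottom_sd     = c(96.69, 89.11, 76.16, 29.53, 46.45, 100.31),
    wiggles_mean  = c(1.05, 1.04, 0, 0.46, 0.35, 0),
    wiggles_sd    = c(0.38, 0.29, 0, 0.51, 0.48, 0),
    skew_mean     = c(0.94, 1.01, 0.95, 1.8, 0.47, 1.04),
    skew_sd       = c(0.26, 0.48, 0.23, 1.17, 0.17, 0.48),
    descent_mean  = c(1.11, 0.54, 1.1, 0.42, 0.65, 0.52),
    descent_sd    = c(0.33, 0.26, 0.33, 0.27, 0.67, 0.26),
    ascent_mean   = c(1, 0.5, 1.02, 0.61, 0.29, 0.5),
    ascent_sd     = c(0.3, 0.25, 0.33, 0.37, 0.18, 0.25),
    stringsAsFactors = FALSE
  )
  sdCols <- grep("_sd$", names(p), value = TRUE)
  p[sdCols] <- lapply(p[sdCols], function(v) v * sdScale)
  validateDiveTypeParams(p)
  p
}

validateDiveTypeParams <- function(p) {
  need <- c("type", "shape", "depth_mean", "depth_sd", "duration_mean",
            "duration_sd", "bottom_mean", "bottom_sd", "wiggles_mean",
            "wiggles_sd", "skew_mean", "skew_sd", "descent_mean",
            "descent_sd", "ascent_mean", "ascent_sd")
  stopIfNot(all(need %in% names(p)),
            "dive type parameters are missing required columns")
  meanCols <- setdiff(grep("_mean$", names(p), value = TRUE), "wiggles_mean")
  stopIfNot(all(unlist(p[meanCols]) > 0),
            "all dive shape means must be positive")
  stopIfNot(all(p$wiggles_mean >= 0), "wiggle means must be >= 0")
  stopIfNot(all(unlist(p[grep("_sd$", names(p))]) >= 0),
            "all SDs must be >= 0")
  stopIfNot(all(p$bottom_mean < p$duration_mean),
            "bottom time mean must be below duration mean")
  invisible(p)
}

#' Published bout-type parameterization
#'
#' Mean and SD of the eight bout summary variables for the three bout
#' types: Type I (deep, long, mostly square dives), Type II (shallower,
#' shorter, mixed shapes) and Type III (very long surface intervals;
#' haul-out related). Also carries the dive-type mixture used when
#' bouts are expanded into full depth traces.
#'
#' @param sdScale multiplier applied to every SD column.
#' @return data.frame with one row per bout type (I, II, III).
#' @examples
#' boutTypeParams()[, c("bout_type", "surface_mean", "bout_duration_mean")]
#' @export
boutTypeParams <- function(sdScale = 1) {
  p <- data.frame(
    bout_type = c("I", "II", "III"),
    ndives_mean  = c(5.82, 5.63, 5.47),
    ndives_sd    = c(2.71, 2.35, 3.11),
    depth_mean   = c(44.73, 18.97, 18.86),
    depth_sd     = c(27.45, 11.47, 12.84),
    duration_mean = c(288.93, 165.59, 193.34),
    duration_sd  = c(84.88, 57.57, 81.54),
    surface_mean = c(45.46, 39.22, 3139.46),
    surface_sd   = c(28.25, 61.37, 2254.39),
    bout_duration_mean = c(2267.70, 1355.34, 20214.87),
    bout_duration_sd   = c(1071.29, 739.92, 12765.20),
    tad_mean = c(0.55, 0.33, 0.04),
    tad_sd   = c(0.13, 0.13, 0.03),
    square_mean = c(0.95, 0.44, 0.53),
    square_sd   = c(0.09, 0.24, 0.28),
    stringsAsFactors = FALSE
  )
  sdCols <- grep("_sd$", names(p), value = TRUE)
  p[sdCols] <- lapply(p[sdCols], function(v) v * sdScale)
  stopIfNot(all(p$square_mean >= 0 & p$square_mean <= 1),
            "square-dive fractions must lie in [0, 1]")
  stopIfNot(all(p$ndives_mean > 0), "dive counts must be positive")
  p
}

# Dive-type mixture for each bout type when expanding bouts into
# traces. Rows sum to 1; chosen to reproduce the per-bout square-dive
# fractions (0.95, 0.44, 0.53) and the depth structure (Type I built
# from the deep types 1 and 3).
boutDiveTypeProbs <- function() {
  rbind(
    I   = c(0.50, 0.00, 0.45, 0.03, 0.02, 0.00),
    II  = c(0.00, 0.25, 0.00, 0.30, 0.26, 0.19),
    III = c(0.00, 0.28, 0.00, 0.25, 0.22, 0.25)
  )
}

# Moment-matched lognormal parameters from a mean and SD.
lnormPars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

# Draw the latent parameters of one dive of a given type.
drawDiveSpec <- function(tp, minDepth = 6.5, dt = 10) {
  D  <- truncNorm(1, tp$depth_mean, tp$depth_sd, lo = minDepth)
  B  <- truncNorm(1, tp$bottom_mean, tp$bottom_sd, lo = 2 * dt)
  rd <- truncNorm(1, tp$descent_mean, tp$descent_sd, lo = 0.1)
  ra <- truncNorm(1, tp$ascent_mean, tp$ascent_sd, lo = 0.1)
  w  <- if (tp$wiggles_sd > 0 || tp$wiggles_mean > 0)
    max(0L, as.integer(round(stats::rnorm(1, tp$wiggles_mean,
                                          tp$wiggles_sd)))) else 0L
  td <- D / rd
  ta <- D / ra
  # guarantee enough submerged samples for detection (>= 7 dt total)
  B <- max(B, 7 * dt - td - ta)
  list(depth = D, bottom = B, descent = rd, ascent = ra, wiggles = w,
       td = td, ta = ta, duration = td + B + ta)
}

# Piecewise template of one dive as (time, depth) knots starting at
# relative time 0 (surface) and ending at the surface. Square dives are
# trapezoids, V dives triangles (bottom phase collapsed toward zero is
# not forced; a V dive simply has a short bottom). Wiggles are
# sin^2 oscillations in the bottom phase with amplitude large enough to
# exceed the wiggle excursion threshold yet small against max depth.
diveKnots <- function(spec, dt) {
  D <- spec$depth; B <- spec$bottom
  t0 <- 0
  t1 <- spec$td
  t2 <- t1 + B
  t3 <- t2 + spec$ta
  if (spec$wiggles > 0) {
    amp <- max(1.4, min(3, 0.15 * D))
    tt <- seq(t1, t2, by = dt / 4)
    dd <- D - amp * sin(pi * spec$wiggles * (tt - t1) / B)^2
    times <- c(t0, tt, t3)
    depthv <- c(0, dd, 0)
  } else {
    times <- c(t0, t1, t2, t3)
    depthv <- c(0, D, D, 0)
  }
  list(time = times, depth = depthv, duration = t3)
}

#' Simulate a TDR depth trace with ground truth
#'
#' Builds a regularly sampled depth trace organised into diving bouts:
#' each bout is a run of dives of one bout type, with within-bout
#' surface intervals drawn lognormally around that type's published
#' mean and long lognormal gaps between bouts. Dive profiles are
#' parametric templates (trapezoid for square dives, triangle for V
#' dives, sinusoidal bottom oscillations for wiggle dives); the
#' downstream metrics only see sampled depths, so templates provide
#' controllable ground truth. Optionally, shallow (5.2-5.9 m) isolated
#' dives are placed mid-gap between bouts, and a constant plus linear
#' transducer drift can be added for zero-offset-correction testing.
#'
#' @param nBouts number of bouts to generate (>= 1).
#' @param shapeParams dive-type parameter table from
#'   [diveTypeParams()].
#' @param boutParams bout-type parameter table from [boutTypeParams()].
#' @param boutTypeProbs mixture over bout types I/II/III; Type III
#'   bouts are rare in field data (about 1%).
#' @param diveTypeProbs 3 x 6 matrix of dive-type mixtures per bout
#'   type; rows must sum to 1.
#' @param dt sampling interval, seconds.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @param animal animal id carried into the trace.
#' @param start absolute start time of the record.
#' @param isolatedFrac target fraction of all dives that are isolated
#'   (outside any bout); isolated dives are 5.2-5.9 m so they can
#'   neither seed nor join a bout.
#' @param gapMean,gapSd between-bout gap mean and SD in seconds. The
#'   default mean is well above within-bout surface intervals so the
#'   sequential bout test has signal.
#' @param offset constant depth offset (m) added to the whole trace.
#' @param driftPerDay linear transducer drift (m per day) added to the
#'   trace.
#' @return list with elements \code{trace} (a [DepthTrace-class]),
#'   \code{truth} (data.frame, one row per generated dive: bout id and
#'   type, dive type, start/end seconds, requested depth, duration,
#'   bottom time and wiggles) and \code{bouts} (data.frame, one row per
#'   bout).
#' @examples
#' sim <- simulateTrace(nBouts = 2, seed = 1)
#' sim$trace
#' head(sim$truth)
#' @export
simulateTrace <- function(nBouts,
                          shapeParams = diveTypeParams(),
                          boutParams = boutTypeParams(),
                          boutTypeProbs = c(I = 0.60, II = 0.39, III = 0.01),
                          diveTypeProbs = boutDiveTypeProbs(),
                          dt = 10, seed = 1, animal = "S01",
                          start = as.POSIXct("2007-04-01", tz = "UTC"),
                          isolatedFrac = 0,
                          gapMean = 1800, gapSd = 900,
                          offset = 0, driftPerDay = 0) {
  stopIfNot(nBouts >= 1, "nBouts must be >= 1")
  stopIfNot(dt > 0, "dt must be positive")
  validateDiveTypeParams(shapeParams)
  stopIfNot(all(abs(rowSums(diveTypeProbs) - 1) < 1e-8),
            "dive-type mixture fractions must sum to 1")
  stopIfNot(all(diveTypeProbs >= 0 & diveTypeProbs <= 1),
            "dive-type mixture fractions must lie in [0, 1]")
  stopIfNot(isolatedFrac >= 0 && isolatedFrac < 1,
            "isolatedFrac must lie in [0, 1)")
  set.seed(seed)

  boutTypes <- sample(c("I", "II", "III"), nBouts, replace = TRUE,
                      prob = boutTypeProbs)
  gp <- lnormPars(gapMean, gapSd)

  knotT <- 0
  knotD <- 0
  cursor <- 60            # initial surface period
  truth <- list()
  boutRows <- list()
  diveId <- 0L

  addDive <- function(spec, startT, boutId, boutType, diveType) {
    k <- diveKnots(spec, dt)
    knotT <<- c(knotT, startT + k$time)
    knotD <<- c(knotD, k$depth)
    diveId <<- diveId + 1L
    truth[[diveId]] <<- data.frame(
      animal = animal, dive = diveId, bout = boutId, bout_type = boutType,
      dive_type = diveType, start_s = startT, end_s = startT + k$duration,
      max_depth = spec$depth, duration_s = k$duration,
      bottom_s = spec$bottom, wiggles = spec$wiggles,
      stringsAsFactors = FALSE)
    startT + k$duration
  }

  for (b in seq_len(nBouts)) {
    btype <- boutTypes[b]
    bp <- boutParams[boutParams$bout_type == btype, ]
    nD <- max(4L, as.integer(round(stats::rnorm(1, bp$ndives_mean,
                                                bp$ndives_sd))))
    sp <- lnormPars(bp$surface_mean, max(bp$surface_sd, 1))
    boutStart <- cursor
    for (d in seq_len(nD)) {
      dtYpe <- sample(1:6, 1, prob = diveTypeProbs[btype, ])
      spec <- drawDiveSpec(shapeParams[shapeParams$type == dtYpe, ], dt = dt)
      cursor <- addDive(spec, cursor, b, btype, dtYpe)
      if (d < nD) {
        surf <- max(2 * dt, stats::rlnorm(1, sp["meanlog"], sp["sdlog"]))
        cursor <- cursor + surf
      }
    }
    boutRows[[b]] <- data.frame(bout = b, bout_type = btype, n_dives = nD,
                                start_s = boutStart, end_s = cursor,
                                stringsAsFactors = FALSE)
    cursor <- cursor + max(4 * dt, stats::rlnorm(1, gp["meanlog"],
                                                 gp["sdlog"]))
  }

  truthDf <- do.call(rbind, truth)
  # isolated dives mid-gap: shallow enough (< 6 m) never to seed or
  # extend a bout, deep enough (> 5 m) to pass the dive filter
  if (isolatedFrac > 0) {
    nBoutDives <- nrow(truthDf)
    nIso <- round(nBoutDives * isolatedFrac / (1 - isolatedFrac))
    gapsAfter <- vapply(seq_len(nBouts), function(b) {
      endB <- boutRows[[b]]$end_s
      nxt <- if (b < nBouts) boutRows[[b + 1]]$start_s else cursor
      c(endB, nxt)
    }, numeric(2))
    isoDur <- 100   # conservative bound on isolated-dive footprint, s
    eligible <- which(gapsAfter[2, ] - gapsAfter[1, ] > 2 * isoDur + 120)
    stopIfNot(length(eligible) > 0,
              "between-bout gaps too short to host isolated dives")
    spots <- sample(rep_len(eligible, nIso))
    slot <- stats::ave(seq_along(spots), spots, FUN = seq_along)
    nSlot <- stats::ave(seq_along(spots), spots, FUN = length)
    isoRows <- list()
    for (i in seq_len(nIso)) {
      g <- spots[i]
      lo <- gapsAfter[1, g] + 60
      hi <- gapsAfter[2, g] - 60 - isoDur
      # evenly spaced slots so dives within one gap never overlap
      mid <- lo + (hi - lo) * slot[i] / (nSlot[i] + 1)
      D <- stats::runif(1, 5.2, 5.9)
      spec <- list(depth = D, bottom = 3 * dt, descent = 0.3, ascent = 0.3,
                   wiggles = 0L, td = D / 0.3, ta = D / 0.3)
      spec$duration <- spec$td + spec$bottom + spec$ta
      k <- diveKnots(spec, dt)
      knotT <- c(knotT, mid + k$time)
      knotD <- c(knotD, k$depth)
      diveId <- diveId + 1L
      isoRows[[i]] <- data.frame(
        animal = animal, dive = diveId, bout = NA_integer_,
        bout_type = NA_character_, dive_type = NA_integer_,
        start_s = mid, end_s = mid + k$duration, max_depth = spec$depth,
        duration_s = k$duration, bottom_s = spec$bottom, wiggles = 0L,
        stringsAsFactors = FALSE)
    }
    truthDf <- rbind(truthDf, do.call(rbind, isoRows))
    truthDf <- truthDf[order(truthDf$start_s), ]
    truthDf$dive <- seq_len(nrow(truthDf))
  }

  totalT <- cursor + 60
  ord <- order(knotT)
  knotT <- knotT[ord]
  knotD <- knotD[ord]
  grid <- seq(0, totalT, by = dt)
  depth <- stats::approx(knotT, knotD, xout = grid, yleft = 0,
                         yright = 0, rule = 2)$y
  depth <- pmax(depth, 0)
  drift <- offset + driftPerDay * grid / 86400
  tr <- depthTrace(depth + drift, dt = dt, animal = animal, start = start,
                   time = grid)
  rownames(truthDf) <- NULL
  list(trace = tr, truth = truthDf, bouts = do.call(rbind, boutRows))
}

#' Simulate a dive-metric table directly
#'
#' Draws per-dive classification variables from the per-type normal
#' summaries without passing through a depth trace: maximum depth,
#' duration, bottom time, wiggle count and skew are drawn (suitably
#' truncated), and the derived ratios (BTD, BTM, MDD, skew2) and rates
#' are computed so the table obeys the same internal identities as
#' [computeDiveMetrics()] output. Used for classification recovery
#' studies where the generating type of every dive must be known.
#'
#' @param n number of dives.
#' @param params dive-type parameter table from [diveTypeParams()].
#' @param typeProbs mixture over the six types (default uniform).
#' @param seed integer seed.
#' @return data.frame with one row per dive: \code{true_type}, the
#'   eight classification variables, rates, \code{is_wiggle},
#'   \code{shape} (square/V by BTD) and \code{depth_class}.
#' @examples
#' head(simulateDiveMetrics(5, seed = 1))
#' @export
simulateDiveMetrics <- function(n, params = diveTypeParams(),
                                typeProbs = rep(1 / 6, 6), seed = 1) {
  validateDiveTypeParams(params)
  set.seed(seed)
  type <- sample(params$type, n, replace = TRUE, prob = typeProbs)
  idx <- match(type, params$type)
  dur <- D <- B <- sk <- rd <- wig <- numeric(n)
  for (i in seq_len(n)) {
    p <- params[idx[i], ]
    D[i] <- truncNorm(1, p$depth_mean, p$depth_sd, lo = 5.5)
    dur[i] <- truncNorm(1, p$duration_mean, p$duration_sd, lo = 50)
    B[i] <- truncNorm(1, p$bottom_mean, p$bottom_sd,
                      lo = 0.05 * dur[i], hi = 0.95 * dur[i])
    sk[i] <- truncNorm(1, p$skew_mean, p$skew_sd, lo = 0.05)
    rd[i] <- truncNorm(1, p$descent_mean, p$descent_sd, lo = 0.1)
    wig[i] <- if (p$wiggles_sd > 0 || p$wiggles_mean > 0)
      max(0, round(stats::rnorm(1, p$wiggles_mean, p$wiggles_sd))) else 0
  }
  out <- data.frame(
    true_type = type,
    max_depth = D, duration = dur, bottom_time = B, wiggles = wig,
    skew1 = sk, skew2 = 1 / sk,
    btd = B / dur, btm = B / D, mdd = D / dur,
    descent_rate = rd, ascent_rate = sk * rd,
    is_wiggle = wig > 0,
    stringsAsFactors = FALSE)
  out$shape <- ifelse(out$btd >= 0.5, "square", "V")
  out$depth_class <- ifelse(out$max_depth >= 20, "deep", "shallow")
  out
}

#' Simulate a bout-summary table directly
#'
#' Draws the eight bout classification variables from the per-type
#' normal summaries, with counts rounded up to the four-dive minimum,
#' proportions truncated to [0, 1] and the square/V fractions forced to
#' sum to 1.
#'
#' @param n number of bouts.
#' @param params bout-type parameter table from [boutTypeParams()].
#' @param typeProbs mixture over bout types I/II/III.
#' @param seed integer seed.
#' @return data.frame with \code{true_type} and the eight bout
#'   variables.
#' @examples
#' head(simulateBoutMetrics(5, seed = 1))
#' @export
simulateBoutMetrics <- function(n, params = boutTypeParams(),
                                typeProbs = c(1, 1, 1) / 3, seed = 1) {
  set.seed(seed)
  type <- sample(params$bout_type, n, replace = TRUE, prob = typeProbs)
  idx <- match(type, params$bout_type)
  draw <- function(mcol, scol, lo = -Inf, hi = Inf) {
    vapply(seq_len(n), function(i)
      truncNorm(1, params[[mcol]][idx[i]], params[[scol]][idx[i]],
                lo = lo, hi = hi), numeric(1))
  }
  nd <- pmax(4L, as.integer(round(draw("ndives_mean", "ndives_sd"))))
  sq <- draw("square_mean", "square_sd", lo = 0, hi = 1)
  out <- data.frame(
    true_type = type,
    n_dives = nd,
    mean_depth = draw("depth_mean", "depth_sd", lo = 5.5),
    mean_duration = draw("duration_mean", "duration_sd", lo = 50),
    mean_surface_interval = draw("surface_mean", "surface_sd", lo = 10),
    bout_duration = draw("bout_duration_mean", "bout_duration_sd", lo = 200),
    pct_time_at_depth = draw("tad_mean", "tad_sd", lo = 0, hi = 1),
    pct_square = sq,
    pct_v = 1 - sq,
    stringsAsFactors = FALSE)
  out
}

#' Posterior-mean fixed-effect defaults for outcome simulation
#'
#' The published posterior means of the bout-type model's fixed effects
#' (logit scale), keyed by design-matrix column. Two interaction terms
#' of the full 16-column factorial expansion (Season:Light and the
#' four-way term) have no published posterior summary and default to
#' zero.
#'
#' @return named numeric vector of length 16 in design-column order.
#' @examples
#' fixedEffectDefaults()[1:5]
#' @export
fixedEffectDefaults <- function() {
  c("(Intercept)" = 0.811,
    "Site1" = 1.188,
    "Season1" = -1.118,
    "Light1" = -0.810,
    "Sex1" = -3.309,
    "Site1:Season1" = 1.03,
    "Site1:Light1" = -0.143,
    "Season1:Light1" = 0,
    "Site1:Sex1" = 2.15,
    "Season1:Sex1" = 0.98,
    "Light1:Sex1" = 1.272,
    "Site1:Season1:Light1" = 0.911,
    "Site1:Season1:Sex1" = -1.906,
    "Site1:Light1:Sex1" = -1.557,
    "Season1:Light1:Sex1" = -0.039,
    "Site1:Season1:Light1:Sex1" = 0)
}

#' Outcome-generation parameters
#'
#' Bundles the true coefficients and design settings for
#' [simulateOutcomes()].
#'
#' @param beta named numeric vector of true fixed effects on the logit
#'   scale, in design-column order (see [fixedEffectDefaults()]).
#' @param sigmaAlpha SD of the per-seal random effects (logit scale),
#'   >= 0.
#' @param nSeals number of seals (>= 2); site and sex are seal-level
#'   covariates assigned in alternating balanced fashion.
#' @param boutsPerSeal bouts observed per seal.
#' @param pSeason,pLight per-bout probability of the non-reference
#'   season/light level.
#' @param coding design coding, \code{"treatment"} or \code{"sum"}.
#' @return list of class \code{"outcomeParams"}.
#' @export
outcomeParams <- function(beta = fixedEffectDefaults(), sigmaAlpha = 1,
                          nSeals = 21, boutsPerSeal = 100,
                          pSeason = 0.5, pLight = 0.5,
                          coding = c("treatment", "sum")) {
  coding <- match.arg(coding)
  stopIfNot(sigmaAlpha >= 0, "sigmaAlpha must be >= 0")
  stopIfNot(nSeals >= 2, "at least two seals are required")
  stopIfNot(length(beta) == 16, "beta must have 16 entries (full design)")
  structure(list(beta = beta, sigmaAlpha = sigmaAlpha, nSeals = nSeals,
                 boutsPerSeal = boutsPerSeal, pSeason = pSeason,
                 pLight = pLight, coding = coding),
            class = "outcomeParams")
}

#' Simulate covariates and binary bout-type outcomes
#'
#' Generates a per-bout covariate table (seal id, haul-out site,
#' season, sex, light), per-seal random effects \eqn{\alpha_i \sim
#' N(0, \sigma_\alpha^2)}, and binary bout-type labels drawn
#' \eqn{y \sim Bernoulli(\mathrm{logit}^{-1}(x'\beta + \alpha_i))},
#' where the design row is built by [buildDesign()] with the full
#' factorial expansion. Label 1 codes a Type II bout, 0 a Type I bout.
#'
#' @param params an [outcomeParams()] bundle.
#' @param seed integer seed.
#' @return list with \code{data} (covariate table incl.
#'   \code{bout_type}), \code{design} (the [buildDesign()] result),
#'   \code{y} (0/1 labels), \code{alpha} (true per-seal effects),
#'   \code{beta} and \code{params}.
#' @examples
#' sim <- simulateOutcomes(outcomeParams(nSeals = 4, boutsPerSeal = 10),
#'                         seed = 1)
#' table(sim$data$bout_type)
#' @export
simulateOutcomes <- function(params = outcomeParams(), seed = 1) {
  set.seed(seed)
  nS <- params$nSeals
  sealIds <- sprintf("S%02d", seq_len(nS))
  siteLv <- c("BirdRocks", "PadillaBay")
  sexLv <- c("female", "male")
  seasonLv <- c("breeding", "nonbreeding")
  lightLv <- c("day", "night")
  sealSite <- siteLv[(seq_len(nS) - 1) %% 2 + 1]
  sealSex <- sexLv[(floor((seq_len(nS) - 1) / 2)) %% 2 + 1]
  nB <- params$boutsPerSeal
  seal <- rep(sealIds, each = nB)
  dat <- data.frame(
    seal_id = seal,
    site = rep(sealSite, each = nB),
    season = seasonLv[stats::rbinom(nS * nB, 1, params$pSeason) + 1],
    sex = rep(sealSex, each = nB),
    light = lightLv[stats::rbinom(nS * nB, 1, params$pLight) + 1],
    stringsAsFactors = FALSE)
  design <- buildDesign(dat, coding = params$coding,
                        interactions = "full", response = NULL)
  alpha <- stats::rnorm(nS, 0, params$sigmaAlpha)
  eta <- drop(design$X %*% params$beta) + alpha[design$sealIndex]
  y <- stats::rbinom(length(eta), 1, stats::plogis(eta))
  dat$bout_type <- ifelse(y == 1, "II", "I")
  design$y <- y
  design$data$bout_type <- dat$bout_type
  list(data = dat, design = design, y = y,
       alpha = stats::setNames(alpha, sealIds),
       beta = params$beta, params = params)
}
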