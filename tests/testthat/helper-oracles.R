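# Independent oracle implementations used to validate the package's
# algorithms. These deliberately share no code with the package: plain
# per-sample loops and library distribution functions only.

# quadratic brute-force dive scan: for every sample, walk outward to
# find its maximal submerged run, then collect unique qualifying runs
oracleDetectDives <- function(depth, surfaceThreshold = 2, minDepth = 5,
                              minSamples = 5) {
  n <- length(depth)
  runs <- list()
  for (i in seq_len(n)) {
    if (depth[i] <= surfaceThreshold) next
    s <- i
    while (s > 1 && depth[s - 1] > surfaceThreshold) s <- s - 1
    e <- i
    while (e < n && depth[e + 1] > surfaceThreshold) e <- e + 1
    runs[[paste(s, e)]] <- c(s, e)
  }
  out <- do.call(rbind, unname(runs))
  if (is.null(out)) return(data.frame(start = integer(), end = integer()))
  out <- out[order(out[, 1]), , drop = FALSE]
  keep <- logical(nrow(out))
  for (r in seq_len(nrow(out))) {
    seg <- depth[out[r, 1]:out[r, 2]]
    keep[r] <- max(seg) > minDepth && length(seg) >= minSamples
  }
  data.frame(start = out[keep, 1], end = out[keep, 2])
}

# per-sample oracle for the dive metrics, written as explicit loops
oracleMetrics <- function(depth, dt, bottomFraction = 0.85, excursion = 1) {
  n <- length(depth)
  maxd <- -Inf
  for (v in depth) if (v > maxd) maxd <- v
  thr <- bottomFraction * maxd
  bot <- c()
  for (i in seq_len(n)) if (depth[i] >= thr) bot <- c(bot, i)
  b1 <- bot[1]; b2 <- bot[length(bot)]
  descT <- (b1 - 1) * dt; if (descT == 0) descT <- dt
  ascT <- (n - b2) * dt; if (ascT == 0) ascT <- dt
  # wiggles: scan the bottom span for shallowing reversals deeper than
  # `excursion` on both flanks
  seg <- depth[b1:b2]
  seg <- seg[c(TRUE, diff(seg) != 0)]
  w <- 0L
  if (length(seg) >= 3) {
    for (i in 2:(length(seg) - 1)) {
      if (seg[i] < seg[i - 1] && seg[i] < seg[i + 1]) {
        # walk each flank to the adjacent local maximum
        j <- i - 1
        while (j > 1 && seg[j - 1] > seg[j]) j <- j - 1
        k <- i + 1
        while (k < length(seg) && seg[k + 1] > seg[k]) k <- k + 1
        if (seg[j] - seg[i] > excursion && seg[k] - seg[i] > excursion)
          w <- w + 1L
      }
    }
  }
  list(max_depth = maxd, duration = n * dt,
       bottom_time = length(bot) * dt, wiggles = w,
       descent_rate = depth[b1] / descT, ascent_rate = depth[b2] / ascT,
       skew1 = (depth[b2] / ascT) / (depth[b1] / descT),
       btd = length(bot) * dt / (n * dt),
       btm = length(bot) * dt / maxd, mdd = maxd / (n * dt))
}

# from-scratch sequential bout partition, recomputing the one-sided
# prediction-form t-test with pt() at every step
oracleBouts <- function(startS, endS, maxDepth, minDives = 4,
                        minDepth = 6, alpha = 0.05) {
  n <- length(startS)
  assignment <- rep(NA_integer_, n)
  if (n >= minDives) {
    gap <- function(i) startS[i + 1] - endS[i]  # interval after dive i
    b <- 0L
    i <- 1L
    while (i <= n - minDives + 1L) {
      ok <- TRUE
      for (d in i:(i + minDives - 1L)) if (maxDepth[d] < minDepth) ok <- FALSE
      if (!ok) { i <- i + 1L; next }
      members <- i:(i + minDives - 1L)
      j <- i + minDives - 1L
      while (j < n) {
        hist <- vapply(members[-length(members)], gap, numeric(1))
        x <- gap(j)
        m <- sum(hist) / length(hist)
        s <- sqrt(sum((hist - m)^2) / (length(hist) - 1))
        if (s == 0) {
          sig <- x > m
        } else {
          tt <- (x - m) / (s * sqrt(1 + 1 / length(hist)))
          sig <- stats::pt(tt, df = length(hist) - 1,
                           lower.tail = FALSE) < alpha
        }
        if (sig) break
        members <- c(members, j + 1L)
        j <- j + 1L
      }
      b <- b + 1L
      assignment[members] <- b
      i <- j + 1L
    }
  }
  assignment
}

# adjusted Rand index from a contingency table
ariIndex <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  e <- b * cc / nn
  (a - e) / ((b + cc) / 2 - e)
}

# adaptive-quadrature posterior oracle for the intercept-only binomial
# model with a Normal(mu, sd^2) prior: returns mean and quantiles
oracleInterceptPosterior <- function(successes, trials, priorMean = 0,
                                     priorSD = 10,
                                     probs = c(0.025, 0.975)) {
  post <- function(b) vapply(b, function(bb)
    exp(successes * stats::plogis(bb, log.p = TRUE) +
        (trials - successes) * stats::plogis(-bb, log.p = TRUE) +
        stats::dnorm(bb, priorMean, priorSD, log = TRUE)), numeric(1))
  Z <- stats::integrate(post, -30, 30, rel.tol = 1e-12)$value
  m <- stats::integrate(function(b) b * post(b) / Z, -30, 30,
                        rel.tol = 1e-12)$value
  cdf <- function(q) stats::integrate(post, -30, q,
                                      rel.tol = 1e-12)$value / Z
  qs <- vapply(probs, function(p)
    stats::uniroot(function(q) cdf(q) - p, c(-10, 10),
                   tol = 1e-10)$root, numeric(1))
  list(mean = m, quantiles = stats::setNames(qs, probs))
}

# random dive sequences with engineered ties and boundary cases for
# bout-partition equivalence testing
randomDiveSequence <- function(n, seed) {
  set.seed(seed)
  # integer-valued intervals from a small support force zero-variance
  # histories and exact x == mean boundary hits
  intervals <- sample(c(30, 30, 30, 60, 90, 600, 3000), n - 1,
                      replace = TRUE)
  durations <- sample(c(50, 100, 150), n, replace = TRUE)
  startS <- cumsum(c(0, intervals + durations[-n]))
  depth <- sample(c(4, 5.5, 8, 15, 40), n, replace = TRUE)
  data.frame(start_s = startS, end_s = startS + durations,
             max_depth = depth)
}
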