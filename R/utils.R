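# Internal numeric helpers shared across modules.

# Rolling lower-percentile baseline. Evaluated exactly on a coarse grid
# (every `stride` samples) and linearly interpolated between grid
# points; surface drift is slow relative to the window so interpolation
# error is negligible against the 0.5 m transducer resolution.
rollingQuantile <- function(x, width, prob = 0.05, stride = NULL) {
  n <- length(x)
  half <- max(1L, floor(width / 2))
  if (is.null(stride)) stride <- max(1L, floor(width / 10))
  at <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(at, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(at) == 1L) return(rep(q, n))
  stats::approx(at, q, xout = seq_len(n), rule = 2)$y
}

# Count wiggles: interior local depth minima (shallowing reversals)
# whose rise to the preceding local maximum and fall to the following
# local maximum both exceed `excursion` metres. Plateaus are collapsed
# before extremum detection.
countWiggles <- function(depth, excursion = 1) {
  keep <- c(TRUE, diff(depth) != 0)
  d <- depth[keep]
  m <- length(d)
  if (m < 3L) return(0L)
  dd <- diff(d)
  # turning points: sign change of successive differences
  turns <- which(dd[-1] * dd[-(m - 1L)] < 0) + 1L
  if (!length(turns)) return(0L)
  isMin <- dd[turns] > 0  # depth fell into the point, rises after it
  extrema <- c(1L, turns, m)
  count <- 0L
  for (j in seq_along(turns)) {
    if (!isMin[j]) next
    pos <- which(extrema == turns[j])[1]
    prevMax <- d[extrema[pos - 1L]]
    nextMax <- d[extrema[pos + 1L]]
    if ((prevMax - d[turns[j]]) > excursion &&
        (nextMax - d[turns[j]]) > excursion)
      count <- count + 1L
  }
  count
}

# FNV-1a 32-bit hash of a character scalar, as hex. Used for config
# fingerprints in run manifests; not cryptographic. Arithmetic is done
# on 16-bit halves because R's bitwXor only covers 32-bit signed
# integers and doubles lose exactness past 2^53.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- bitwXor(hi, b %/% 65536) * 65536 + bitwXor(lo, b %% 65536)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Split-half potential scale reduction factor from a single chain.
splitRhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4L) return(NA_real_)
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + n]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- n * stats::var(c(mean(a), mean(b)))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size by Geyer's initial positive sequence on the
# autocorrelation function of one chain.
effectiveSize <- function(x) {
  n <- length(x)
  if (n < 8L || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
  pair <- rho[seq(1, length(rho) - 1, by = 2)] +
    rho[seq(2, length(rho), by = 2)]
  stop_at <- which(pair <= 0)[1]
  if (!is.na(stop_at)) pair <- pair[seq_len(stop_at - 1L)]
  ess <- n / (1 + 2 * sum(pmax(pair, 0)))
  min(ess, n)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
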