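#' DepthTrace: a regularly sampled depth record
#'
#' Container for one animal's time-depth recorder (TDR) record sampled
#' at a fixed interval. Depth is in metres, positive downward; time is
#' elapsed seconds from the record start. An optional absolute start
#' time anchors dives to calendar dates for season/light assignment.
#'
#' @slot time numeric, elapsed seconds, strictly increasing at a
#'   constant step \code{dt}.
#' @slot depth numeric, depth in metres (positive down), finite.
#' @slot dt numeric(1), sampling interval in seconds.
#' @slot animal character(1), animal identifier.
#' @slot start POSIXct(1), absolute time of the first sample.
#'
#' @seealso [depthTrace()], [zeroOffsetCorrect()], [detectDives()]
#' @export
setClass("DepthTrace",
  representation(
    time   = "numeric",
    depth  = "numeric",
    dt     = "numeric",
    animal = "character",
    start  = "POSIXct"
  )
)

setValidity("DepthTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 2L) msg <- c(msg, "trace must have at least 2 samples")
  if (length(object@depth) != n)
    msg <- c(msg, "time and depth must have equal length")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (any(!is.finite(object@depth)))
    msg <- c(msg, "depths must be finite")
  if (n >= 2L) {
    steps <- diff(object@time)
    if (any(steps <= 0) || max(abs(steps - object@dt)) > 1e-6 * object@dt)
      msg <- c(msg, "time must increase strictly at constant step dt")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DepthTrace
#'
#' @param depth numeric vector of depths (m, positive down).
#' @param dt sampling interval in seconds.
#' @param animal animal identifier.
#' @param start absolute time of the first sample (POSIXct); defaults
#'   to 2007-04-01 00:00 UTC, an arbitrary spring anchor.
#' @param time optional elapsed-seconds vector; defaults to
#'   \code{(0:(n-1)) * dt}.
#' @return A [DepthTrace-class] object.
#' @examples
#' tr <- depthTrace(c(0, 3, 10, 10, 3, 0), dt = 10)
#' samplingInterval(tr)
#' @export
depthTrace <- function(depth, dt = 10, animal = "A1",
                       start = as.POSIXct("2007-04-01", tz = "UTC"),
                       time = NULL) {
  if (is.null(time)) time <- (seq_along(depth) - 1) * dt
  new("DepthTrace", time = as.numeric(time), depth = as.numeric(depth),
      dt = as.numeric(dt), animal = as.character(animal),
      start = as.POSIXct(start, tz = "UTC"))
}

setMethod("show", "DepthTrace", function(object) {
  cat("DepthTrace for animal", object@animal, "\n")
  cat(sprintf("  %d samples at dt = %g s (%.2f h)\n",
              length(object@depth), object@dt,
              length(object@depth) * object@dt / 3600))
  cat(sprintf("  depth range: %.1f - %.1f m; start %s\n",
              min(object@depth), max(object@depth),
              format(object@start, "%Y-%m-%d %H:%M:%S %Z")))
})

#' ClusterSolution: a fitted classification bundle
#'
#' Result of standardisation + PCA + k-means for one cluster count k,
#' with (optionally) discriminant-validation accuracy attached. The
#' bundle stores everything needed to reproduce factor scores and
#' labels: per-variable centring/scaling, PCA loadings, the retained
#' component count, centroids in score space, and per-observation
#' labels.
#'
#' @slot k integer(1), number of clusters.
#' @slot variables character, numeric variables used.
#' @slot center,scale numeric, per-variable standardisation parameters.
#' @slot loadings matrix, PCA rotation (variables x components).
#' @slot nComponents integer(1), retained components (cumulative
#'   explained variance >= the variance target).
#' @slot varianceExplained numeric, per-component proportion of
#'   variance.
#' @slot centroids matrix, cluster centres in clustering space (PC
#'   scores plus any scaled categorical passthrough columns).
#' @slot labels integer, per-observation cluster labels in 1..k.
#' @slot accuracy numeric(1), discriminant validation accuracy in
#'   percent (NA before validation).
#' @slot passthrough character, names of categorical passthrough
#'   columns appended to the PC scores.
#' @slot meta list, free-form metadata (seed, restarts, inertia).
#' @export
setClass("ClusterSolution",
  representation(
    k = "integer",
    variables = "character",
    center = "numeric",
    scale = "numeric",
    loadings = "matrix",
    nComponents = "integer",
    varianceExplained = "numeric",
    centroids = "matrix",
    labels = "integer",
    accuracy = "numeric",
    passthrough = "character",
    meta = "list"
  )
)

setValidity("ClusterSolution", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (!is.na(object@accuracy) &&
      (object@accuracy < 0 || object@accuracy > 100))
    msg <- c(msg, "accuracy must lie in [0, 100]")
  if (length(object@varianceExplained) &&
      object@nComponents >= 1L) {
    cum <- cumsum(object@varianceExplained)
    tgt <- object@meta$varianceTarget
    if (!is.null(tgt) && cum[object@nComponents] < tgt - 1e-8)
      msg <- c(msg, "retained components fall short of variance target")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: k = %d over %d variables\n",
              object@k, length(object@variables)))
  cat(sprintf("  %d PCs retained (%.1f%% variance)%s\n",
              object@nComponents,
              100 * sum(object@varianceExplained[seq_len(object@nComponents)]),
              if (length(object@passthrough))
                paste0(" + passthrough: ",
                       paste(object@passthrough, collapse = ", "))
              else ""))
  cat(sprintf("  accuracy: %s; n = %d\n",
              if (is.na(object@accuracy)) "unvalidated"
              else sprintf("%.1f%%", object@accuracy),
              length(object@labels)))
})

#' PosteriorSample: MCMC draws from the bout-type model
#'
#' Retained (post burn-in, thinned) draws from the
#' Metropolis-within-Gibbs sampler for the binomial mixed model, with
#' acceptance rates and per-parameter summaries.
#'
#' @slot draws matrix, retained draws; columns are the fixed effects,
#'   the per-animal random effects, then \code{sigma_alpha}.
#' @slot parameters character, column names of \code{draws}.
#' @slot nFixed integer(1), number of fixed-effect columns.
#' @slot animals character, animal ids for the random-effect columns.
#' @slot acceptance numeric, per-parameter acceptance rates in [0, 1].
#' @slot spec list, the sampler settings used (iterations, burn-in,
#'   thinning, priors, seed, mode).
#' @export
setClass("PosteriorSample",
  representation(
    draws = "matrix",
    parameters = "character",
    nFixed = "integer",
    animals = "character",
    acceptance = "numeric",
    spec = "list"
  )
)

setValidity("PosteriorSample", function(object) {
  msg <- character()
  if (ncol(object@draws) != length(object@parameters))
    msg <- c(msg, "parameter names must match draw columns")
  if (any(object@acceptance < 0 | object@acceptance > 1))
    msg <- c(msg, "acceptance rates must lie in [0, 1]")
  if (object@nFixed < 1L || object@nFixed > ncol(object@draws))
    msg <- c(msg, "nFixed out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf("PosteriorSample: %d draws x %d parameters\n",
              nrow(object@draws), ncol(object@draws)))
  cat(sprintf("  %d fixed effects, %d random effects, sigma_alpha (%s mode)\n",
              object@nFixed, length(object@animals),
              if (isTRUE(object@spec$hierarchical)) "hierarchical" else "flat"))
  cat(sprintf("  mean acceptance: %.2f\n", mean(object@acceptance)))
})

# ---- accessor generics -------------------------------------------------

#' Accessors for diveBout S4 classes
#'
#' @param object a [DepthTrace-class], [ClusterSolution-class] or
#'   [PosteriorSample-class] object.
#' @return The requested component: numeric vectors for
#'   \code{depths}/\code{elapsedTime}, scalars for
#'   \code{samplingInterval}/\code{animalId}/\code{startTime}, a matrix
#'   for \code{posteriorDraws}, integers for \code{clusterLabels}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("elapsedTime", function(object) standardGeneric("elapsedTime"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("animalId", function(object) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname accessors
setMethod("depths", "DepthTrace", function(object) object@depth)
#' @rdname accessors
setMethod("elapsedTime", "DepthTrace", function(object) object@time)
#' @rdname accessors
setMethod("samplingInterval", "DepthTrace", function(object) object@dt)
#' @rdname accessors
setMethod("animalId", "DepthTrace", function(object) object@animal)
#' @rdname accessors
setMethod("startTime", "DepthTrace", function(object) object@start)
#' @rdname accessors
setMethod("clusterLabels", "ClusterSolution", function(object) object@labels)
#' @rdname accessors
setMethod("posteriorDraws", "PosteriorSample", function(object) object@draws)
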