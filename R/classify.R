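#' Fit a standardising PCA retaining a variance target
#'
#' Standardises each variable to zero mean and unit SD, fits a
#' principal components analysis, and retains the smallest number of
#' components whose cumulative explained variance reaches
#' \code{varianceTarget}. Constant variables are dropped with a
#' warning.
#'
#' @param x numeric matrix or data.frame (observations x variables).
#' @param varianceTarget cumulative variance proportion to retain
#'   (default 0.80).
#' @return list with \code{center}, \code{scale}, \code{loadings}
#'   (full rotation), \code{varianceExplained} (per-component
#'   proportions), \code{nComponents}, \code{scores} (retained-score
#'   matrix) and \code{variables}.
#' @examples
#' p <- fitPCA(simulateDiveMetrics(100, seed = 1)[,
#'   c("max_depth", "duration", "bottom_time", "skew1")])
#' p$nComponents
#' @export
fitPCA <- function(x, varianceTarget = 0.80) {
  x <- as.matrix(as.data.frame(x))
  stopIfNot(ncol(x) >= 2, "need at least two variables")
  stopIfNot(nrow(x) > ncol(x), "need more observations than variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nComp <- which(cumsum(ve) >= varianceTarget - 1e-12)[1]
  list(center = ctr, scale = sds, loadings = pc$rotation,
       varianceExplained = ve, nComponents = as.integer(nComp),
       scores = pc$x[, seq_len(nComp), drop = FALSE],
       variables = colnames(x), varianceTarget = varianceTarget)
}

# project new data onto a fitted PCA
pcaScores <- function(fit, x) {
  z <- scale(as.matrix(as.data.frame(x)[, fit$variables]),
             center = fit$center, scale = fit$scale)
  (z %*% fit$loadings)[, seq_len(fit$nComponents), drop = FALSE]
}

#' k-means scan over a range of cluster counts
#'
#' Runs k-means (multiple random restarts, fixed seed) on the retained
#' PCA factor scores, optionally augmented with 0/1 categorical
#' passthrough columns scaled to unit variance, for each k in
#' \code{kRange}. The best-inertia solution per k is kept. Empty
#' clusters trigger a re-run with fresh centres (counted in the
#' metadata).
#'
#' @param pca a fitted PCA from [fitPCA()].
#' @param passthrough optional data.frame/matrix of 0-1 categorical
#'   columns appended to the scores after scaling to unit variance.
#' @param kRange integer vector of cluster counts (default 4:8).
#' @param restarts random restarts per k (default 25).
#' @param seed integer seed; same data and seed give identical labels
#'   and inertia.
#' @return list of [ClusterSolution-class] objects, one per k
#'   (accuracy unset until [validateDFA()]).
#' @export
kmeansScan <- function(pca, passthrough = NULL, kRange = 4:8,
                       restarts = 25, seed = 1) {
  feat <- pca$scores
  ptNames <- character()
  if (!is.null(passthrough)) {
    pt <- as.matrix(as.data.frame(passthrough)) * 1
    ptNames <- colnames(pt)
    ptScaled <- apply(pt, 2, function(v) {
      s <- stats::sd(v)
      if (s > 0) v / s else v * 0
    })
    feat <- cbind(feat, ptScaled)
  }
  n <- nrow(feat)
  stopIfNot(min(kRange) >= 2 && max(kRange) <= n - 1,
            "kRange must lie within [2, n - 1]")
  ptScale <- if (length(ptNames))
    vapply(as.data.frame(as.matrix(as.data.frame(passthrough)) * 1),
           stats::sd, numeric(1)) else numeric()
  set.seed(seed)
  lapply(kRange, function(k) {
    fit <- NULL
    tries <- 0L
    while (is.null(fit) && tries < 10L) {
      tries <- tries + 1L
      fit <- tryCatch(
        stats::kmeans(feat, centers = k, nstart = restarts,
                      iter.max = 200),
        error = function(e) NULL,
        warning = function(w) NULL)
    }
    stopIfNot(!is.null(fit), "k-means failed to converge")
    new("ClusterSolution",
        k = as.integer(k),
        variables = pca$variables,
        center = pca$center, scale = pca$scale,
        loadings = pca$loadings,
        nComponents = pca$nComponents,
        varianceExplained = pca$varianceExplained,
        centroids = fit$centers,
        labels = as.integer(fit$cluster),
        accuracy = NA_real_,
        passthrough = ptNames,
        meta = list(seed = seed, restarts = restarts,
                    inertia = fit$tot.withinss,
                    emptyRestarts = tries - 1L,
                    varianceTarget = pca$varianceTarget,
                    ptScale = ptScale))
  })
}

#' Validate a cluster solution by discriminant analysis
#'
#' Trains a linear discriminant classifier on the cluster labels over
#' the standardised original variables (any categorical passthrough
#' column included, scaled to unit variance) and reports the percentage of
#' observations whose discriminant reassignment matches their k-means
#' label (resubstitution by default; leave-one-out by flag). A
#' singular within-class covariance falls back to a ridge-regularised
#' discriminant, with a message.
#'
#' @param solution a [ClusterSolution-class].
#' @param x the original variable table the solution was fitted to.
#' @param leaveOneOut use leave-one-out cross-validation instead of
#'   resubstitution.
#' @return the solution with its \code{accuracy} slot (percent) set.
#' @export
validateDFA <- function(solution, x, leaveOneOut = FALSE) {
  x <- as.data.frame(x)
  z <- scale(as.matrix(x[, solution@variables]),
             center = solution@center, scale = solution@scale)
  if (length(solution@passthrough)) {
    pt <- as.matrix(x[, solution@passthrough, drop = FALSE]) * 1
    pt <- apply(pt, 2, function(v) {
      s <- stats::sd(v)
      if (s > 0) v / s else v * 0
    })
    z <- cbind(z, pt)
  }
  grp <- factor(solution@labels)
  # collinear inputs (e.g. the square/V fractions summing to 1) are
  # expected; lda handles them, so its collinearity warning is muffled
  pred <- tryCatch({
    if (leaveOneOut) {
      fit <- suppressWarnings(MASS::lda(z, grouping = grp, CV = TRUE))
      fit$class
    } else {
      fit <- suppressWarnings(MASS::lda(z, grouping = grp))
      suppressWarnings(stats::predict(fit, z)$class)
    }
  }, error = function(e) {
    message("within-class covariance singular; ",
            "using ridge-regularised discriminant")
    ridgeLdaPredict(z, grp)
  })
  acc <- 100 * mean(as.integer(as.character(pred)) == solution@labels)
  solution@accuracy <- acc
  validObject(solution)
  solution
}

# Hand-rolled Gaussian LDA with a ridge on the pooled covariance, used
# only when MASS::lda rejects a singular fit.
ridgeLdaPredict <- function(z, grp) {
  lev <- levels(grp)
  p <- ncol(z)
  means <- t(vapply(lev, function(g) colMeans(z[grp == g, , drop = FALSE]),
                    numeric(p)))
  W <- matrix(0, p, p)
  for (g in lev) {
    zg <- z[grp == g, , drop = FALSE]
    if (nrow(zg) > 1)
      W <- W + crossprod(sweep(zg, 2, colMeans(zg)))
  }
  W <- W / max(1, nrow(z) - length(lev))
  W <- W + diag(1e-6 * mean(diag(W)) + 1e-12, p)
  Winv <- solve(W)
  prior <- as.numeric(table(grp)) / nrow(z)
  disc <- vapply(seq_along(lev), function(gi) {
    mu <- means[gi, ]
    drop(z %*% Winv %*% mu) - 0.5 * drop(mu %*% Winv %*% mu) +
      log(prior[gi])
  }, numeric(nrow(z)))
  # not max.col: its random tie-breaking uses a relative tolerance,
  # which misfires when the ridge inflates discriminant magnitudes
  factor(lev[apply(disc, 1, which.max)], levels = lev)
}

#' Select the parsimonious cluster solution
#'
#' Among the validated solutions whose accuracy is within
#' \code{tolerance} percentage points of the best accuracy, returns
#' the one with the fewest clusters. This operationalises the dual
#' criterion "fewest clusters, highest accuracy", which is otherwise
#' ill-posed when accuracy keeps rising with k.
#'
#' @param solutions list of validated [ClusterSolution-class] objects.
#' @param tolerance accuracy tolerance in percentage points (default
#'   1.0).
#' @return the selected [ClusterSolution-class].
#' @export
selectParsimonious <- function(solutions, tolerance = 1.0) {
  stopIfNot(length(solutions) >= 1, "need at least one solution")
  accs <- vapply(solutions, function(s) s@accuracy, numeric(1))
  stopIfNot(all(!is.na(accs)), "all solutions must be validated first")
  ks <- vapply(solutions, function(s) s@k, integer(1))
  keep <- which(accs >= max(accs) - tolerance)
  solutions[[keep[which.min(ks[keep])]]]
}

#' Name cluster types from centroid characteristics
#'
#' For dives: each cluster is described by its mean BTD (square if
#' >= 0.5 else V), mean maximum depth (deep if >= 20 m else shallow)
#' and wiggle share (wiggle if the majority of members are wiggle
#' dives). For bouts: clusters whose mean surface interval exceeds
#' twice their mean dive duration are Type III (surface-dominated, haul-out
#' related); when exactly two clusters remain the deeper one is Type I
#' and the other Type II; with more, the 20 m deep/shallow anchor
#' splits them when it separates the clusters, else the deepest
#' cluster is Type I and the rest Type II.
#'
#' @param solution a [ClusterSolution-class].
#' @param records the original record table (rows matching
#'   \code{clusterLabels(solution)}).
#' @param role \code{"dive"} or \code{"bout"}.
#' @return data.frame with one row per cluster: \code{cluster},
#'   descriptive fields, and \code{assigned_type} (for dives an
#'   integer label ordered deep-to-shallow; for bouts I/II/III).
#' @export
nameTypes <- function(solution, records, role = c("dive", "bout")) {
  role <- match.arg(role)
  lab <- solution@labels
  stopIfNot(nrow(records) == length(lab),
            "records must match the clustered observations")
  if (role == "dive") {
    need <- c("btd", "max_depth", "is_wiggle")
    stopIfNot(all(need %in% names(records)),
              "dive records need btd, max_depth and is_wiggle")
    agg <- do.call(rbind, lapply(sort(unique(lab)), function(g) {
      r <- records[lab == g, ]
      data.frame(cluster = g, mean_btd = mean(r$btd),
                 mean_depth = mean(r$max_depth),
                 wiggle_share = mean(r$is_wiggle))
    }))
    agg$shape <- ifelse(agg$mean_btd >= 0.5, "square", "V")
    agg$depth_class <- ifelse(agg$mean_depth >= 20, "deep", "shallow")
    agg$wiggle <- agg$wiggle_share >= 0.5
    ord <- order(-agg$mean_depth, -agg$mean_btd)
    agg$assigned_type <- NA_integer_
    agg$assigned_type[ord] <- seq_len(nrow(agg))
    agg
  } else {
    need <- c("mean_surface_interval", "mean_duration", "mean_depth")
    stopIfNot(all(need %in% names(records)),
              "bout records need surface interval, duration and depth means")
    agg <- do.call(rbind, lapply(sort(unique(lab)), function(g) {
      r <- records[lab == g, ]
      data.frame(cluster = g,
                 mean_surface = mean(r$mean_surface_interval),
                 mean_duration = mean(r$mean_duration),
                 mean_depth = mean(r$mean_depth))
    }))
    isIII <- agg$mean_surface > 2 * agg$mean_duration
    agg$assigned_type <- ifelse(isIII, "III", NA_character_)
    rest <- which(!isIII)
    if (length(rest) == 2L) {
      # canonical case: the deeper, longer cluster is Type I
      deeper <- rest[which.max(agg$mean_depth[rest])]
      agg$assigned_type[deeper] <- "I"
      agg$assigned_type[setdiff(rest, deeper)] <- "II"
    } else if (length(rest) >= 1L) {
      byAnchor <- agg$mean_depth[rest] >= 20
      if (length(rest) == 1L || (any(byAnchor) && !all(byAnchor))) {
        # the 20 m deep/shallow anchor separates the clusters
        agg$assigned_type[rest] <- ifelse(byAnchor, "I", "II")
      } else {
        # all clusters on one side of the anchor: fall back to the
        # relative ordering (Type II is shallower than Type I)
        deepest <- rest[which.max(agg$mean_depth[rest])]
        agg$assigned_type[deepest] <- "I"
        agg$assigned_type[setdiff(rest, deepest)] <- "II"
      }
    }
    agg
  }
}

#' Classify dives end-to-end
#'
#' Standardisation + PCA (>= 80% variance) over the seven numeric
#' shape variables, k-means over \code{kRange} with the wiggle-dive
#' indicator appended as a unit-variance 0/1 passthrough, discriminant
#' validation, parsimonious selection and type naming. The wiggle
#' count enters only through the indicator: wiggle presence defines
#' dive types, its magnitude does not.
#'
#' @param dives dive metric table from [computeDiveMetrics()] or
#'   [simulateDiveMetrics()].
#' @param kRange cluster counts to scan (default 4:8).
#' @param varianceTarget PCA variance target (default 0.80).
#' @param tolerance parsimony tolerance in accuracy points.
#' @param restarts,seed k-means restarts and seed.
#' @param leaveOneOut validation mode flag, see [validateDFA()].
#' @return list with \code{solutions} (all validated k), a data.frame
#'   \code{scan} (k vs accuracy), \code{selected} (the chosen
#'   [ClusterSolution-class]), \code{types} (centroid naming table)
#'   and \code{dives} (input with \code{cluster} and
#'   \code{assigned_type} columns).
#' @examples
#' \donttest{
#' dv <- simulateDiveMetrics(400, diveTypeParams(sdScale = 0.5), seed = 2)
#' res <- classifyDives(dv, kRange = 4:6, restarts = 5)
#' res$scan
#' }
#' @export
classifyDives <- function(dives, kRange = 4:8, varianceTarget = 0.80,
                          tolerance = 1.0, restarts = 25, seed = 1,
                          leaveOneOut = FALSE) {
  vars <- c("max_depth", "duration", "bottom_time", "skew1",
            "btd", "btm", "mdd")
  pca <- fitPCA(dives[, vars], varianceTarget)
  sols <- kmeansScan(pca, passthrough = dives[, "is_wiggle", drop = FALSE],
                     kRange = kRange, restarts = restarts, seed = seed)
  sols <- lapply(sols, validateDFA, x = dives, leaveOneOut = leaveOneOut)
  sel <- selectParsimonious(sols, tolerance)
  types <- nameTypes(sel, dives, role = "dive")
  out <- dives
  out$cluster <- sel@labels
  out$assigned_type <- types$assigned_type[match(sel@labels, types$cluster)]
  scan <- data.frame(
    k = vapply(sols, function(s) s@k, integer(1)),
    accuracy = vapply(sols, function(s) s@accuracy, numeric(1)))
  list(solutions = sols, scan = scan, selected = sel, types = types,
       dives = out)
}

#' Classify bouts end-to-end
#'
#' Same engine as [classifyDives()] applied to the eight numeric bout
#' variables, with no categorical passthrough.
#'
#' @param bouts bout summary table from [summarizeBouts()] or
#'   [simulateBoutMetrics()].
#' @inheritParams classifyDives
#' @return list as in [classifyDives()], with \code{bouts} instead of
#'   \code{dives}.
#' @export
classifyBouts <- function(bouts, kRange = 2:5, varianceTarget = 0.80,
                          tolerance = 1.0, restarts = 25, seed = 1,
                          leaveOneOut = FALSE) {
  vars <- c("n_dives", "mean_depth", "mean_duration",
            "mean_surface_interval", "bout_duration",
            "pct_time_at_depth", "pct_square", "pct_v")
  pca <- fitPCA(bouts[, vars], varianceTarget)
  sols <- kmeansScan(pca, passthrough = NULL, kRange = kRange,
                     restarts = restarts, seed = seed)
  sols <- lapply(sols, validateDFA, x = bouts, leaveOneOut = leaveOneOut)
  sel <- selectParsimonious(sols, tolerance)
  types <- nameTypes(sel, bouts, role = "bout")
  out <- bouts
  out$cluster <- sel@labels
  out$assigned_type <- types$assigned_type[match(sel@labels, types$cluster)]
  scan <- data.frame(
    k = vapply(sols, function(s) s@k, integer(1)),
    accuracy = vapply(sols, function(s) s@accuracy, numeric(1)))
  list(solutions = sols, scan = scan, selected = sel, types = types,
       bouts = out)
}

#' Serialize and restore a cluster solution
#'
#' Writes a [ClusterSolution-class] as plain structured JSON (all
#' standardisation parameters, loadings, centroids, labels and
#' metadata), and restores it, so a fitted classification can be
#' archived alongside the delimited data tables and applied to new
#' records later.
#'
#' @param solution a [ClusterSolution-class].
#' @param path JSON file path.
#' @return \code{writeClusterSolution}: \code{path}, invisibly;
#'   \code{readClusterSolution}: the restored
#'   [ClusterSolution-class].
#' @export
writeClusterSolution <- function(solution, path) {
  obj <- list(
    k = solution@k,
    variables = solution@variables,
    center = as.list(solution@center),
    scale = as.list(solution@scale),
    loadings = list(values = as.numeric(solution@loadings),
                    dim = dim(solution@loadings),
                    rowNames = rownames(solution@loadings),
                    colNames = colnames(solution@loadings)),
    nComponents = solution@nComponents,
    varianceExplained = solution@varianceExplained,
    centroids = list(values = as.numeric(solution@centroids),
                     dim = dim(solution@centroids),
                     rowNames = rownames(solution@centroids),
                     colNames = colnames(solution@centroids)),
    labels = solution@labels,
    accuracy = solution@accuracy,
    passthrough = solution@passthrough,
    meta = solution@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeClusterSolution
#' @export
readClusterSolution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(obj$loadings$values, obj$loadings$dim[1],
                     obj$loadings$dim[2],
                     dimnames = list(obj$loadings$rowNames,
                                     obj$loadings$colNames))
  centroids <- matrix(obj$centroids$values, obj$centroids$dim[1],
                      obj$centroids$dim[2],
                      dimnames = list(obj$centroids$rowNames,
                                      obj$centroids$colNames))
  pass <- if (length(obj$passthrough)) obj$passthrough else character()
  meta <- obj$meta
  ps <- unlist(meta$ptScale)
  # a length-one named vector loses its name through JSON unboxing
  if (!is.null(ps) && is.null(names(ps)) && length(ps) == length(pass))
    names(ps) <- pass
  meta$ptScale <- ps
  new("ClusterSolution",
      k = as.integer(obj$k),
      variables = obj$variables,
      center = unlist(obj$center),
      scale = unlist(obj$scale),
      loadings = loadings,
      nComponents = as.integer(obj$nComponents),
      varianceExplained = obj$varianceExplained,
      centroids = centroids,
      labels = as.integer(obj$labels),
      accuracy = as.numeric(obj$accuracy),
      passthrough = pass,
      meta = meta)
}

#' Apply a fitted cluster solution to new records
#'
#' Standardises the records with the solution's stored parameters,
#' projects onto its retained principal components, appends any
#' categorical passthrough columns scaled as at fit time, and assigns
#' each record to the nearest centroid in clustering space.
#'
#' @param solution a [ClusterSolution-class].
#' @param records data.frame holding the solution's variables (and
#'   passthrough columns, if any).
#' @return integer vector of cluster labels in 1..k.
#' @examples
#' dv <- simulateDiveMetrics(200, diveTypeParams(sdScale = 0.5), seed = 2)
#' res <- classifyDives(dv, kRange = 4:5, restarts = 5)
#' lab <- applySolution(res$selected, dv)
#' mean(lab == clusterLabels(res$selected))
#' @export
applySolution <- function(solution, records) {
  records <- as.data.frame(records)
  z <- scale(as.matrix(records[, solution@variables]),
             center = solution@center, scale = solution@scale)
  feat <- (z %*% solution@loadings)[, seq_len(solution@nComponents),
                                    drop = FALSE]
  if (length(solution@passthrough)) {
    pt <- as.matrix(records[, solution@passthrough, drop = FALSE]) * 1
    sc <- solution@meta$ptScale
    for (j in seq_along(solution@passthrough)) {
      nm <- solution@passthrough[j]
      s <- if (!is.null(names(sc)) && nm %in% names(sc)) sc[[nm]]
           else if (length(sc) >= j) sc[[j]] else 1
      if (is.null(s) || !is.finite(s) || s == 0) s <- 1
      pt[, j] <- pt[, j] / s
    }
    feat <- cbind(feat, pt)
  }
  cen <- solution@centroids
  d2 <- outer(rowSums(feat^2), rowSums(cen^2), `+`) -
    2 * feat %*% t(cen)
  as.integer(apply(d2, 1, which.min))
}
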