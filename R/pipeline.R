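#' Default pipeline configuration
#'
#' All thresholds default to the standard values for harbor-seal TDR
#' analysis: 10 s sampling, 2 m surface threshold, dives kept if
#' deeper than 5 m with at least 5 readings, 85% bottom-phase
#' fraction, bouts opened by 4 consecutive dives to 6 m with a 0.05
#' sequential-test alpha, 80% PCA variance target, k scanned over 4-8
#' for dives (3-8 for bouts, so the three-type solution is reachable).
#'
#' @param ... overrides of the defaults, as name = value pairs;
#'   unknown names are an error.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1,
    nSeals = 2,
    nBouts = 100,            # per seal
    dt = 10,
    isolatedFrac = 0.1,
    zocWindow = 7200,
    surfaceThreshold = 2,
    minDepth = 5,
    minSamples = 5,
    bottomFraction = 0.85,
    wiggleMinExcursion = 1,
    startMinDives = 4,
    startMinDepth = 6,
    alpha = 0.05,
    varianceTarget = 0.80,
    diveKRange = c(4, 8),
    boutKRange = c(3, 8),
    restarts = 25,
    mcmcIter = 5e4,
    mcmcBurnin = 0.5,
    mcmcThin = 10,
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stopIfNot(length(unknown) == 0,
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pipelineConfig")
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of a [pipelineConfig()]; reading applies the file's
#' keys over the defaults, so a partial file is valid.
#'
#' @param path YAML file path.
#' @param config a \code{pipelineConfig} to write.
#' @return \code{readPipelineConfig}: a \code{pipelineConfig};
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

writeTableArtifact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 6))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic seals
#'
#' End-to-end orchestration: simulate one TDR trace per seal, apply
#' zero-offset correction and dive detection, compute dive metrics and
#' season/light context, detect and summarise bouts, classify dives
#' and bouts, and fit the Bayesian bout-type model on the Type I/II
#' bouts. Per-stage artifacts are written as plain-text tables under
#' \code{outdir} together with a JSON run manifest recording the
#' configuration, its hash and the seeds, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [pipelineConfig()] (or path to a YAML file).
#' @param quiet suppress stage messages.
#' @return list with \code{dives}, \code{bouts}, \code{diveClasses},
#'   \code{boutClasses}, \code{fit} (a [PosteriorSample-class] or NULL
#'   when too few labelled bouts), \code{effects}, \code{manifest} and
#'   \code{outdir}.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(nBouts = 30, mcmcIter = 2000,
#'                                   outdir = tempfile()))
#' res$manifest$stages
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outdir <- config$outdir %||% tempfile("divebout_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stages <- character()

  # stage 1: synthesis ---------------------------------------------------
  say("synth: ", config$nSeals, " seals x ", config$nBouts, " bouts")
  sites <- c("BirdRocks", "PadillaBay")
  sexes <- c("female", "male")
  # deployments staggered across the year so both seasons (and day and
  # night) are represented, as in a spring plus winter tagging design
  starts <- as.POSIXct("2007-04-01", tz = "UTC") +
    ((seq_len(config$nSeals) - 1) %% 3) * 120 * 86400
  sims <- lapply(seq_len(config$nSeals), function(s) {
    sim <- simulateTrace(nBouts = config$nBouts, dt = config$dt,
                         seed = config$seed + 1000L * s,
                         animal = sprintf("S%02d", s),
                         start = starts[s],
                         isolatedFrac = config$isolatedFrac)
    writeDepthTrace(sim$trace,
                    file.path(outdir, sprintf("trace_S%02d.csv", s)))
    sim
  })
  s0 <- seq_len(config$nSeals) - 1
  sealMeta <- data.frame(
    animal = sprintf("S%02d", seq_len(config$nSeals)),
    site = sites[s0 %% 2 + 1],
    # phase-shifted so both sexes appear even with two seals, without
    # aliasing sex to site once four or more are simulated
    sex = sexes[(s0 + floor(s0 / 2)) %% 2 + 1],
    stringsAsFactors = FALSE)
  stages <- c(stages, "synth")

  # stage 2+3: correction, dive detection, metrics, context --------------
  diveTabs <- lapply(seq_along(sims), function(s) {
    tr <- zeroOffsetCorrect(sims[[s]]$trace, window = config$zocWindow)
    win <- detectDives(tr, config$surfaceThreshold, config$minDepth,
                       config$minSamples)
    dv <- computeDiveMetrics(tr, win, config$bottomFraction,
                             config$wiggleMinExcursion)
    if (nrow(dv)) assignContext(dv, start = startTime(tr)) else dv
  })
  dives <- do.call(rbind, diveTabs)
  dives <- merge(dives, sealMeta, by = "animal", sort = FALSE)
  dives <- dives[order(dives$animal, dives$start_s), ]
  rownames(dives) <- NULL
  say("dives: ", nrow(dives), " detected")
  writeTableArtifact(dives, file.path(outdir, "dives.tsv"))
  stages <- c(stages, "trace", "dives")

  # stage 4: bouts --------------------------------------------------------
  cfgB <- boutConfig(config$startMinDives, config$startMinDepth,
                     config$alpha)
  boutTabs <- lapply(split(dives, dives$animal), function(d) {
    d <- d[order(d$start_s), ]
    det <- detectBouts(d, cfgB)
    summarizeBouts(d, det)
  })
  bouts <- do.call(rbind, boutTabs[vapply(boutTabs, nrow, 0L) > 0])
  rownames(bouts) <- NULL
  say("bouts: ", nrow(bouts), " detected")
  writeTableArtifact(bouts, file.path(outdir, "bouts.tsv"))
  stages <- c(stages, "bouts")

  # stage 5: classification ----------------------------------------------
  diveClasses <- classifyDives(
    dives, kRange = seq(config$diveKRange[1], config$diveKRange[2]),
    varianceTarget = config$varianceTarget, restarts = config$restarts,
    seed = config$seed)
  boutClasses <- classifyBouts(
    bouts, kRange = seq(config$boutKRange[1], config$boutKRange[2]),
    varianceTarget = config$varianceTarget, restarts = config$restarts,
    seed = config$seed)
  say("classify: dives k = ", diveClasses$selected@k,
      " (", round(diveClasses$selected@accuracy, 1), "%), bouts k = ",
      boutClasses$selected@k,
      " (", round(boutClasses$selected@accuracy, 1), "%)")
  writeTableArtifact(diveClasses$dives,
                     file.path(outdir, "dives_classified.tsv"))
  writeTableArtifact(boutClasses$bouts,
                     file.path(outdir, "bouts_classified.tsv"))
  writeClusterSolution(diveClasses$selected,
                       file.path(outdir, "dive_clusters.json"))
  writeClusterSolution(boutClasses$selected,
                       file.path(outdir, "bout_clusters.json"))
  stages <- c(stages, "classify")

  # stage 6: Bayesian bout-type model -------------------------------------
  lb <- boutClasses$bouts
  lb <- lb[lb$assigned_type %in% c("I", "II"), ]
  lb$seal_id <- lb$animal
  lb$bout_type <- lb$assigned_type
  fit <- NULL
  effects <- NULL
  canFit <- nrow(lb) >= 20 &&
    all(vapply(lb[c("site", "season", "sex", "light")],
               function(v) length(unique(v)) == 2, logical(1)))
  if (canFit) {
    des <- buildDesign(lb)
    fit <- fitMWG(des, mwgSpec(nIter = config$mcmcIter,
                               burnin = config$mcmcBurnin,
                               thin = config$mcmcThin,
                               seed = config$seed))
    effects <- summarizeEffects(fit)
    jsonlite::write_json(
      lapply(effects, function(d) d),
      file.path(outdir, "posterior_summary.json"),
      dataframe = "rows", digits = 8, auto_unbox = TRUE)
    writeTableArtifact(as.data.frame(posteriorDraws(fit)),
                       file.path(outdir, "posterior_draws.tsv"))
    stages <- c(stages, "bayes")
    say("bayes: ", nrow(posteriorDraws(fit)), " retained draws")
  } else {
    say("bayes: skipped (too few labelled bouts or one-level factor)")
  }

  manifest <- list(
    package = "diveBout",
    version = as.character(utils::packageVersion("diveBout")),
    config = unclass(config),
    configHash = fnv1a(paste(names(unclass(config)),
                             vapply(unclass(config), paste, collapse = ",",
                                    character(1)),
                             sep = "=", collapse = ";")),
    stages = stages,
    nDives = nrow(dives), nBouts = nrow(bouts))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  list(dives = dives, bouts = bouts, diveClasses = diveClasses,
       boutClasses = boutClasses, fit = fit, effects = effects,
       manifest = manifest, outdir = outdir)
}
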