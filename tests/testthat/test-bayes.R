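fullGrid <- function(reps = 1) {
  g <- expand.grid(site = c("BirdRocks", "PadillaBay"),
                   season = c("breeding", "nonbreeding"),
                   sex = c("female", "male"),
                   light = c("day", "night"),
                   stringsAsFactors = FALSE)
  g <- g[rep(seq_len(nrow(g)), reps), ]
  g$seal_id <- "S01"
  g
}

test_that("the full factorial design has the sixteen expected columns", {
  des <- buildDesign(fullGrid())
  expect_equal(ncol(des$X), 16L)
  expect_equal(colnames(des$X)[1:5],
               c("(Intercept)", "Site1", "Season1", "Light1", "Sex1"))
  expect_equal(colnames(des$X)[16], "Site1:Season1:Light1:Sex1")
  # interaction columns are products of their main-effect columns
  expect_equal(des$X[, "Site1:Season1"], des$X[, "Site1"] * des$X[, "Season1"])
  expect_equal(des$X[, "Site1:Season1:Light1:Sex1"],
               des$X[, "Site1"] * des$X[, "Season1"] *
               des$X[, "Light1"] * des$X[, "Sex1"])
  # all-reference row is the unit vector under treatment coding
  refRow <- which(apply(des$X[, 2:16], 1, function(r) all(r == 0)))[1]
  expect_equal(unname(des$X[refRow, ]), c(1, rep(0, 15)))
  expect_equal(ncol(buildDesign(fullGrid(), interactions = "main")$X), 5L)
  expect_equal(ncol(buildDesign(fullGrid(), interactions = "two-way")$X), 11L)
})

test_that("design construction rejects one-level factors and drops Type III", {
  g <- fullGrid()
  g$site <- "BirdRocks"
  expect_error(buildDesign(g), "site")
  g2 <- fullGrid()
  g2$bout_type <- c("I", "II", "III", rep("I", 13))
  expect_warning(des <- buildDesign(g2), "other than I/II")
  expect_equal(length(des$y), 15L)
})

test_that("sum coding flips the reference sign convention", {
  des <- buildDesign(fullGrid(), coding = "sum")
  expect_true(all(des$X[, "Site1"] %in% c(-1, 1)))
  expect_equal(sort(unique(des$X[, "Site1:Season1"])), c(-1, 1))
})

test_that("the log-likelihood matches closed forms and a scalar oracle", {
  g <- fullGrid()
  g$bout_type <- rep(c("I", "II"), 8)
  des <- buildDesign(g)
  # beta = 0: every theta is 1/2
  expect_equal(binomialLogLik(rep(0, 16), 0, des), 16 * log(0.5))
  # saturated single observation: loglik tends to 0 from below
  des1 <- list(X = matrix(1, 1, 1), y = 1, sealIndex = 1L, seals = "S01")
  expect_gt(binomialLogLik(700, 0, des1), -1e-10)
  expect_lte(binomialLogLik(700, 0, des1), 0)
  expect_true(is.finite(binomialLogLik(-700, 0, des1)))
  # random small case against direct per-row evaluation
  set.seed(61)
  idx <- sample(16, 6)
  desS <- list(X = des$X[idx, ], y = des$y[idx],
               sealIndex = rep(1L, 6), seals = "S01")
  beta <- rnorm(16, 0, 0.5)
  alpha <- rnorm(1, 0, 0.3)
  want <- 0
  for (i in 1:6) {
    th <- 1 / (1 + exp(-(sum(desS$X[i, ] * beta) + alpha)))
    want <- want + desS$y[i] * log(th) + (1 - desS$y[i]) * log(1 - th)
  }
  expect_equal(binomialLogLik(beta, alpha, desS), want, tolerance = 1e-12)
})

test_that("the sampler is deterministic under a fixed seed", {
  sim <- simulateOutcomes(outcomeParams(nSeals = 4, boutsPerSeal = 30),
                          seed = 62)
  f1 <- fitMWG(sim$design, mwgSpec(nIter = 2000, seed = 7))
  f2 <- fitMWG(sim$design, mwgSpec(nIter = 2000, seed = 7))
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  f3 <- fitMWG(sim$design, mwgSpec(nIter = 2000, seed = 8))
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("the intercept-only posterior matches adaptive quadrature", {
  oracle <- oracleInterceptPosterior(7, 10)
  g <- fullGrid()[1:10, ]
  g$bout_type <- c(rep("II", 7), rep("I", 3))
  des <- buildDesign(g)
  des$X <- des$X[, 1, drop = FALSE]
  fit <- fitMWG(des, mwgSpec(nIter = 2.2e5, burnin = 2e4, thin = 8,
                             hierarchical = FALSE, sigmaAlpha = 1e-8,
                             seed = 9))
  dr <- posteriorDraws(fit)[, "(Intercept)"]
  expect_equal(length(dr), 25000)
  expect_lt(abs(mean(dr) - oracle$mean), 0.02)
  # tail quantiles carry more Monte-Carlo error than the mean at this
  # chain length; 0.04 is about 4 quantile standard errors here
  expect_lt(abs(quantile(dr, 0.025, names = FALSE) -
                oracle$quantiles[["0.025"]]), 0.04)
  expect_lt(abs(quantile(dr, 0.975, names = FALSE) -
                oracle$quantiles[["0.975"]]), 0.04)
})

test_that("posterior means concentrate on the truth as data grow", {
  sim <- simulateOutcomes(outcomeParams(boutsPerSeal = 250,
                                        sigmaAlpha = 0.5), seed = 63)
  fit <- fitMWG(sim$design, mwgSpec(nIter = 2e4, seed = 10))
  eff <- summarizeEffects(fit)$fixed
  sdPost <- apply(posteriorDraws(fit)[, seq_len(16)], 2, sd)
  expect_true(all(abs(eff$mean - sim$beta) < 3.5 * sdPost))
})

test_that("hierarchical and flat modes agree when sigma is matched", {
  sim <- simulateOutcomes(outcomeParams(nSeals = 8, boutsPerSeal = 80,
                                        sigmaAlpha = 1), seed = 64)
  hier <- fitMWG(sim$design, mwgSpec(nIter = 3e4, seed = 11))
  sHat <- mean(posteriorDraws(hier)[, "sigma_alpha"])
  flat <- fitMWG(sim$design, mwgSpec(nIter = 3e4, hierarchical = FALSE,
                                     sigmaAlpha = sHat, seed = 12))
  dh <- posteriorDraws(hier)[, 1:16]
  df <- posteriorDraws(flat)[, 1:16]
  mh <- colMeans(dh)
  mf <- colMeans(df)
  # agreement to within the Monte-Carlo error of the two chains;
  # seal-level covariates leave some fixed effects diffuse, so the
  # yardstick must be each parameter's own MCSE
  essh <- apply(dh, 2, diveBout:::effectiveSize)
  essf <- apply(df, 2, diveBout:::effectiveSize)
  mcse <- sqrt(apply(dh, 2, var) / essh + apply(df, 2, var) / essf)
  expect_true(all(abs(mh - mf) < 4 * mcse + 0.05))
})

test_that("posterior summaries implement the significance rule and schema", {
  mkSample <- function(draws) {
    colnames(draws) <- c("(Intercept)", "S01", "sigma_alpha")
    new("PosteriorSample", draws = draws,
        parameters = colnames(draws), nFixed = 1L, animals = "S01",
        acceptance = rep(0.3, 3), spec = list(hierarchical = TRUE))
  }
  allPos <- mkSample(cbind(runif(200, 0.5, 2), rnorm(200), runif(200)))
  sf <- summarizeEffects(allPos)
  expect_identical(names(sf$fixed),
                   c("parameter", "mean", "0.025", "0.975",
                     "significant", "rhat", "ess"))
  expect_true(sf$fixed$significant[1])
  sym <- mkSample(cbind(seq(-1, 1, length.out = 200), rnorm(200),
                        runif(200)))
  expect_false(summarizeEffects(sym)$fixed$significant[1])
  # quantiles of a sorted grid match the direct percentile rule
  grid <- mkSample(cbind(1:1000, rnorm(1000), runif(1000)))
  sg <- summarizeEffects(grid)$fixed
  expect_equal(sg$`0.025`, quantile(1:1000, 0.025, names = FALSE))
  expect_equal(sg$`0.975`, quantile(1:1000, 0.975, names = FALSE))
  expect_equal(sg$mean, 500.5)
})

test_that("model screening ranks the generating structure first", {
  beta <- setNames(rep(0, 16), names(fixedEffectDefaults()))
  beta[1:5] <- c(0.4, 0.8, -0.9, 0.7, -1.1)   # main effects only
  sim <- simulateOutcomes(outcomeParams(beta = beta, sigmaAlpha = 0.3,
                                        nSeals = 10, boutsPerSeal = 200),
                          seed = 65)
  tab <- screenModels(sim$design$data)
  expect_equal(tab$model[1], "main")
  expect_true(all(diff(tab$BIC) >= 0))
  # identical candidates score identically
  tab2 <- screenModels(sim$design$data,
                       candidates = c(a = "main", b = "main"))
  expect_equal(tab2$AIC[1], tab2$AIC[2])
  expect_equal(tab2$BIC[1], tab2$BIC[2])
})

test_that("the saturated model loses by penalty on tiny samples", {
  set.seed(66)
  g <- fullGrid(2)
  g$seal_id <- rep(c("S01", "S02"), each = 16)
  g$bout_type <- sample(c("I", "II"), 32, replace = TRUE)
  tab <- suppressWarnings(screenModels(g))
  expect_equal(tab$model[nrow(tab)], "full")
})
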