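test_that("equal-variance independent variables need 7 of 8 components", {
  set.seed(41)
  x <- matrix(rnorm(5000 * 8), ncol = 8)
  colnames(x) <- paste0("v", 1:8)
  fit <- fitPCA(x, 0.80)
  expect_equal(fit$nComponents, 7L)
})

test_that("degenerate rank structure collapses the component count", {
  set.seed(42)
  latent <- rnorm(300)
  x1 <- sapply(1:8, function(i) latent * i)  # rank 1
  expect_equal(fitPCA(x1, 0.80)$nComponents, 1L)
  l2 <- cbind(rnorm(300), rnorm(300))
  x2 <- l2 %*% matrix(rnorm(16), 2, 8)      # rank 2
  expect_lte(fitPCA(x2, 0.80)$nComponents, 2L)
})

test_that("constant variables are dropped with a warning", {
  set.seed(43)
  x <- data.frame(a = rnorm(100), b = rnorm(100), c = 1)
  expect_warning(fit <- fitPCA(x, 0.8), "constant")
  expect_equal(fit$variables, c("a", "b"))
})

test_that("standardise-PCA reconstruction error equals the discarded eigenvalues", {
  set.seed(44)
  x <- as.matrix(simulateDiveMetrics(400, seed = 44)[,
    c("max_depth", "duration", "bottom_time", "skew1", "btd", "btm", "mdd")])
  fit <- fitPCA(x, 0.8)
  z <- scale(x, fit$center, fit$scale)
  k <- fit$nComponents
  recon <- fit$scores %*% t(fit$loadings[, seq_len(k)])
  resid <- sum((z - recon)^2)
  ev <- fit$varianceExplained * sum(apply(z, 2, var)) * (nrow(z) - 1)
  expect_equal(resid, sum(ev[-seq_len(k)]), tolerance = 1e-8)
})

test_that("well-separated blobs are recovered exactly and deterministically", {
  set.seed(45)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
  truth <- rep(1:4, each = 100)
  x <- centers[truth, ] + matrix(rnorm(800, 0, 0.3), ncol = 2)
  colnames(x) <- c("a", "b")
  pca <- fitPCA(x, 0.999)
  sols <- kmeansScan(pca, kRange = 4, seed = 1)
  expect_equal(ariIndex(table(truth, sols[[1]]@labels)), 1)
  sols2 <- kmeansScan(pca, kRange = 4, seed = 1)
  expect_identical(sols[[1]]@labels, sols2[[1]]@labels)
  expect_identical(sols[[1]]@meta$inertia, sols2[[1]]@meta$inertia)
})

test_that("discriminant validation is perfect on separated clusters and
           at chance on permuted labels", {
  set.seed(46)
  truth <- rep(1:2, times = c(300, 100))
  x <- cbind(a = rnorm(400, c(0, 20)[truth], 0.5),
             b = rnorm(400, 0, 0.5))
  pca <- fitPCA(x, 0.999)
  sols <- kmeansScan(pca, kRange = 2, seed = 2)
  val <- validateDFA(sols[[1]], x)
  expect_equal(val@accuracy, 100)
  # random labels carry no structure: LDA falls to the majority share
  perm <- sols[[1]]
  perm@labels <- sample(perm@labels)
  chance <- 100 * max(table(perm@labels)) / length(perm@labels)
  valPerm <- validateDFA(perm, x)
  expect_lt(abs(valPerm@accuracy - chance), 8)
})

test_that("parsimony selection follows the tolerance rule", {
  mk <- function(k, acc) new("ClusterSolution", k = as.integer(k),
    variables = "v", center = 0, scale = 1,
    loadings = matrix(1), nComponents = 1L, varianceExplained = 1,
    centroids = matrix(0), labels = 1L, accuracy = acc,
    passthrough = character(), meta = list())
  sols <- list(mk(4, 90), mk(5, 95), mk(6, 95.2), mk(7, 95.3), mk(8, 95.1))
  expect_equal(selectParsimonious(sols, 1.0)@k, 5L)
  expect_equal(selectParsimonious(sols[3], 1.0)@k, 6L)
  eq <- list(mk(4, 95), mk(5, 95), mk(6, 95))
  expect_equal(selectParsimonious(eq, 1.0)@k, 4L)
})

test_that("type naming reads centroid characteristics", {
  # dives: deep square wiggle vs shallow V
  rec <- data.frame(
    btd = c(rep(0.59, 10), rep(0.36, 10)),
    max_depth = c(rep(62, 10), rep(16, 10)),
    is_wiggle = c(rep(TRUE, 10), rep(FALSE, 10)))
  sol <- new("ClusterSolution", k = 2L, variables = "v", center = 0,
             scale = 1, loadings = matrix(1), nComponents = 1L,
             varianceExplained = 1, centroids = matrix(0),
             labels = rep(1:2, each = 10L), accuracy = 99,
             passthrough = character(), meta = list())
  tt <- nameTypes(sol, rec, role = "dive")
  expect_equal(tt$shape, c("square", "V"))
  expect_equal(tt$depth_class, c("deep", "shallow"))
  expect_equal(tt$wiggle, c(TRUE, FALSE))
  # bouts: surface-dominated cluster is Type III
  brec <- data.frame(
    mean_surface_interval = c(rep(45, 10), rep(39, 10), rep(3139, 10)),
    mean_duration = c(rep(289, 10), rep(166, 10), rep(193, 10)),
    mean_depth = c(rep(45, 10), rep(19, 10), rep(19, 10)))
  bsol <- sol
  bsol@k <- 3L
  bsol@labels <- rep(1:3, each = 10L)
  btt <- nameTypes(bsol, brec, role = "bout")
  expect_equal(btt$assigned_type, c("I", "II", "III"))
})

test_that("the pipeline is invariant to affine rescaling of an input variable", {
  dv <- simulateDiveMetrics(600, diveTypeParams(sdScale = 0.5), seed = 47)
  r1 <- classifyDives(dv, kRange = 4:6, restarts = 10, seed = 3)
  dv2 <- dv
  dv2$max_depth <- dv2$max_depth * 3.7 + 5
  r2 <- classifyDives(dv2, kRange = 4:6, restarts = 10, seed = 3)
  expect_identical(r1$selected@labels, r2$selected@labels)
  expect_equal(r1$scan$accuracy, r2$scan$accuracy)
})

test_that("bout types are recovered from published parameters", {
  bt <- simulateBoutMetrics(600, seed = 48)
  res <- classifyBouts(bt, kRange = 3:6, restarts = 10, seed = 4)
  expect_equal(res$selected@k, 3L)
  expect_gt(res$selected@accuracy, 90)
  got <- factor(res$bouts$assigned_type, levels = c("I", "II", "III"))
  expect_gt(mean(!is.na(got) & got == bt$true_type), 0.9)
})

test_that("dive types are recovered to the level the geometry supports", {
  dv <- simulateDiveMetrics(1500, diveTypeParams(sdScale = 0.5), seed = 49)
  res <- classifyDives(dv, kRange = 4:8, restarts = 10, seed = 5)
  # at half the published dispersion the shallow types still overlap,
  # so agreement with truth is high but not perfect, and the
  # accuracy-based parsimony rule admits small k
  expect_gt(res$selected@accuracy, 90)
  sol6 <- res$solutions[[which(res$scan$k == 6)]]
  expect_gt(ariIndex(table(dv$true_type, sol6@labels)), 0.7)
})

test_that("generating class is recovered by nearest centroid at half dispersion", {
  dv <- simulateDiveMetrics(1500, diveTypeParams(sdScale = 0.5), seed = 50)
  vars <- c("max_depth", "duration", "bottom_time", "wiggles", "skew1",
            "btd", "btm", "mdd")
  z <- scale(as.matrix(dv[, vars]))
  cen <- t(sapply(sort(unique(dv$true_type)), function(g)
    colMeans(z[dv$true_type == g, , drop = FALSE])))
  d2 <- as.matrix(dist(rbind(cen, z)))[-(1:6), 1:6]
  assigned <- max.col(-d2)
  expect_gt(mean(assigned == dv$true_type), 0.9)
})

test_that("cluster bundles round-trip through JSON and apply to records", {
  dv <- simulateDiveMetrics(400, diveTypeParams(sdScale = 0.5), seed = 51)
  res <- classifyDives(dv, kRange = 4:5, restarts = 5, seed = 6)
  sol <- res$selected
  f <- tempfile(fileext = ".json")
  writeClusterSolution(sol, f)
  back <- readClusterSolution(f)
  expect_equal(back@k, sol@k)
  expect_equal(back@center, sol@center)
  expect_equal(back@loadings, sol@loadings)
  expect_equal(back@centroids, sol@centroids, tolerance = 1e-12)
  expect_identical(back@labels, sol@labels)
  expect_equal(back@accuracy, sol@accuracy)
  expect_identical(back@passthrough, sol@passthrough)
  # nearest-centroid application reproduces the training partition
  lab <- applySolution(back, dv)
  expect_gt(mean(lab == sol@labels), 0.99)
  unlink(f)
})
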