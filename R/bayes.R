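#' Build the factorial design matrix for the bout-type model
#'
#' Expands the four binary covariates (haul-out site, season, sex,
#' light) into a fixed-effect design with intercept, main effects and
#' interactions up to the requested order, in a deterministic column
#' order (intercept; Site1, Season1, Light1, Sex1; the six two-way,
#' four three-way and one four-way products). Reference levels are
#' alphabetical (BirdRocks, breeding, day, female), so under treatment
#' coding a row with all factors at reference is (1, 0, ..., 0).
#' The animal mapping Z is returned as an index vector (each bout
#' belongs to exactly one seal).
#'
#' @param data data.frame with columns \code{site}, \code{season},
#'   \code{sex}, \code{light} (each with exactly two observed levels)
#'   and optionally \code{seal_id} and \code{bout_type}.
#' @param coding \code{"treatment"} (0/1) or \code{"sum"} (-1/+1).
#' @param interactions \code{"full"} (16 columns), \code{"two-way"}
#'   (11) or \code{"main"} (5).
#' @param response how to build the response: \code{NULL} for none, or
#'   the name of a column holding bout types; label 1 codes a Type II
#'   bout, 0 a Type I bout ("a positive effect indicates a shift from
#'   Type I to Type II"). Type III bouts must be excluded upstream;
#'   rows with other labels are dropped with a warning.
#' @return list with \code{X} (design matrix), \code{y} (0/1 response
#'   or NULL), \code{sealIndex} (integer seal per row), \code{seals}
#'   (seal ids), \code{coding}, \code{reference} (named reference
#'   levels) and \code{data} (possibly filtered rows).
#' @examples
#' d <- expand.grid(site = c("BirdRocks", "PadillaBay"),
#'                  season = c("breeding", "nonbreeding"),
#'                  sex = c("female", "male"),
#'                  light = c("day", "night"),
#'                  stringsAsFactors = FALSE)
#' dim(buildDesign(d)$X)
#' @export
buildDesign <- function(data, coding = c("treatment", "sum"),
                        interactions = c("full", "two-way", "main"),
                        response = "bout_type") {
  coding <- match.arg(coding)
  interactions <- match.arg(interactions)
  factors <- c("site", "season", "light", "sex")
  stopIfNot(all(factors %in% names(data)),
            "data needs site, season, sex and light columns")
  if (!is.null(response) && response %in% names(data)) {
    lv <- unique(data[[response]])
    bad <- setdiff(lv, c("I", "II", 0, 1, "0", "1"))
    if (length(bad)) {
      warning("dropping ", sum(data[[response]] %in% bad),
              " rows with bout types other than I/II")
      data <- data[!(data[[response]] %in% bad), , drop = FALSE]
    }
  }
  ref <- vapply(factors, function(f) {
    lev <- sort(unique(as.character(data[[f]])))
    if (length(lev) != 2)
      stop("factor '", f, "' must have exactly two observed levels",
           call. = FALSE)
    lev[1]
  }, character(1))
  codes <- lapply(factors, function(f) {
    hi <- as.integer(as.character(data[[f]]) != ref[[f]])
    if (coding == "sum") 2 * hi - 1 else hi
  })
  names(codes) <- c("Site1", "Season1", "Light1", "Sex1")
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n),
               Site1 = codes$Site1, Season1 = codes$Season1,
               Light1 = codes$Light1, Sex1 = codes$Sex1)
  twoWay <- list(c("Site1", "Season1"), c("Site1", "Light1"),
                 c("Season1", "Light1"), c("Site1", "Sex1"),
                 c("Season1", "Sex1"), c("Light1", "Sex1"))
  threeWay <- list(c("Site1", "Season1", "Light1"),
                   c("Site1", "Season1", "Sex1"),
                   c("Site1", "Light1", "Sex1"),
                   c("Season1", "Light1", "Sex1"))
  addProducts <- function(termSets) {
    for (ts in termSets) {
      nm <- paste(ts, collapse = ":")
      cols[[nm]] <<- Reduce(`*`, codes[ts])
    }
  }
  if (interactions %in% c("two-way", "full")) addProducts(twoWay)
  if (interactions == "full") {
    addProducts(threeWay)
    addProducts(list(c("Site1", "Season1", "Light1", "Sex1")))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  sealIds <- if (!is.null(data$seal_id)) as.character(data$seal_id)
             else rep("S01", n)
  seals <- sort(unique(sealIds))
  y <- NULL
  if (!is.null(response) && response %in% names(data)) {
    v <- data[[response]]
    y <- as.integer(v %in% c("II", 1, "1"))
  }
  list(X = X, y = y, sealIndex = match(sealIds, seals), seals = seals,
       coding = coding, reference = ref, data = data)
}

#' Binomial log-likelihood of the mixed logit model
#'
#' \eqn{\sum_i y_i \log\theta_i + (1 - y_i)\log(1 - \theta_i)} with
#' \eqn{\mathrm{logit}(\theta) = X\beta + Z\alpha}, computed
#' overflow-safely for linear predictors up to about \eqn{\pm 700}.
#'
#' @param beta fixed-effect vector.
#' @param alpha per-seal random-effect vector (may be a scalar 0).
#' @param design a [buildDesign()] result.
#' @param y 0/1 response vector (defaults to \code{design$y}).
#' @return scalar log-likelihood.
#' @export
binomialLogLik <- function(beta, alpha, design, y = design$y) {
  eta <- drop(design$X %*% beta)
  if (length(alpha) > 1 || alpha[1] != 0)
    eta <- eta + alpha[design$sealIndex]
  sum(y * stats::plogis(eta, log.p = TRUE) +
      (1 - y) * stats::plogis(-eta, log.p = TRUE))
}

#' Sampler settings for the Metropolis-within-Gibbs fit
#'
#' @param nIter total iterations (recommend >= 1e4).
#' @param burnin burn-in fraction of \code{nIter} (in (0, 1)) or an
#'   absolute iteration count.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param priorMean,priorSD Normal prior on each fixed effect
#'   (default Normal(0, 10^2), a vague prior on the logit scale).
#' @param hierarchical if TRUE, \code{sigma_alpha} gets a
#'   half-Normal(0, \code{hyperSD}^2) hyperprior and is sampled; if
#'   FALSE it is fixed at \code{sigmaAlpha}.
#' @param sigmaAlpha initial (hierarchical) or fixed (flat) value of
#'   the random-effect SD.
#' @param hyperSD scale of the half-Normal hyperprior (default 5).
#' @param adapt adapt proposal scales toward 0.2-0.4 acceptance during
#'   burn-in, then freeze (preserves the stationary distribution).
#' @param targetAccept target acceptance rate during adaptation.
#' @param seed integer seed; same seed, same draws.
#' @return list of class \code{"mwgSpec"}.
#' @export
mwgSpec <- function(nIter = 2e4, burnin = 0.5, thin = 10,
                    priorMean = 0, priorSD = 10,
                    hierarchical = TRUE, sigmaAlpha = 1, hyperSD = 5,
                    adapt = TRUE, targetAccept = 0.3, seed = 1) {
  stopIfNot(priorSD > 0, "prior SD must be positive")
  nBurn <- if (burnin < 1) as.integer(round(nIter * burnin))
           else as.integer(burnin)
  stopIfNot(nIter > nBurn, "chain length must exceed burn-in")
  structure(list(nIter = as.integer(nIter), nBurn = nBurn,
                 thin = as.integer(thin), priorMean = priorMean,
                 priorSD = priorSD, hierarchical = hierarchical,
                 sigmaAlpha = sigmaAlpha, hyperSD = hyperSD,
                 adapt = adapt, targetAccept = targetAccept,
                 seed = as.integer(seed)),
            class = "mwgSpec")
}

#' Fit the Bayesian binomial mixed model by Metropolis-within-Gibbs
#'
#' Samples the posterior of the bout-type model: binomial likelihood
#' with logit link, Normal priors on the fixed effects, per-seal
#' random effects \eqn{\alpha_i \sim N(0, \sigma_\alpha^2)} and (in
#' hierarchical mode) a half-Normal hyperprior on
#' \eqn{\sigma_\alpha}. Each Gibbs scan updates every fixed effect by
#' a componentwise random-walk Metropolis step, every random effect
#' likewise, and \eqn{\sigma_\alpha} by a Metropolis step on its log
#' targeting the full conditional. Proposal SDs adapt toward the
#' target acceptance rate during burn-in only.
#'
#' @param design a [buildDesign()] result with a response.
#' @param spec an [mwgSpec()] settings bundle.
#' @param y optional response override.
#' @return A [PosteriorSample-class] object.
#' @examples
#' \donttest{
#' sim <- simulateOutcomes(outcomeParams(nSeals = 6, boutsPerSeal = 40),
#'                         seed = 1)
#' fit <- fitMWG(sim$design, mwgSpec(nIter = 2000, seed = 1))
#' fit
#' }
#' @export
fitMWG <- function(design, spec = mwgSpec(), y = design$y) {
  stopIfNot(!is.null(y), "design carries no response")
  X <- design$X
  p <- ncol(X)
  nSeals <- length(design$seals)
  init <- rep(0, p)
  ll0 <- binomialLogLik(init, 0, design, y)
  if (!is.finite(ll0))
    stop("non-finite log-posterior at initial values; ",
         "check the prior and response coding", call. = FALSE)
  set.seed(spec$seed)
  res <- mwg_sample_cpp(
    X, as.integer(design$sealIndex - 1L), as.numeric(y),
    rep(spec$priorMean, length.out = p),
    rep(spec$priorSD, length.out = p),
    as.integer(nSeals), isTRUE(spec$hierarchical),
    spec$sigmaAlpha, spec$hyperSD,
    spec$nIter, spec$nBurn, spec$thin,
    isTRUE(spec$adapt), spec$targetAccept)
  draws <- res$draws
  params <- c(colnames(X), design$seals, "sigma_alpha")
  colnames(draws) <- params
  new("PosteriorSample",
      draws = draws, parameters = params, nFixed = as.integer(p),
      animals = design$seals,
      acceptance = pmin(pmax(res$acceptance, 0), 1),
      spec = unclass(spec))
}

#' Summarise posterior effects
#'
#' Per-parameter posterior mean and central 95% credible interval
#' (0.025 and 0.975 quantiles, type-7), with a significance flag set
#' when the interval excludes zero. Split into a fixed-effects table
#' (logit scale) and a per-seal random-effects table, plus
#' convergence diagnostics (split R-hat, effective sample size).
#'
#' @param sample a [PosteriorSample-class] object.
#' @return list with data.frames \code{fixed}, \code{random} and
#'   \code{sigma}; each has columns \code{parameter}, \code{mean},
#'   \code{0.025}, \code{0.975}, \code{significant}, \code{rhat},
#'   \code{ess}.
#' @export
summarizeEffects <- function(sample) {
  stopIfNot(is(sample, "PosteriorSample"), "need a PosteriorSample")
  draws <- sample@draws
  summ <- function(cols) {
    d <- draws[, cols, drop = FALSE]
    lo <- apply(d, 2, stats::quantile, probs = 0.025, names = FALSE)
    hi <- apply(d, 2, stats::quantile, probs = 0.975, names = FALSE)
    out <- data.frame(
      parameter = cols,
      mean = colMeans(d),
      lo, hi,
      significant = lo > 0 | hi < 0,
      rhat = apply(d, 2, splitRhat),
      ess = apply(d, 2, effectiveSize),
      stringsAsFactors = FALSE, check.names = FALSE)
    names(out)[3:4] <- c("0.025", "0.975")
    rownames(out) <- NULL
    out
  }
  pFix <- sample@parameters[seq_len(sample@nFixed)]
  list(fixed = summ(pFix),
       random = summ(sample@animals),
       sigma = summ("sigma_alpha"))
}

#' Screen candidate fixed-effect structures by AIC/BIC
#'
#' Fits each candidate model by maximum likelihood with the seal
#' identity included as fixed indicator effects (a documented
#' approximation to the mixed-model screen: the screen only orders
#' candidate fixed-effect structures) and ranks by BIC, then AIC.
#' Models showing quasi-complete separation (any |coefficient| > 15)
#' are flagged but retained.
#'
#' @param data covariate table with \code{bout_type} and
#'   \code{seal_id} columns.
#' @param candidates named list of interaction orders to try; default
#'   main effects, all two-way, full interactions.
#' @return data.frame with columns \code{model}, \code{p},
#'   \code{logLik}, \code{AIC}, \code{BIC}, \code{separation}, sorted
#'   ascending by BIC then AIC.
#' @export
screenModels <- function(data,
                         candidates = c(main = "main",
                                        `two-way` = "two-way",
                                        full = "full")) {
  multiSeal <- length(unique(data$seal_id)) > 1
  rows <- lapply(names(candidates), function(nm) {
    des <- buildDesign(data, interactions = candidates[[nm]])
    df <- as.data.frame(des$X[, -1, drop = FALSE])
    df$y <- des$y
    if (multiSeal) df$seal <- factor(des$seals[des$sealIndex])
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    cf <- stats::coef(fit)
    data.frame(model = nm, p = sum(!is.na(cf)),
               logLik = as.numeric(stats::logLik(fit)),
               AIC = stats::AIC(fit), BIC = stats::BIC(fit),
               separation = any(abs(cf[!is.na(cf)]) > 15),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$BIC, out$AIC), ]
  rownames(out) <- NULL
  if (any(out$separation))
    warning("possible separation (|coef| > 15) in: ",
            paste(out$model[out$separation], collapse = ", "))
  out
}
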