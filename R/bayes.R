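# Bayesian models of space-use drivers. Three families:
#   regression_cauchy  -- simple linear regression, Cauchy(0, 10) intercept and
#                         Cauchy(0, 2.5) slope priors
#   regression_normal  -- simple linear regression, Normal(0, 1e6 variance)
#                         intercept/slope, half-Cauchy(0, 5) residual scale
#   paired_difference  -- robust one-sample location-scale model on paired
#                         difference scores, t likelihood with a
#                         shifted-exponential prior on the df
# Sampling is delegated to JAGS (rjags); HPDIs, tail fractions, certainty
# bands, odds, split-chain PSRF, DIC and posterior-predictive Bayesian p are
# computed here from the chains.

#' Model specification for the Bayesian fits
#'
#' @param family one of \code{"regression_cauchy"}, \code{"regression_normal"},
#'   \code{"paired_difference"}.
#' @param chains number of MCMC chains (default 3).
#' @param burnin burn-in steps; defaults to 1e3 for regressions and 3e3 for
#'   paired differences.
#' @param iterations total post-burn-in draws pooled over chains
#'   (default 3e5).
#' @param seed integer RNG seed (drives the JAGS chain RNGs).
#' @param likelihood for \code{paired_difference}: \code{"t"} (robust,
#'   default) or \code{"normal"}.
#' @param skeptical also fit the skeptical prior (paired differences only;
#'   default TRUE).
#' @return a list of class \code{modelSpec}.
#' @export
modelSpec <- function(family = c("regression_cauchy", "regression_normal",
                                 "paired_difference"),
                      chains = 3, burnin = NULL, iterations = 3e5,
                      seed = 1L, likelihood = c("t", "normal"),
                      skeptical = TRUE) {
  family <- match.arg(family)
  if (is.null(burnin))
    burnin <- if (family == "paired_difference") 3e3 else 1e3
  stopifnot(chains >= 1, iterations > 0, burnin >= 0)
  structure(list(family = family, chains = as.integer(chains),
                 burnin = as.integer(burnin),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 likelihood = match.arg(likelihood),
                 skeptical = isTRUE(skeptical)),
            class = "modelSpec")
}

jagsInits <- function(spec) {
  lapply(seq_len(spec$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + k))
}

runJags <- function(model, data, monitor, spec) {
  perChain <- ceiling(spec$iterations / spec$chains)
  m <- rjags::jags.model(textConnection(model), data = data,
                         inits = jagsInits(spec), n.chains = spec$chains,
                         quiet = TRUE)
  stats::update(m, spec$burnin, progress.bar = "none")
  rjags::coda.samples(m, monitor, n.iter = perChain, progress.bar = "none")
}

#' Highest posterior density interval
#'
#' Shortest interval containing the requested posterior mass, by the
#' sorted-window algorithm.
#'
#' @param draws numeric vector of posterior draws (1000 or more recommended).
#' @param mass interval mass (default 0.95).
#' @return numeric(2): lower and upper bound.
#' @export
hpdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  n <- length(draws)
  if (n < 1000)
    warning("HPDI from fewer than 1000 draws is unstable", call. = FALSE)
  s <- sort(draws)
  k <- max(1, ceiling(mass * n))
  if (k >= n) return(c(s[1], s[n]))
  width <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(width)
  c(s[i], s[i + k])
}

#' Certainty band and odds from posterior draws
#'
#' The tail is the smaller of the posterior fractions below and above zero.
#' Bands: high certainty when the tail is below 5%, moderate when 5--10%,
#' uncertain otherwise. Odds in favour of the dominant sign are
#' (1 - tail)/tail, so a 95% one-sided posterior gives 19:1 and 98% gives
#' 49:1.
#'
#' @param draws numeric vector of posterior draws.
#' @return list with \code{pBelow}, \code{pAbove} (percent), \code{tail},
#'   \code{band}, \code{odds}.
#' @export
certaintyAndOdds <- function(draws) {
  stopifnot(length(draws) > 0)
  below <- mean(draws < 0)
  above <- 1 - below
  tail <- min(below, above)
  band <- if (tail < 0.05) "high" else if (tail < 0.10) "moderate" else
    "uncertain"
  odds <- if (tail == 0) Inf else (1 - tail) / tail
  list(pBelow = 100 * below, pAbove = 100 * above, tail = tail,
       band = band, odds = odds)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin PSRF with each chain split in half, per parameter.
#'
#' @param chains list of numeric matrices (iterations x parameters), one per
#'   chain, or a coda \code{mcmc.list}.
#' @return named numeric of PSRF values.
#' @export
psrf <- function(chains) {
  if (inherits(chains, "mcmc.list"))
    chains <- lapply(chains, function(c2) as.matrix(c2))
  if (length(chains) < 2 && nrow(chains[[1]]) < 4)
    stop("PSRF needs at least 2 chains (or one splittable chain)",
         call. = FALSE)
  half <- function(m) {
    n <- floor(nrow(m) / 2)
    list(m[seq_len(n), , drop = FALSE],
         m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
  }
  splits <- unlist(lapply(chains, half), recursive = FALSE)
  p <- ncol(splits[[1]])
  nms <- colnames(splits[[1]])
  out <- vapply(seq_len(p), function(j) {
    xs <- lapply(splits, function(m) m[, j])
    m <- length(xs); n <- length(xs[[1]])
    means <- vapply(xs, mean, 0)
    vars <- vapply(xs, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    varPlus <- (n - 1) / n * W + B / n
    sqrt(varPlus / W)
  }, 0)
  names(out) <- nms
  out
}

# lag-k autocorrelation of the pooled effect draws
lagAutocorr <- function(chains, param, lags = c(1, 5, 10, 50)) {
  x <- unlist(lapply(chains, function(m) as.matrix(m)[, param]))
  vapply(lags, function(k) {
    n <- length(x)
    stats::cor(x[1:(n - k)], x[(k + 1):n])
  }, 0)
}

# deviance helpers per family --------------------------------------------

regressionDeviance <- function(a, b, sigma, x, y) {
  vapply(seq_along(a), function(k)
    -2 * sum(stats::dnorm(y, a[k] + b[k] * x, sigma[k], log = TRUE)), 0)
}

pairedDeviance <- function(mu, sigma, nu, d, robust = TRUE) {
  n <- length(d)
  vapply(seq_along(mu), function(k) {
    z <- (d - mu[k]) / sigma[k]
    ll <- if (robust)
      sum(stats::dt(z, df = nu[k], log = TRUE) - log(sigma[k]))
    else
      sum(stats::dnorm(z, log = TRUE) - log(sigma[k]))
    -2 * ll
  }, 0)
}

# DIC = Dbar + pD with pD = Dbar - D(posterior means)
computeDIC <- function(devDraws, devAtMean) {
  dbar <- mean(devDraws)
  pD <- dbar - devAtMean
  dbar + pD
}

makeSummary <- function(effDraws, chains, effName, dic, bayesP, extras = list()) {
  hp <- hpdi(effDraws)
  co <- certaintyAndOdds(effDraws)
  rh <- psrf(chains)
  methods::new("PosteriorSummary",
               beta = mean(effDraws), hpdi = hp, pBelow = co$pBelow,
               pAbove = co$pAbove, band = co$band, odds = co$odds,
               dic = dic, bayesP = bayesP, psrf = rh, draws = effDraws,
               diagnostics = c(list(
                 autocorrelation = lagAutocorr(chains, effName)), extras))
}

thinIdx <- function(n, target) {
  if (n <= target) seq_len(n) else round(seq(1, n, length.out = target))
}

#' Bayesian simple linear regression
#'
#' Fits y = alpha + beta x + eps under the priors of the requested family and
#' summarises the slope posterior: mean effect size, 95% HPDI, tail fractions,
#' certainty band and odds, DIC, posterior-predictive Bayesian p
#' (mean-absolute-residual discrepancy) and split-chain PSRF. A fit whose
#' PSRF exceeds 1.1 on any parameter is retried with a doubled burn-in, then
#' reported as a convergence error.
#'
#' @param x,y predictor and response (finite, length 3 or more).
#' @param spec a \code{\link{modelSpec}} with a regression family.
#' @return a \linkS4class{PosteriorSummary} for the slope.
#' @export
fitLinearModel <- function(x, y, spec = modelSpec("regression_cauchy")) {
  stopifnot(length(x) == length(y))
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0)
    stop("constant predictor: slope not identifiable", call. = FALSE)
  if (!spec$family %in% c("regression_cauchy", "regression_normal"))
    stop("spec family must be a regression family", call. = FALSE)
  # centre the predictor for sampling: decorrelates intercept and slope so
  # single-site updates mix; the slope posterior is unchanged
  x <- x - mean(x)
  priors <- if (spec$family == "regression_cauchy") "
    alpha ~ dt(0, 0.01, 1)       # Cauchy(0, 10)
    beta  ~ dt(0, 0.16, 1)       # Cauchy(0, 2.5)
    sigma ~ dt(0, 0.04, 1) T(0,) # half-Cauchy(0, 5)
  " else "
    alpha ~ dnorm(0, 1.0E-6)     # Normal(0, variance 1e6)
    beta  ~ dnorm(0, 1.0E-6)
    sigma ~ dt(0, 0.04, 1) T(0,) # half-Cauchy(0, 5)
  "
  model <- paste0("model {
    for (i in 1:n) { y[i] ~ dnorm(alpha + beta * x[i], tau) }",
    priors, "
    tau <- pow(sigma, -2)
  }")
  spec2 <- spec
  for (attempt in 1:3) {
    s <- runJags(model, list(x = x, y = y, n = length(y)),
                 c("alpha", "beta", "sigma"), spec2)
    rh <- psrf(s)
    if (all(rh < 1.1)) break
    if (attempt == 3)
      stop("MCMC did not converge (PSRF >= 1.1 after retries)",
           call. = FALSE)
    spec2$burnin <- spec2$burnin * 4L
  }
  pooled <- do.call(rbind, lapply(s, as.matrix))
  idx <- thinIdx(nrow(pooled), 4000)
  a <- pooled[idx, "alpha"]; b <- pooled[idx, "beta"]
  sg <- pooled[idx, "sigma"]
  dev <- regressionDeviance(a, b, sg, x, y)
  devAtMean <- regressionDeviance(mean(pooled[, "alpha"]),
                                  mean(pooled[, "beta"]),
                                  mean(pooled[, "sigma"]), x, y)
  dic <- computeDIC(dev, devAtMean)
  bp <- regressionBayesP(a, b, sg, x, y)
  makeSummary(pooled[, "beta"], s, "beta", dic, bp)
}

regressionBayesP <- function(a, b, sigma, x, y, nRep = 1000) {
  idx <- thinIdx(length(a), nRep)
  ge <- 0
  for (k in idx) {
    mu <- a[k] + b[k] * x
    tObs <- mean(abs(y - mu))
    yRep <- stats::rnorm(length(y), mu, sigma[k])
    tRep <- mean(abs(yRep - mu))
    ge <- ge + (tRep >= tObs)
  }
  ge / length(idx)
}

#' Bayesian paired-difference model
#'
#' One-sample location-scale model on paired difference scores d (dry minus
#' wet), with a robust t likelihood whose degrees of freedom carry a shifted
#' exponential prior (mean 30), or a normal likelihood on request. The diffuse
#' location prior is a t distribution (3 df) centred on mean(d) with variance
#' 1e6 times var(d); a sensitivity refit under the skeptical prior t(0,
#' variance 1) is reported alongside.
#'
#' @param d numeric vector of paired difference scores (length 2 or more,
#'   non-zero variance).
#' @param spec a \code{\link{modelSpec}} with family
#'   \code{"paired_difference"}.
#' @return a \linkS4class{PosteriorSummary} for the location; the skeptical
#'   refit is in \code{diagnostics$skeptical} (band and HPDI).
#' @export
fitPairedDifference <- function(d, spec = modelSpec("paired_difference")) {
  if (length(d) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::var(d) == 0)
    stop("degenerate input: zero-variance difference scores", call. = FALSE)
  robust <- spec$likelihood == "t"
  fitOnce <- function(center, scale2) {
    precMu <- 1 / scale2  # JAGS dt precision = 1/scale^2
    lik <- if (robust) "d[i] ~ dt(mu, tauS, nu)" else
      "d[i] ~ dnorm(mu, tauS)"
    nuBlock <- if (robust)
      "nuM1 ~ dexp(0.0345)\n    nu <- nuM1 + 1" else "nu <- 1000"
    model <- sprintf("model {
      for (i in 1:n) { %s }
      mu ~ dt(center, precMu, 3)
      sigma ~ dunif(sdD / 1000, sdD * 1000)
      tauS <- pow(sigma, -2)
      %s
    }", lik, nuBlock)
    runJags(model,
            list(d = d, n = length(d), center = center, precMu = precMu,
                 sdD = stats::sd(d)),
            c("mu", "sigma", "nu"), spec)
  }
  # t(3 df) scale chosen so prior variance is exactly the requested variance:
  # var = scale^2 * nu/(nu-2) = 3 scale^2
  diffuseScale2 <- 1e6 * stats::var(d) / 3
  s <- fitOnce(mean(d), diffuseScale2)
  rh <- psrf(s)
  if (any(rh >= 1.1)) {
    spec$burnin <- spec$burnin * 4L
    s <- fitOnce(mean(d), diffuseScale2)
    if (any(psrf(s) >= 1.1))
      stop("MCMC did not converge (PSRF >= 1.1 after retries)", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(s, as.matrix))
  idx <- thinIdx(nrow(pooled), 4000)
  mu <- pooled[idx, "mu"]; sg <- pooled[idx, "sigma"]
  nu <- pooled[idx, "nu"]
  dev <- pairedDeviance(mu, sg, nu, d, robust)
  devAtMean <- pairedDeviance(mean(pooled[, "mu"]), mean(pooled[, "sigma"]),
                              mean(pooled[, "nu"]), d, robust)
  dic <- computeDIC(dev, devAtMean)
  bp <- pairedBayesP(mu, sg, nu, d, robust)
  extras <- list()
  if (spec$skeptical) {
    sk <- fitOnce(0, 1 / 3)  # t(0, variance 1), 3 df
    skDraws <- unlist(lapply(sk, function(m) as.matrix(m)[, "mu"]))
    skCo <- certaintyAndOdds(skDraws)
    extras$skeptical <- list(beta = mean(skDraws), hpdi = hpdi(skDraws),
                             band = skCo$band, odds = skCo$odds)
  }
  makeSummary(pooled[, "mu"], s, "mu", dic, bp, extras)
}

pairedBayesP <- function(mu, sigma, nu, d, robust, nRep = 1000) {
  idx <- thinIdx(length(mu), nRep)
  ge <- 0
  for (k in idx) {
    tObs <- mean(abs(d - mu[k]))
    dRep <- if (robust) mu[k] + sigma[k] * stats::rt(length(d), nu[k]) else
      stats::rnorm(length(d), mu[k], sigma[k])
    tRep <- mean(abs(dRep - mu[k]))
    ge <- ge + (tRep >= tObs)
  }
  ge / length(idx)
}
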