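test_that("hpdi is the shortest mass interval", {
  set.seed(81)
  z <- rnorm(1e6)
  h <- hpdi(z)
  expect_equal(h[1], qnorm(0.025), tolerance = 0.02)
  expect_equal(h[2], qnorm(0.975), tolerance = 0.02)
  u <- runif(1e5)
  hu <- hpdi(u)
  expect_equal(diff(hu), 0.95, tolerance = 0.01)
  expect_equal(suppressWarnings(hpdi(rep(3.5, 2000))), c(3.5, 3.5))
  # shortest-interval property on a skewed posterior: narrower than the
  # equal-tail interval
  g <- rgamma(2e5, shape = 2)
  expect_lt(diff(hpdi(g)), diff(quantile(g, c(0.025, 0.975))))
})

test_that("certainty bands and odds follow the tail conventions", {
  mk <- function(pNeg) c(rep(-1, round(1000 * pNeg)),
                         rep(1, 1000 - round(1000 * pNeg)))
  co95 <- certaintyAndOdds(mk(0.05))
  expect_equal(co95$odds, 19)
  co90 <- certaintyAndOdds(mk(0.10))
  expect_equal(co90$odds, 9)
  co98 <- certaintyAndOdds(mk(0.02))
  expect_equal(co98$odds, 49)
  expect_equal(co98$band, "high")
  expect_equal(certaintyAndOdds(mk(0.07))$band, "moderate")
  co50 <- certaintyAndOdds(mk(0.5))
  expect_equal(co50$odds, 1)
  expect_equal(co50$band, "uncertain")
  expect_equal(co50$pBelow + co50$pAbove, 100)
  # odds are monotone in the dominant-sign mass
  ps <- seq(0.5, 0.99, by = 0.01)
  odds <- vapply(ps, function(p) certaintyAndOdds(mk(1 - p))$odds, 0)
  expect_true(all(diff(odds) > 0))
})

test_that("split-chain PSRF separates convergent from divergent chains", {
  set.seed(82)
  same <- lapply(1:3, function(k) cbind(theta = rnorm(4000)))
  expect_equal(unname(psrf(same)), 1, tolerance = 0.02)
  apart <- list(cbind(theta = rnorm(2000, 0)), cbind(theta = rnorm(2000, 5)))
  expect_gt(psrf(apart)[["theta"]], 1.1)
  # agrees with the independent coda implementation on stationary
  # autocorrelated chains
  ch <- lapply(1:3, function(k)
    cbind(a = as.numeric(arima.sim(list(ar = 0.8), 4000))))
  ours <- psrf(ch)[["a"]]
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                          autoburnin = FALSE)$psrf[1, 1]
  expect_equal(ours, cd, tolerance = 0.05)
})

test_that("regression recovers a known slope and flags constant predictors", {
  set.seed(83)
  x <- rnorm(100); y <- 2 * x + rnorm(100, 0, 0.1)
  f <- fitLinearModel(x, y, fastSpec("regression_cauchy", seed = 2))
  hp <- hpdiBounds(f)
  expect_true(hp[1] <= 2 && 2 <= hp[2])
  expect_equal(effectSize(f), 2, tolerance = 0.02)
  expect_true(all(f@psrf < 1.1))
  expect_gt(f@bayesP, 0.05); expect_lt(f@bayesP, 0.95)
  expect_error(fitLinearModel(rep(1, 10), rnorm(10),
                              fastSpec("regression_cauchy")),
               "constant predictor")
  expect_error(fitLinearModel(1:2, 1:2, fastSpec("regression_cauchy")),
               "at least 3")
})

test_that("our HPDI agrees with coda on real posterior draws", {
  set.seed(84)
  x <- rnorm(50); y <- 1 + 0.5 * x + rnorm(50)
  f <- fitLinearModel(x, y, fastSpec("regression_normal", seed = 4))
  cd <- coda::HPDinterval(coda::mcmc(posteriorDraws(f)))
  expect_equal(hpdiBounds(f), unname(cd[1, ]), tolerance = 1e-6)
})

test_that("conjugate special case matches the closed-form posterior", {
  # near-flat priors and informative data: the slope posterior approaches the
  # classical normal form b_hat +/- sigma/sqrt(Sxx)
  set.seed(85)
  n <- 200
  x <- rnorm(n); y <- 3 + 1.5 * x + rnorm(n, 0, 2)
  f <- fitLinearModel(x, y, fastSpec("regression_normal", seed = 5,
                                     iterations = 30000))
  fit <- lm(y ~ x)
  bHat <- coef(fit)[["x"]]
  sHat <- summary(fit)$sigma
  seB <- sHat / sqrt(sum((x - mean(x))^2))
  expect_equal(effectSize(f), bHat, tolerance = 0.02)
  expect_equal(sd(posteriorDraws(f)), seB, tolerance = 0.1)
})

test_that("DIC prefers the model with the generating covariate", {
  set.seed(86)
  x <- rnorm(40); y <- 2 * x + rnorm(40, 0, 0.7)
  fGood <- fitLinearModel(x, y, fastSpec("regression_normal", seed = 6))
  fNull <- fitLinearModel(sample(x), y, fastSpec("regression_normal", seed = 7))
  expect_lt(fGood@dic, fNull@dic)
})

test_that("paired-difference model finds strong effects and respects symmetry", {
  set.seed(87)
  d <- rnorm(7, -5, 1)
  f <- fitPairedDifference(d, fastSpec("paired_difference", seed = 8))
  expect_gt(f@pBelow, 95)
  expect_true(all(f@psrf < 1.1))
  # diffuse and skeptical priors agree for well-separated effects
  expect_equal(f@diagnostics$skeptical$band, certaintyBand(f))

  # exactly symmetric (antithetic) unimodal scores: posterior splits 50:50
  z <- rnorm(500)
  fS <- fitPairedDifference(c(z, -z), fastSpec("paired_difference", seed = 9))
  expect_gt(fS@pBelow, 40); expect_lt(fS@pBelow, 60)

  expect_error(fitPairedDifference(rep(2, 6)), "zero-variance")
  expect_error(fitPairedDifference(1), "at least 2")
  # normal-likelihood variant also runs
  spN <- fastSpec("paired_difference", seed = 10)
  spN$likelihood <- "normal"
  fN <- fitPairedDifference(d, spN)
  expect_gt(fN@pBelow, 95)
})

test_that("posterior predictive p is calibrated for a well-specified model", {
  set.seed(88)
  ps <- vapply(1:20, function(r) {
    x <- rnorm(30); y <- 1 + x + rnorm(30)
    f <- fitLinearModel(x, y, fastSpec("regression_normal", seed = 100 + r,
                                       iterations = 3000, burnin = 300))
    f@bayesP
  }, 0)
  expect_true(all(ps > 0.01 & ps < 0.99))
  expect_gte(mean(ps > 0.05 & ps < 0.95), 0.9)
})
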