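test_that("beta-binomial pmf matches exact and integral oracles", {
  # one trial under a uniform level distribution: alpha = beta = 1
  expect_equal(dBetaBinom(1, 1, pi = 0.5, gamma = 1/3), 0.5)
  # alpha = 2, beta = 3: exact value C(5,2) B(4,6)/B(2,3) = 5/21
  expect_equal(dBetaBinom(2, 5, pi = 0.4, gamma = 1/6), 5/21,
               tolerance = 1e-12)
  # same value by numerical integration of the binomial against Beta(2,3)
  oracle <- integrate(function(p) dbinom(2, 5, p) * dbeta(p, 2, 3),
                      0, 1)$value
  expect_equal(dBetaBinom(2, 5, pi = 0.4, gamma = 1/6), oracle,
               tolerance = 1e-8)
  # gamma = 0 is the binomial, exactly
  expect_identical(dBetaBinom(0:10, 10, pi = 0.37, gamma = 0),
                   dbinom(0:10, 10, 0.37))
})

test_that("pmf rejects domain violations", {
  expect_error(dBetaBinom(3, 2, 0.5, 0.1), "0 <= m <= n")
  expect_error(dBetaBinom(1, 2, 1.2, 0.1), "pi")
  expect_error(dBetaBinom(1, 2, 0.5, 1), "gamma")
  expect_error(dBetaBinom(1.5, 3, 0.5, 0.1), "integers")
})

test_that("pmf normalizes and approaches the binomial as gamma -> 0", {
  for (n in c(1L, 7L, 23L, 50L)) {
    for (pi in c(0.05, 0.3, 0.5, 0.8, 0.95)) {
      for (gamma in c(0, 0.1, 0.35, 0.7)) {
        expect_equal(sum(dBetaBinom(0:n, n, pi, gamma)), 1,
                     tolerance = 1e-10)
      }
      d <- abs(dBetaBinom(0:n, n, pi, 1e-8, log = TRUE) -
                 dbinom(0:n, n, pi, log = TRUE))
      expect_lt(max(d), 1e-3)
    }
  }
})

test_that("moments formula agrees with brute-force pmf moments", {
  mom <- betaBinomMoments(10, 0.5, 0)
  expect_equal(mom$mean, 5)
  expect_equal(mom$variance, 2.5)
  # dispersion has no effect at n = 1
  expect_equal(betaBinomMoments(1, 0.3, 0.7)$variance, 0.3 * 0.7)
  expect_equal(betaBinomMoments(10, 0.5, 0.2)$variance, 7)
  for (n in c(2L, 10L, 50L)) {
    for (pi in c(0.2, 0.5, 0.9)) {
      for (gamma in c(0, 0.15, 0.5)) {
        pmf <- dBetaBinom(0:n, n, pi, gamma)
        mu <- sum((0:n) * pmf)
        v <- sum(((0:n) - mu)^2 * pmf)
        mom <- betaBinomMoments(n, pi, gamma)
        expect_equal(mom$mean, mu, tolerance = 1e-8)
        expect_equal(mom$variance, v, tolerance = 1e-8)
      }
    }
  }
})

test_that("regression log-likelihood sums per-sample pmfs and drops
           uncovered samples", {
  X1 <- matrix(1, 1, 1)
  expect_equal(betaBinomLogLik(0, 0, X1, totals = 2, meths = 1), log(0.5))
  # two samples, uniform level distribution, (1,1) and (0,1)
  X2 <- matrix(1, 2, 1)
  expect_equal(betaBinomLogLik(0, 1/3, X2, c(1, 1), c(1, 0)), 2 * log(0.5))
  # a zero-coverage sample changes nothing
  X3 <- matrix(1, 3, 1)
  expect_equal(betaBinomLogLik(0, 1/3, X3, c(1, 1, 0), c(1, 0, 0)),
               2 * log(0.5))
  expect_error(betaBinomLogLik(0, 0, X2, c(0, 0), c(0, 0)),
               "no covered samples")
})

test_that("fitBetaBinom recovers symmetric data and known parameters", {
  X <- matrix(1, 6, 1, dimnames = list(NULL, "base"))
  fit <- fitBetaBinom(X, totals = rep(6L, 6), meths = rep(3L, 6))
  expect_true(fit$converged)
  expect_equal(plogis(fit$eta[[1]]), 0.5, tolerance = 1e-3)
  expect_lt(fit$gamma, 0.01)   # no overdispersion in constant data
  expect_lte(fit$logLik, 0)
  expect_identical(fit$nUsed, 6L)

  # parameter recovery on 200 samples at coverage 30, vs an independent
  # grid-search maximizer of the same likelihood
  set.seed(11)
  d <- drawSite(200, 30, pi = 0.3, gamma = 0.1)
  Xl <- matrix(1, 200, 1)
  fit <- fitBetaBinom(Xl, d$n, d$m)
  expect_true(fit$converged)
  piHat <- plogis(fit$eta[[1]])
  expect_lt(abs(piHat - 0.3), 0.03)
  expect_lt(abs(fit$gamma - 0.1), 0.05)
  oracle <- gridSearchFit(d$n, d$m)
  expect_lt(abs(piHat - oracle$pi), 0.005)
  expect_lt(abs(fit$gamma - oracle$gamma), 0.005)
  expect_gte(fit$logLik, oracle$logLik - 1e-6)
})

test_that("testSite: no group effect gives a null result and the LRT is
           internally consistent", {
  X <- cbind(base = 1, case = rep(0:1, each = 3))
  # identical data in both groups: test effect ~0, statistic ~0, p ~1
  tt <- testSite(X, "case", totals = rep(10L, 6),
                 meths = rep(c(2L, 5L, 7L), 2))
  expect_lt(abs(tt$full$eta[["case"]]), 0.02)
  expect_lt(abs(tt$full$logLik - tt$reduced$logLik), 1e-4)
  expect_gt(tt$pRaw, 0.99)
  expect_identical(tt$df, 1L)

  # p equals the chi-squared tail of the clamped statistic
  set.seed(3)
  for (i in 1:5) {
    d <- drawSite(8, 12, pi = 0.4, gamma = 0.15)
    X8 <- cbind(base = 1, case = rep(0:1, each = 4))
    tt <- testSite(X8, "case", d$n, d$m)
    stat <- max(0, 2 * (tt$full$logLik - tt$reduced$logLik))
    expect_equal(tt$pRaw, pchisq(stat, 1, lower.tail = FALSE))
    expect_gte(tt$full$logLik, tt$reduced$logLik - 1e-6)
  }
})

test_that("sites with coverage in only one group are untestable", {
  X <- cbind(base = 1, case = rep(0:1, each = 3))
  tt <- testSite(X, "case", totals = c(5L, 8L, 6L, 0L, 0L, 0L),
                 meths = c(2L, 3L, 1L, 0L, 0L, 0L))
  expect_true(is.na(tt$pRaw))
  expect_error(testSite(X, "treatment", rep(5L, 6), rep(1L, 6)),
               "unknown test factor")
})

test_that("p-values are invariant to sample order", {
  set.seed(7)
  X <- cbind(base = 1, case = rep(0:1, each = 6))
  for (i in 1:5) {
    n <- rpois(12, 10) + 1L
    m <- rbinom(12, n, rbeta(12, 2, 2))
    p1 <- testSite(X, "case", n, m)$pRaw
    perm <- sample(12)
    p2 <- testSite(X[perm, ], "case", n[perm], m[perm])$pRaw
    expect_lt(abs(p1 - p2), 1e-6)
  }
})

test_that("full model log-likelihood dominates the reduced (nesting)", {
  set.seed(19)
  ns <- 300
  n <- matrix(rpois(ns * 12, 8) + 1L, ns)
  m <- matrix(rbinom(ns * 12, n, rbeta(ns * 12, 2, 2)), ns)
  X <- cbind(base = 1, case = rep(0:1, each = 6))
  fit <- methylBB:::.fitSitesCpp(n, m, X, 2L)
  conv <- fit$convFull & fit$convRed
  expect_gt(mean(conv), 0.95)
  expect_true(all(fit$llFull[conv] >= fit$llRed[conv] - 1e-6))
  expect_true(all(fit$llFull[conv] <= 1e-9))
})

test_that("the LRT is calibrated when replicates are plentiful", {
  # 15 vs 15 samples, truly beta-binomial null data: rejection at 0.05
  # should sit within 3 Monte-Carlo SEs of nominal
  set.seed(25)
  ns <- 2000; s <- 30
  n <- matrix(rpois(ns * s, 10) + 1L, ns)
  m <- matrix(rbinom(ns * s, n, rbeta(ns * s, 2, 2)), ns)
  X <- cbind(base = 1, case = rep(0:1, each = 15))
  fit <- methylBB:::.fitSitesCpp(n, m, X, 2L)
  pv <- pchisq(pmax(0, 2 * (fit$llFull - fit$llRed)), 1,
               lower.tail = FALSE)
  rate <- mean(pv < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / ns))
})
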