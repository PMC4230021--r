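test_that("z-transform matches the normal quantile and propagates NA", {
  expect_equal(zTransform(0.5), 0)
  expect_equal(zTransform(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_true(is.na(zTransform(NA_real_)))
  # clipping keeps extreme p finite
  expect_true(is.finite(zTransform(0)))
  expect_true(is.finite(zTransform(1)))
  expect_error(zTransform(1.5), "0, 1")
})

test_that("correlation profile: independent z-scores give rho ~ 0", {
  set.seed(5)
  n <- 1e5
  pos <- seq_len(n)           # unit spacing: every bin is populated
  z <- rnorm(n)
  prof <- estimateCorrelation(rep("chr1", n), pos, z, maxDist = 200)
  expect_lt(max(abs(prof$rho)), 0.02)
})

test_that("correlation profile: duplicated z at distance 2 gives rho[2] ~ 1", {
  base <- seq(0, by = 1000, length.out = 60)
  pos <- as.integer(sort(c(base + 1, base + 3)))
  set.seed(6)
  zz <- rnorm(60)
  z <- as.vector(rbind(zz, zz))  # z at p equals z at p + 2
  prof <- estimateCorrelation(rep("chr1", length(pos)), pos, z,
                              maxDist = 10)
  expect_gt(prof$rho[2], 0.99)
})

test_that("correlation profile recovers AR(1) autocorrelation", {
  set.seed(8)
  n <- 2e4
  z <- as.vector(arima.sim(list(ar = 0.5), n))
  prof <- estimateCorrelation(rep("chr1", n), seq_len(n), z, maxDist = 5)
  expect_lt(abs(prof$rho[1] - 0.5), 0.05)
  # sparse-bin borrowing: with < 2 sites it errors
  expect_error(estimateCorrelation("chr1", 1L, 0.3), "at least 2")
})

test_that("weighted Z combination matches hand-computed values", {
  # singleton window returns the raw p unchanged
  expect_identical(combinePvalues("chr1", 100L, 0.03, NULL,
                                  windowBp = 200), 0.03)
  # two sites with z = 0 combine to 0.5
  expect_equal(combinePvalues(c("chr1", "chr1"), c(100L, 110L),
                              c(0.5, 0.5), NULL, windowBp = 200),
               c(0.5, 0.5))
  # two sites with z = 1.6449, independent: 1 - Phi(2z/sqrt(2)) ~ 0.0100
  p <- combinePvalues(c("chr1", "chr1"), c(100L, 110L), c(0.05, 0.05),
                      NULL, windowBp = 200)
  expect_equal(p[1], 1 - pnorm(2 * qnorm(0.95) / sqrt(2)),
               tolerance = 1e-10)
  expect_equal(p[1], 0.0100, tolerance = 1e-3)
  # untestable center stays NA
  expect_true(is.na(combinePvalues("chr1", 100L, NA_real_, NULL)[1]))
})

test_that("zero correlation reduces to the classic Stouffer combination", {
  set.seed(9)
  zeroProf <- structure(list(rho = rep(0, 200), nPairs = rep(100, 200),
                             maxDist = 200L), class = "corProfile")
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    pos <- sort(sample(1000:1200, k))
    p <- runif(k)
    got <- combinePvalues(rep("chr1", k), pos, p, zeroProf,
                          windowBp = 1e6)
    z <- qnorm(1 - p)
    want <- pnorm(sum(z) / sqrt(k), lower.tail = FALSE)
    expect_equal(got[1], want, tolerance = 1e-12)
  }
})

test_that("combined p is invariant under reversal of the window", {
  set.seed(10)
  k <- 7
  pos <- sort(sample(1000:1300, k))
  p <- runif(k)
  prof <- structure(list(rho = runif(400, -0.1, 0.5),
                         nPairs = rep(100, 400), maxDist = 400L),
                    class = "corProfile")
  fwd <- combinePvalues(rep("chr1", k), pos, p, prof, windowBp = 800)
  rpos <- sort(max(pos) + min(pos) - pos)  # mirrored layout
  bwd <- combinePvalues(rep("chr1", k), rpos, rev(p), prof,
                        windowBp = 800)
  expect_equal(fwd, rev(bwd), tolerance = 1e-12)
})

test_that("adjustPvalues boosts consensus runs and dilutes isolated hits", {
  n <- 60
  pos <- seq(1L, by = 50L, length.out = n)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
  # uniform p = 0.5 everywhere stays 0.5
  gr$pRaw <- rep(0.5, n)
  expect_equal(adjustPvalues(gr)$pCombined, rep(0.5, n),
               tolerance = 1e-12)
  # a run of 10 sites at p = 0.05: interior combined p < 0.05
  gr$pRaw <- rep(0.5, n); gr$pRaw[25:34] <- 0.05
  out <- adjustPvalues(gr)
  expect_true(all(out$pCombined[27:32] < 0.05))
  # an isolated p = 1e-6 among nulls is diluted upward
  gr$pRaw <- rep(0.5, n); gr$pRaw[30] <- 1e-6
  out <- adjustPvalues(gr)
  expect_gt(out$pCombined[30], 1e-6)
})

test_that("combined p-values stay calibrated under a global null", {
  set.seed(12)
  n <- 1e5
  pos <- simPositions(n, seed = 12)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
  gr$pRaw <- runif(n)
  out <- adjustPvalues(gr)
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(out$pCombined < alpha)
    expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
  }
})

test_that("BH adjustment matches the textbook step-up and its properties", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.2), 0.2)
  got <- bhAdjust(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], bhOracle(c(0.01, 0.04)))
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone in rank
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))
  }
})
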