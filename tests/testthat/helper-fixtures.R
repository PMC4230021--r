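# fixtures are built in code at test time

# tiny two-sample counts object
toyCounts <- function() {
  MethCounts(total = rbind(c(5L, 4L), c(9L, 7L), c(6L, 8L)),
             meth = rbind(c(2L, 4L), c(1L, 6L), c(3L, 3L)),
             chrom = c("chr1", "chr1", "chr2"),
             pos = c(108L, 230L, 15L),
             sampleNames = c("s1", "s2"))
}

# simulate raw counts for one site: levels ~ Beta reparameterised by
# (pi, gamma), reads binomial given the level
drawSite <- function(s, coverage, pi, gamma) {
  if (gamma > 0) {
    shape <- 1 / gamma - 1
    lev <- rbeta(s, pi * shape, (1 - pi) * shape)
  } else {
    lev <- rep(pi, s)
  }
  n <- rep_len(as.integer(coverage), s)
  list(n = n, m = rbinom(s, n, lev))
}

# brute-force grid-search ML over (pi, gamma) for an intercept-only fit;
# independent of the packaged optimizer
gridSearchFit <- function(totals, meths, piGrid = seq(0.02, 0.98, by = 0.005),
                          gammaGrid = seq(0.001, 0.6, by = 0.005)) {
  best <- c(NA, NA, -Inf)
  X <- matrix(1, length(totals), 1)
  for (p in piGrid) {
    for (g in gammaGrid) {
      ll <- betaBinomLogLik(qlogis(p), g, X, totals, meths)
      if (ll > best[3]) best <- c(p, g, ll)
    }
  }
  list(pi = best[1], gamma = best[2], logLik = best[3])
}

# textbook BH step-up computed from first principles
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# generator-like site positions: gaps uniform on [2, 200]
simPositions <- function(n, seed = 1) {
  set.seed(seed)
  cumsum(c(1L, sample(2:200, n - 1L, replace = TRUE)))
}
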