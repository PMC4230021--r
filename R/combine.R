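#' Z-transform of p-values
#'
#' Maps raw p-values to standard-normal scores `z = qnorm(1 - p)`, the
#' first step of the weighted Z (Stouffer-Liptak) combination. Small p
#' gives large positive z. p-values are clipped to
#' `[clipEps, 1 - clipEps]` first so z stays finite; `NA` propagates.
#'
#' @param p numeric vector of p-values in \[0, 1\] (or `NA`).
#' @param clipEps clipping bound in (0, 0.5); default `1e-15`.
#' @return numeric vector of z-scores.
#' @examples
#' zTransform(c(0.5, 0.05, NA))
#' @export
zTransform <- function(p, clipEps = 1e-15) {
  stopifnot(clipEps > 0, clipEps < 0.5)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qnorm(1 - pmin(pmax(p, clipEps), 1 - clipEps))
}

#' Distance-binned autocorrelation of z-scores
#'
#' Estimates, for every integer genomic distance `d` in `1..maxDist` bp,
#' the Pearson correlation of z-scores over all genome-wide pairs of
#' testable sites exactly `d` bp apart on the same chromosome. Sparse bins
#' (fewer than `minPairs` pairs, or degenerate variance) inherit the
#' nearest populated bin's estimate; if no bin is populated the profile is
#' all zeros. Estimates are clamped to (-1, 1).
#'
#' @param chrom chromosome of each site.
#' @param pos 1-based position of each site.
#' @param z per-site z-scores (`NA` for untestable sites).
#' @param maxDist largest distance (bp) estimated; default 200.
#' @param minPairs minimum pairs per bin before borrowing; default 50.
#' @return an object of class `"corProfile"`: a list with `rho` (length
#'   `maxDist`), `nPairs`, and `maxDist`.
#' @export
estimateCorrelation <- function(chrom, pos, z, maxDist = 200L,
                                minPairs = 50L) {
  maxDist <- as.integer(maxDist)
  stopifnot(maxDist >= 1L)
  ok <- !is.na(z)
  if (sum(ok) < 2L)
    stop("need at least 2 testable sites to estimate correlation")
  acc <- matrix(0, nrow = maxDist, ncol = 6L)  # n, sx, sy, sxx, syy, sxy
  for (ch in unique(chrom)) {
    sel <- which(ok & chrom == ch)
    if (length(sel) < 2L) next
    p <- pos[sel][order(pos[sel])]
    x <- z[sel][order(pos[sel])]
    n <- length(p)
    for (k in seq_len(n - 1L)) {
      d <- p[(1L + k):n] - p[1L:(n - k)]
      if (min(d) > maxDist) break
      keep <- d >= 1L & d <= maxDist
      if (!any(keep)) next
      a <- x[1L:(n - k)][keep]
      b <- x[(1L + k):n][keep]
      dd <- d[keep]
      part <- rowsum(cbind(1, a, b, a * a, b * b, a * b), group = dd)
      idx <- as.integer(rownames(part))
      acc[idx, ] <- acc[idx, , drop = FALSE] + part
    }
  }
  nP <- acc[, 1L]
  rho <- rep(NA_real_, maxDist)
  has <- nP >= minPairs
  if (any(has)) {
    n <- nP[has]
    cxy <- acc[has, 6L] - acc[has, 2L] * acc[has, 3L] / n
    vx <- acc[has, 4L] - acc[has, 2L]^2 / n
    vy <- acc[has, 5L] - acc[has, 3L]^2 / n
    r <- ifelse(vx > 0 & vy > 0, cxy / sqrt(vx * vy), NA_real_)
    rho[has] <- r
  }
  pop <- which(!is.na(rho))
  if (length(pop)) {
    for (d in which(is.na(rho))) {
      near <- pop[which.min(abs(pop - d))]
      rho[d] <- rho[near]
    }
  } else {
    rho[] <- 0
  }
  rho <- pmin(pmax(rho, -0.999), 0.999)
  structure(list(rho = rho, nPairs = nP, maxDist = maxDist),
            class = "corProfile")
}

#' @export
print.corProfile <- function(x, ...) {
  cat("corProfile: distances 1..", x$maxDist, " bp; ",
      sum(x$nPairs > 0), " populated bins; rho range [",
      sprintf("%.3f", min(x$rho)), ", ", sprintf("%.3f", max(x$rho)),
      "]\n", sep = "")
  invisible(x)
}

# sum over i<j of rho(|pos_i - pos_j|) for window member positions;
# distances beyond the profile contribute 0
.pairRhoSum <- function(wpos, rho, maxDist) {
  k <- length(wpos)
  if (k < 2L) return(0)
  tot <- 0
  for (a in 1L:(k - 1L)) {
    d <- wpos[(a + 1L):k] - wpos[a]
    d <- d[d >= 1L & d <= maxDist]
    if (length(d)) tot <- tot + sum(rho[d])
  }
  tot
}

#' Weighted Z combination of neighbouring p-values
#'
#' Combines each testable site's p-value with those of its neighbours in a
#' symmetric window of `windowBp/2` bp on each side (same chromosome) via
#' the weighted Z test:
#' \deqn{p_z = 1 - \Phi\!\Big(\sum_i z_i \Big/
#'   \sqrt{n + 2\sum_{i<j}\rho(|d_{ij}|)}\Big),}
#' with `rho` taken from a [estimateCorrelation()] profile (0 beyond its
#' range). If estimated negative correlations push the variance term below
#' `0.1 * n` it is floored there. A singleton window returns the raw
#' p-value unchanged; untestable sites stay `NA`.
#'
#' @inheritParams estimateCorrelation
#' @param p per-site raw p-values (`NA` for untestable sites).
#' @param profile a `"corProfile"` from [estimateCorrelation()], or `NULL`
#'   for independence (all correlations 0).
#' @param windowBp full window span in bp; default 200 (i.e. +-100 bp).
#' @param clipEps p-value clipping bound for the z-transform.
#' @return numeric vector of combined p-values, aligned with the input.
#' @export
combinePvalues <- function(chrom, pos, p, profile = NULL, windowBp = 200,
                           clipEps = 1e-15) {
  stopifnot(windowBp >= 0)
  z <- zTransform(p, clipEps)
  if (is.null(profile)) {
    rho <- numeric(0)
    maxDist <- 0L
  } else {
    rho <- profile$rho
    maxDist <- profile$maxDist
  }
  half <- windowBp / 2
  out <- rep(NA_real_, length(p))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch & !is.na(z))
    if (!length(sel)) next
    o <- order(pos[sel])
    sel <- sel[o]
    cpos <- pos[sel]
    cz <- z[sel]
    n <- length(sel)
    lo <- findInterval(cpos - half, cpos, left.open = TRUE) + 1L
    hi <- findInterval(cpos + half, cpos)
    for (i in seq_len(n)) {
      idx <- lo[i]:hi[i]
      k <- length(idx)
      if (k == 1L) {
        out[sel[i]] <- p[sel[i]]
        next
      }
      S <- sum(cz[idx])
      v <- k + 2 * .pairRhoSum(cpos[idx], rho, maxDist)
      v <- max(v, 0.1 * k)
      out[sel[i]] <- pnorm(S / sqrt(v), lower.tail = FALSE)
    }
  }
  out
}

#' Benjamini-Hochberg adjustment with NA handling
#'
#' Step-up false discovery rate adjustment. `NA` p-values are excluded
#' from the ranking (they do not count towards the number of tests) and
#' returned as `NA`.
#'
#' @param p numeric vector of p-values (or `NA`).
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, NA))
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Combine and FDR-adjust a per-site result table
#'
#' One pass over a [dmTest()] result: estimates the genome-wide
#' distance-binned autocorrelation of z-scores, combines every testable
#' site's p-value with its windowed neighbours (chromosome boundaries
#' respected), and applies the Benjamini-Hochberg correction to the
#' combined p-values. With fewer than two testable sites the combined
#' p-values equal the raw ones.
#'
#' @param siteRes the `GRanges` returned by [dmTest()] (or any `GRanges`
#'   with a numeric `pRaw` column).
#' @param windowBp combination window span in bp (default 200).
#' @param maxDist correlation-profile span in bp (default 200).
#' @param clipEps p-value clipping bound; default `1e-15`.
#' @param minPairs minimum pairs per correlation bin; default 50.
#' @return `siteRes` with `pCombined` and `pAdj` filled in.
#' @export
adjustPvalues <- function(siteRes, windowBp = 200, maxDist = 200,
                          clipEps = 1e-15, minPairs = 50L) {
  p <- siteRes$pRaw
  chrom <- as.character(GenomicRanges::seqnames(siteRes))
  pos <- GenomicRanges::start(siteRes)
  if (sum(!is.na(p)) < 2L) {
    siteRes$pCombined <- p
  } else {
    prof <- estimateCorrelation(chrom, pos, zTransform(p, clipEps),
                                maxDist = maxDist, minPairs = minPairs)
    siteRes$pCombined <- combinePvalues(chrom, pos, p, prof,
                                        windowBp = windowBp,
                                        clipEps = clipEps)
  }
  siteRes$pAdj <- bhAdjust(siteRes$pCombined)
  siteRes
}
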