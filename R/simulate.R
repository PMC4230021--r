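#' Describe a methylation-level distribution
#'
#' Levels across replicates are modelled either as draws from a beta
#' distribution or as a fixed constant (the zero-dispersion case).
#'
#' @param dist `"beta"` or `"constant"`.
#' @param shape1,shape2 beta shape parameters (when `dist = "beta"`).
#' @param value the fixed level (when `dist = "constant"`).
#' @return a list of class `"levelDist"`.
#' @examples
#' levelDist("beta", 2, 2)       # intermediate levels, variance 1/20
#' levelDist("constant", value = 0.7)
#' @export
levelDist <- function(dist = c("beta", "constant"), shape1 = 2,
                      shape2 = 2, value = 0.7) {
  dist <- match.arg(dist)
  if (dist == "beta") stopifnot(shape1 > 0, shape2 > 0)
  else stopifnot(value >= 0, value <= 1)
  structure(list(dist = dist, shape1 = shape1, shape2 = shape2,
                 value = value), class = "levelDist")
}

#' Draw methylation levels from a level distribution
#'
#' @param spec a [levelDist()] object.
#' @param n number of draws.
#' @return numeric vector of levels in \[0, 1\].
#' @export
sampleLevels <- function(spec, n) {
  stopifnot(inherits(spec, "levelDist"))
  if (spec$dist == "beta") rbeta(n, spec$shape1, spec$shape2)
  else rep(spec$value, n)
}

#' Simulation parameters
#'
#' Describes a synthetic WGBS benchmark dataset: a case/control design in
#' which non-DM sites draw every sample's methylation level from a common
#' null distribution, while DM sites -- grouped into contiguous regions --
#' draw high levels in cases (default Beta(6, 1.5), mean 0.8) and low
#' levels in controls (default Beta(1.5, 6), mean 0.2). Site positions are
#' laid out on one chromosome with inter-site gaps uniform on
#' `[2, maxGapBp]` bp, so every region satisfies the neighbour-gap
#' constraint by construction. Read counts are binomial draws at the
#' site/sample level given a Poisson (or empirical) coverage.
#'
#' @param nCase,nControl numbers of case and control samples.
#' @param nSites total number of simulated sites.
#' @param nRegions number of true DM regions.
#' @param regionSizeRange inclusive range of region sizes in CpGs;
#'   default `c(10, 100)`.
#' @param maxGapBp largest inter-site gap in bp; default 200.
#' @param coverageMean mean of the Poisson per-site/per-sample coverage.
#' @param coverageFloor minimum coverage (draws below it are raised);
#'   default 0, i.e. zero-coverage observations are kept as zeros and the
#'   site is simply uncovered in that sample.
#' @param coverageFile optional path to a whitespace-separated file of
#'   nonnegative integer coverages resampled (with replacement) instead of
#'   the Poisson model.
#' @param nullLevels,dmCaseLevels,dmControlLevels [levelDist()] objects.
#' @param chrom chromosome name used for the layout.
#' @return a list of class `"simParams"`.
#' @examples
#' simParams(nCase = 6, nControl = 6, nSites = 2000, nRegions = 10)
#' @export
simParams <- function(nCase = 6L, nControl = 6L, nSites = 20000L,
                      nRegions = 100L, regionSizeRange = c(10L, 100L),
                      maxGapBp = 200L, coverageMean = 10,
                      coverageFloor = 0L, coverageFile = NULL,
                      nullLevels = levelDist("beta", 2, 2),
                      dmCaseLevels = levelDist("beta", 6, 1.5),
                      dmControlLevels = levelDist("beta", 1.5, 6),
                      chrom = "chr1") {
  stopifnot(nCase >= 1, nControl >= 1, nSites >= 1, nRegions >= 0,
            length(regionSizeRange) == 2L,
            regionSizeRange[1] >= 1,
            regionSizeRange[2] >= regionSizeRange[1],
            maxGapBp >= 2, coverageMean > 0, coverageFloor >= 0)
  if (nRegions * regionSizeRange[2] > nSites)
    stop("infeasible layout: nRegions * max(regionSizeRange) exceeds nSites")
  structure(list(nCase = as.integer(nCase), nControl = as.integer(nControl),
                 nSites = as.integer(nSites), nRegions = as.integer(nRegions),
                 regionSizeRange = as.integer(regionSizeRange),
                 maxGapBp = as.integer(maxGapBp),
                 coverageMean = coverageMean,
                 coverageFloor = as.integer(coverageFloor),
                 coverageFile = coverageFile,
                 nullLevels = nullLevels, dmCaseLevels = dmCaseLevels,
                 dmControlLevels = dmControlLevels, chrom = chrom),
            class = "simParams")
}

#' Benchmark presets
#'
#' Ready-made [simParams()] configurations:
#' \describe{
#'   \item{`paper-main`}{6 cases vs 6 controls; null levels Beta(2, 2);
#'     Poisson(10) coverage; 20,000 sites, 100 DM regions.}
#'   \item{`higher-variance`}{as `paper-main` with null levels
#'     Beta(1.5, 1.5) (level variance 1/16 instead of 1/20).}
#'   \item{`zero-dispersion`}{as `paper-main` with all non-DM levels fixed
#'     at 0.7.}
#'   \item{`low-coverage`}{50 cases vs 50 controls at mean coverage 1.5;
#'     20,000 sites, 200 DM regions.}
#' }
#'
#' @param name preset name.
#' @return a `"simParams"` object.
#' @export
simPreset <- function(name = c("paper-main", "higher-variance",
                               "zero-dispersion", "low-coverage")) {
  name <- match.arg(name)
  switch(name,
    "paper-main" = simParams(),
    "higher-variance" = simParams(nullLevels = levelDist("beta", 1.5, 1.5)),
    "zero-dispersion" = simParams(nullLevels = levelDist("constant",
                                                         value = 0.7)),
    "low-coverage" = simParams(nCase = 50L, nControl = 50L,
                               nSites = 20000L, nRegions = 200L,
                               coverageMean = 1.5))
}

.drawCoverage <- function(params, n) {
  if (!is.null(params$coverageFile)) {
    pool <- scan(params$coverageFile, what = integer(), quiet = TRUE)
    if (!length(pool) || any(pool < 0))
      stop("coverage file must contain nonnegative integers")
    cov <- sample(pool, n, replace = TRUE)
  } else {
    cov <- rpois(n, params$coverageMean)
  }
  pmax(cov, params$coverageFloor)
}

#' Simulate a WGBS benchmark dataset
#'
#' Generates counts, a design matrix, and the ground truth from a
#' [simParams()] configuration. A single master seed drives four
#' independent streams (layout, levels, coverage, counts), so the result
#' is bit-for-bit reproducible.
#'
#' @param params a `"simParams"` object.
#' @param seed integer RNG seed.
#' @return a list with components:
#'   \describe{
#'     \item{`counts`}{a [MethCounts-class] object (controls first, then
#'       cases);}
#'     \item{`design`}{the samples x 2 model matrix (`base`, `case`);}
#'     \item{`truth`}{a list with `dmSites` (character keys
#'       `"chrom:pos"` of truly DM sites), `dmFlags` (per-site logical),
#'       and `regions` (a `GRanges` of true region spans with an
#'       `nCpGs` column).}
#'   }
#' @examples
#' sim <- simulateDataset(simParams(nSites = 300, nRegions = 2), seed = 7)
#' sum(sim$truth$dmFlags)
#' @export
simulateDataset <- function(params, seed = 1L) {
  stopifnot(inherits(params, "simParams"))
  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max, 4L)

  nS <- params$nSites
  s <- params$nCase + params$nControl

  ## layout: positions and DM-region placement
  set.seed(subseeds[1L])
  gaps <- sample(seq.int(2L, params$maxGapBp), nS - 1L, replace = TRUE)
  pos <- cumsum(c(1L, gaps))
  dmFlag <- rep(FALSE, nS)
  regionStartIdx <- integer(0)
  regionLen <- integer(0)
  if (params$nRegions > 0L) {
    regionLen <- sample(seq.int(params$regionSizeRange[1L],
                                params$regionSizeRange[2L]),
                        params$nRegions, replace = TRUE)
    nSpacer <- params$nRegions + 1L
    extra <- nS - sum(regionLen) - nSpacer
    if (extra < 0L) stop("infeasible layout for the drawn region sizes")
    spacer <- rep(1L, nSpacer) +
      tabulate(sample.int(nSpacer, extra, replace = TRUE), nbins = nSpacer)
    cursor <- 0L
    for (k in seq_len(params$nRegions)) {
      cursor <- cursor + spacer[k]
      regionStartIdx <- c(regionStartIdx, cursor + 1L)
      dmFlag[(cursor + 1L):(cursor + regionLen[k])] <- TRUE
      cursor <- cursor + regionLen[k]
    }
  }

  ## methylation levels, per site and sample
  set.seed(subseeds[2L])
  isCase <- c(rep(FALSE, params$nControl), rep(TRUE, params$nCase))
  lev <- matrix(NA_real_, nS, s)
  nNull <- sum(!dmFlag)
  if (nNull)
    lev[!dmFlag, ] <- sampleLevels(params$nullLevels, nNull * s)
  nDM <- sum(dmFlag)
  if (nDM) {
    lev[dmFlag, !isCase] <- sampleLevels(params$dmControlLevels,
                                         nDM * sum(!isCase))
    lev[dmFlag, isCase] <- sampleLevels(params$dmCaseLevels,
                                        nDM * sum(isCase))
  }

  ## coverage, then methylated-read counts
  set.seed(subseeds[3L])
  tot <- matrix(.drawCoverage(params, nS * s), nS, s)
  set.seed(subseeds[4L])
  met <- matrix(rbinom(nS * s, as.vector(tot), as.vector(lev)), nS, s)

  sampleNames <- c(sprintf("control%d", seq_len(params$nControl)),
                   sprintf("case%d", seq_len(params$nCase)))
  counts <- MethCounts(tot, met, chrom = rep(params$chrom, nS), pos = pos,
                       strand = "+", context = "CpG",
                       sampleNames = sampleNames)
  design <- cbind(base = 1, case = as.integer(isCase))
  rownames(design) <- sampleNames

  if (params$nRegions > 0L) {
    regGR <- GenomicRanges::GRanges(
      seqnames = params$chrom,
      ranges = IRanges::IRanges(
        start = pos[regionStartIdx],
        end = pos[regionStartIdx + regionLen - 1L]))
    regGR$nCpGs <- regionLen
  } else {
    regGR <- GenomicRanges::GRanges()
  }
  truth <- list(dmSites = paste(params$chrom, pos[dmFlag], sep = ":"),
                dmFlags = dmFlag, regions = regGR)
  list(counts = counts, design = design, truth = truth)
}

#' Jaccard index between two site sets
#'
#' `|M intersect T| / |M union T|`; defined as 1 when both sets are empty.
#'
#' @param called,truth character vectors of site keys (e.g. `"chrom:pos"`).
#' @return the index in \[0, 1\].
#' @examples
#' jaccardIndex(c("chr1:1", "chr1:5"), c("chr1:5", "chr1:9"))  # 1/3
#' @export
jaccardIndex <- function(called, truth) {
  called <- unique(called)
  truth <- unique(truth)
  u <- length(union(called, truth))
  if (u == 0L) return(1)
  length(intersect(called, truth)) / u
}

#' Run the simulation benchmark end to end
#'
#' Simulates a dataset, runs the full pipeline (per-site regression,
#' windowed p-value combination, FDR correction, site calls at the
#' cutoff), and scores the called DM sites against the simulated truth.
#'
#' @param params a [simParams()] configuration.
#' @param seed RNG seed for the simulation.
#' @param windowBp,maxDist combination window and correlation span (bp).
#' @param fdrCutoff site-call cutoff on adjusted p-values; default 0.01.
#' @return a list with `jaccard`, `tp`, `fp`, `fn`, `nCalled`, `nTrue`.
#' @examples
#' \donttest{
#' runBenchmark(simPreset("low-coverage"), seed = 1)$jaccard
#' }
#' @export
runBenchmark <- function(params, seed = 1L, windowBp = 200, maxDist = 200,
                         fdrCutoff = 0.01) {
  sim <- simulateDataset(params, seed = seed)
  res <- dmTest(sim$counts, sim$design, "case")
  res <- adjustPvalues(res, windowBp = windowBp, maxDist = maxDist)
  flag <- callDMSites(res$pAdj, fdrCutoff)
  key <- paste(as.character(GenomicRanges::seqnames(res)),
               GenomicRanges::start(res), sep = ":")
  called <- key[flag]
  truth <- sim$truth$dmSites
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  list(jaccard = jaccardIndex(called, truth), tp = tp, fp = fp, fn = fn,
       nCalled = length(called), nTrue = length(truth))
}
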