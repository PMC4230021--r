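#' Full differential-methylation pipeline
#'
#' Convenience wrapper chaining [dmTest()], [adjustPvalues()],
#' [mergeDMRegions()], [summarizeRegions()], and [filterRegions()].
#' Identical to running the staged command-line interface on intermediate
#' files.
#'
#' @inheritParams dmTest
#' @inheritParams adjustPvalues
#' @param fdrCutoff DM-site cutoff on adjusted p-values; default 0.01.
#' @param maxGap largest bp gap between DM sites merged into one region.
#' @param minCpgs,minDiff region filters (see [filterRegions()]);
#'   `minCpgs = 1` and `minDiff = 0` keep every region with a nonzero
#'   methylation difference.
#' @return a list with `sites` (per-site `GRanges`) and `regions`
#'   (filtered, summarised region `GRanges`).
#' @examples
#' sim <- simulateDataset(simParams(nSites = 400, nRegions = 3,
#'                                  coverageMean = 20), seed = 2)
#' out <- dmPipeline(sim$counts, sim$design, "case", minCpgs = 5)
#' out$regions
#' @export
dmPipeline <- function(counts, design, testFactor, windowBp = 200,
                       maxDist = 200, fdrCutoff = 0.01, maxGap = 200,
                       minCpgs = 1L, minDiff = 0) {
  sites <- dmTest(counts, design, testFactor)
  sites <- adjustPvalues(sites, windowBp = windowBp, maxDist = maxDist)
  regions <- mergeDMRegions(sites, fdrCutoff = fdrCutoff, maxGap = maxGap)
  regions <- summarizeRegions(regions, sites)
  regions <- filterRegions(regions, minCpgs = minCpgs, minDiff = minDiff)
  list(sites = sites, regions = regions)
}
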