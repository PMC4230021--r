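#' Flag differentially methylated sites
#'
#' A site is called DM when its FDR-adjusted p-value lies strictly below
#' the cutoff; `NA` (untestable) sites are never called.
#'
#' @param pAdj adjusted p-values.
#' @param cutoff significance level in (0, 1); default 0.01.
#' @return logical vector of DM flags.
#' @export
callDMSites <- function(pAdj, cutoff = 0.01) {
  stopifnot(cutoff > 0, cutoff < 1)
  flag <- pAdj < cutoff
  flag[is.na(flag)] <- FALSE
  flag
}

#' Merge DM sites into regions
#'
#' Maximal runs of DM sites on one chromosome with at most `maxGap` bp
#' between consecutive DM sites become one region spanning the first to
#' the last member site; a lone DM site forms a single-CpG region.
#' Tested-but-not-significant sites interior to a region do not break the
#' run (only gap distance does), so `nSig/nCpGs` measures how strongly a
#' region is dominated by DM sites once [summarizeRegions()] has counted
#' the tested members.
#'
#' @param siteRes a [dmTest()]/[adjustPvalues()] result `GRanges`.
#' @param fdrCutoff site-call cutoff on `pAdj`; default 0.01.
#' @param maxGap largest bp distance between consecutive DM sites merged
#'   into one region; default 200.
#' @return a `GRanges` of regions (1-based inclusive coordinates) with a
#'   metadata column `nSig`.
#' @seealso [summarizeRegions()], [filterRegions()]
#' @export
mergeDMRegions <- function(siteRes, fdrCutoff = 0.01, maxGap = 200) {
  stopifnot(maxGap > 0)
  flag <- callDMSites(siteRes$pAdj, fdrCutoff)
  empty <- GenomicRanges::GRanges()
  if (!any(flag)) return(empty)
  dm <- siteRes[flag]
  o <- .orderSites(as.character(GenomicRanges::seqnames(dm)),
                   GenomicRanges::start(dm),
                   as.character(GenomicRanges::strand(dm)))
  dm <- dm[o]
  chrom <- as.character(GenomicRanges::seqnames(dm))
  pos <- GenomicRanges::start(dm)
  newRun <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) > maxGap)
  run <- cumsum(newRun)
  starts <- tapply(pos, run, min)
  ends <- tapply(pos, run, max)
  rchrom <- tapply(chrom, run, `[`, 1L)
  nSig <- as.integer(table(run))
  out <- GenomicRanges::GRanges(
    seqnames = as.character(rchrom),
    ranges = IRanges::IRanges(start = as.integer(starts),
                              end = as.integer(ends)))
  out$nSig <- nSig
  out
}

#' Summarise DM regions
#'
#' Completes each region with the quantities used for downstream
#' filtering and interpretation:
#' \itemize{
#'   \item `nCpGs`: tested sites (non-`NA` p) inside the region span;
#'   \item `logOdds`: region effect on the log-odds scale from pooled
#'     per-group counts over all member sites, Laplace-smoothed (+0.5 to
#'     methylated reads, +1 to totals per group) so proportions of 0 or 1
#'     stay finite:
#'     `log[pA(1-pB) / (pB(1-pA))]`;
#'   \item `minMethDiff`: the minimum over member sites (with coverage in
#'     both groups) of the absolute difference between the two groups'
#'     pooled site-level methylation levels.
#' }
#' A group with zero coverage over the whole region yields `NA` summaries.
#'
#' @param regions the `GRanges` from [mergeDMRegions()].
#' @param siteRes the site-level `GRanges` (must carry `pRaw` and the
#'   pooled group count columns `totalA`, `methA`, `totalB`, `methB`).
#' @return `regions` with `nCpGs`, `logOdds`, `minMethDiff` added.
#' @export
summarizeRegions <- function(regions, siteRes) {
  n <- length(regions)
  nCpGs <- integer(n)
  logOdds <- rep(NA_real_, n)
  minDiff <- rep(NA_real_, n)
  if (n) {
    tested <- siteRes[!is.na(siteRes$pRaw)]
    ov <- GenomicRanges::findOverlaps(regions, tested, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in seq_len(n)) {
      mem <- tested[sh[qh == i]]
      nCpGs[i] <- length(mem)
      if (!length(mem)) next
      tA <- sum(mem$totalA); mA <- sum(mem$methA)
      tB <- sum(mem$totalB); mB <- sum(mem$methB)
      if (tA > 0 && tB > 0) {
        pA <- (mA + 0.5) / (tA + 1)
        pB <- (mB + 0.5) / (tB + 1)
        logOdds[i] <- log(pA * (1 - pB) / (pB * (1 - pA)))
        both <- mem$totalA > 0 & mem$totalB > 0
        if (any(both))
          minDiff[i] <- min(abs(mem$levelA[both] - mem$levelB[both]))
      }
    }
  }
  regions$nCpGs <- nCpGs
  regions$logOdds <- logOdds
  regions$minMethDiff <- minDiff
  regions
}

#' Filter DM regions
#'
#' Keeps regions with at least `minCpgs` tested CpGs and a minimum
#' methylation difference strictly above `minDiff` (regions with `NA`
#' summaries are dropped when the corresponding threshold is active,
#' i.e. `minDiff >= 0` always drops `NA` differences).
#'
#' @param regions a summarised region `GRanges`.
#' @param minCpgs smallest region size kept (tested CpGs); default 10.
#' @param minDiff regions must satisfy `minMethDiff > minDiff`; default 0.
#' @return the filtered `GRanges`.
#' @export
filterRegions <- function(regions, minCpgs = 10L, minDiff = 0) {
  stopifnot(minCpgs >= 0, minDiff >= 0)
  if (!length(regions)) return(regions)
  keep <- regions$nCpGs >= minCpgs &
    !is.na(regions$minMethDiff) & regions$minMethDiff > minDiff
  regions[keep]
}
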