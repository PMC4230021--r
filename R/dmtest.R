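#' Genome-wide per-site differential methylation test
#'
#' Fits the beta-binomial regression (full model, and reduced model without
#' the test factor) at every site of a [MethCounts-class] object and
#' computes the per-site likelihood-ratio p-value. Untestable sites --
#' where zero-coverage samples leave the design rank deficient or leave a
#' level of the test factor without coverage -- get `pRaw = NA`.
#'
#' For a single-column test factor the two groups are summarised per site
#' by pooled (coverage-weighted) methylation levels: group A are the
#' samples with a 1 in the test-factor column, group B the rest.
#'
#' @param counts a [MethCounts-class] object.
#' @param design samples x factors model matrix of 0/1 entries with named
#'   columns, first column the intercept (as read by [readDesign()]);
#'   row order must match `colnames(counts)`.
#' @param testFactor name(s) of the design column(s) tested.
#' @return a `GRanges`, one range per site (same order as `counts`), with
#'   metadata columns `context`, `pRaw`, `pCombined` (`NA` until
#'   [adjustPvalues()]), `pAdj`, `levelA`, `levelB`, `totalA`, `methA`,
#'   `totalB`, `methB`, and `converged`.
#' @examples
#' sim <- simulateDataset(simParams(nSites = 60, nRegions = 1), seed = 1)
#' res <- dmTest(sim$counts, sim$design, "case")
#' head(res$pRaw)
#' @seealso [adjustPvalues()], [mergeDMRegions()], [dmPipeline()]
#' @export
dmTest <- function(counts, design, testFactor) {
  stopifnot(is(counts, "MethCounts"))
  design <- .checkDesign(design)
  if (!is.null(rownames(design)) &&
      !identical(rownames(design), colnames(counts)))
    stop("design samples do not match counts samples (same names, same order)")
  if (nrow(design) != ncol(counts))
    stop("design has ", nrow(design), " rows but counts has ",
         ncol(counts), " samples")
  drop <- .dropColsFor(design, testFactor)

  tot <- totalReads(counts)
  met <- methReads(counts)
  fit <- .fitSitesCpp(tot, met, design, drop)

  stat <- pmax(0, 2 * (fit$llFull - fit$llRed))
  p <- pchisq(stat, df = length(drop), lower.tail = FALSE)
  p[!fit$testable | !is.finite(fit$llFull) | !is.finite(fit$llRed)] <- NA_real_

  gr <- SummarizedExperiment::rowRanges(counts)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(GenomicRanges::start(gr), width = 1L),
    strand = GenomicRanges::strand(gr))
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(gr)
  out$context <- gr$context
  out$pRaw <- p
  out$pCombined <- NA_real_
  out$pAdj <- NA_real_

  if (length(drop) == 1L) {
    grpA <- design[, drop] == 1
  } else {
    grpA <- rep(NA, nrow(design))
  }
  if (!anyNA(grpA)) {
    totalA <- as.integer(rowSums(tot[, grpA, drop = FALSE]))
    methA <- as.integer(rowSums(met[, grpA, drop = FALSE]))
    totalB <- as.integer(rowSums(tot[, !grpA, drop = FALSE]))
    methB <- as.integer(rowSums(met[, !grpA, drop = FALSE]))
    out$levelA <- ifelse(totalA > 0L, methA / totalA, NA_real_)
    out$levelB <- ifelse(totalB > 0L, methB / totalB, NA_real_)
    out$totalA <- totalA
    out$methA <- methA
    out$totalB <- totalB
    out$methB <- methB
  } else {
    out$levelA <- out$levelB <- NA_real_
    out$totalA <- out$methA <- out$totalB <- out$methB <- NA_integer_
  }
  out$converged <- fit$convFull & fit$convRed
  out
}
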