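#' MethCounts: methylation read counts with genomic coordinates
#'
#' An S4 container for per-site bisulfite sequencing counts: one row per
#' cytosine site (CpG, CHH, CHG, ...), one column per sample, with two
#' integer assays \code{"total"} (reads covering the site) and \code{"meth"}
#' (reads indicating methylation). It extends
#' \linkS4class{RangedSummarizedExperiment}; the row ranges are width-1
#' positions carrying the site strand and a \code{context} metadata column.
#'
#' Sites on opposite strands at the same position are kept as independent
#' rows (strand collapsing, if wanted, is an upstream data-preparation
#' step). Rows are stored sorted by (chromosome, position, strand) and
#' duplicate site keys are rejected.
#'
#' @slot .
#'   inherits all slots from \linkS4class{RangedSummarizedExperiment}.
#'
#' @seealso [readMethCounts()], [totalReads()], [methReads()]
#' @export
setClass("MethCounts", contains = "RangedSummarizedExperiment")

.orderSites <- function(chrom, pos, strand) {
  order(as.integer(factor(chrom, levels = sort(unique(chrom)))),
        pos, match(strand, c("+", "-")))
}

setValidity("MethCounts", function(object) {
  msg <- character()
  if (!all(c("total", "meth") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'total' and 'meth' are required")
  tot <- SummarizedExperiment::assay(object, "total")
  met <- SummarizedExperiment::assay(object, "meth")
  if (any(tot < 0) || any(met < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (any(met > tot))
    msg <- c(msg, "meth count exceeds total count")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (any(GenomicRanges::width(rr) != 1L))
      msg <- c(msg, "sites must be width-1 positions")
    if (is.null(rr$context))
      msg <- c(msg, "rowRanges must carry a 'context' column")
    st <- as.character(GenomicRanges::strand(rr))
    if (!all(st %in% c("+", "-")))
      msg <- c(msg, "site strand must be '+' or '-'")
    key <- paste(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr), st, sep = ":")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate site keys")
    o <- .orderSites(as.character(GenomicRanges::seqnames(rr)),
                     GenomicRanges::start(rr), st)
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "sites must be sorted by (chrom, pos, strand)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethCounts object
#'
#' @param total,meth integer matrices, sites x samples, of covering reads
#'   and reads indicating methylation (`0 <= meth <= total`).
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based site positions.
#' @param strand site strand, `"+"` or `"-"` (recycled).
#' @param context site context label such as `"CpG"` (recycled).
#' @param sampleNames sample names; defaults to `colnames(total)`.
#'
#' @details Rows are sorted by (chromosome, position, strand) on
#'   construction; chromosomes order naturally (chr2 before chr10).
#'
#' @return a [MethCounts-class] object.
#' @examples
#' mc <- MethCounts(total = matrix(c(5L, 4L), 1), meth = matrix(c(2L, 4L), 1),
#'                  chrom = "chr1", pos = 108L,
#'                  sampleNames = c("s1", "s2"))
#' totalReads(mc)
#' @export
MethCounts <- function(total, meth, chrom, pos, strand = "+",
                       context = "CpG", sampleNames = colnames(total)) {
  total <- as.matrix(total)
  meth <- as.matrix(meth)
  storage.mode(total) <- "integer"
  storage.mode(meth) <- "integer"
  n <- nrow(total)
  strand <- rep_len(strand, n)
  context <- rep_len(context, n)
  if (is.null(sampleNames))
    sampleNames <- paste0("sample", seq_len(ncol(total)))
  o <- .orderSites(chrom, pos, strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[o],
    ranges = IRanges::IRanges(start = as.integer(pos)[o], width = 1L),
    strand = strand[o], context = context[o])
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevelsInUse(gr))
  total <- total[o, , drop = FALSE]
  meth <- meth[o, , drop = FALSE]
  colnames(total) <- colnames(meth) <- sampleNames
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(total = total, meth = meth), rowRanges = gr)
  new("MethCounts", se)
}

#' @rdname totalReads
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname totalReads
#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))

#' @rdname totalReads
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname totalReads
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' Accessors for MethCounts assays
#'
#' `totalReads()` and `methReads()` return the sites x samples count
#' matrices; `methLevels()` returns per-sample methylation-level estimates
#' `meth/total` (`NA` where a sample has no coverage); `siteKeys()` returns
#' the `"chrom:pos:strand:context"` key of every site.
#'
#' @param x a [MethCounts-class] object.
#' @return a matrix (counts, levels) or character vector (keys).
#' @aliases totalReads methReads methLevels siteKeys
#' @export
setMethod("totalReads", "MethCounts", function(x)
  SummarizedExperiment::assay(x, "total"))

#' @rdname totalReads
#' @export
setMethod("methReads", "MethCounts", function(x)
  SummarizedExperiment::assay(x, "meth"))

#' @rdname totalReads
#' @export
setMethod("methLevels", "MethCounts", function(x) {
  tot <- SummarizedExperiment::assay(x, "total")
  lev <- SummarizedExperiment::assay(x, "meth") / tot
  lev[tot == 0L] <- NA_real_
  lev
})

#' @rdname totalReads
#' @export
setMethod("siteKeys", "MethCounts", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  paste(as.character(GenomicRanges::seqnames(rr)),
        GenomicRanges::start(rr),
        as.character(GenomicRanges::strand(rr)),
        rr$context, sep = ":")
})

setMethod("show", "MethCounts", function(object) {
  cat("MethCounts:", nrow(object), "sites x", ncol(object), "samples\n")
  callNextMethod()
})
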