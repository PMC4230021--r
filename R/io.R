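#' Read a methylation counts table
#'
#' The counts dialect is a plain whitespace-separated text table. The
#' first line holds the sample names. Every following line starts with a
#' colon-delimited site key `chrom:pos:strand:context` (1-based position,
#' strand `+` or `-`) followed by one pair of integers per sample:
#' total reads, then methylated reads. Example:
#' \preformatted{s1 s2
#' chr1:108:+:CpG 5 2 4 4}
#' Validation failures (malformed key, meth > total, wrong field count,
#' duplicate site) report the offending line number.
#'
#' @param path file path.
#' @return a [MethCounts-class] object.
#' @seealso [writeMethCounts()]
#' @export
readMethCounts <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty counts file: ", path)
  samples <- scan(text = lines[1L], what = character(), quiet = TRUE)
  if (!length(samples)) stop("no sample names in counts header")
  s <- length(samples)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  if (!n) {
    return(MethCounts(matrix(integer(), 0L, s),
                      matrix(integer(), 0L, s),
                      chrom = character(), pos = integer(),
                      sampleNames = samples))
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 1L + 2L * s)
  if (length(bad))
    stop("wrong field count (expected ", 1L + 2L * s, ") at line ",
         bad[1L] + 1L)
  flat <- unlist(fields, use.names = FALSE)
  mat <- matrix(flat, nrow = n, byrow = TRUE)
  keyparts <- strsplit(mat[, 1L], ":", fixed = TRUE)
  badkey <- which(lengths(keyparts) != 4L)
  if (length(badkey))
    stop("malformed site key '", mat[badkey[1L], 1L], "' at line ",
         badkey[1L] + 1L)
  km <- matrix(unlist(keyparts, use.names = FALSE), nrow = n, byrow = TRUE)
  pos <- suppressWarnings(as.integer(km[, 2L]))
  badpos <- which(is.na(pos) | pos < 1L)
  if (length(badpos))
    stop("invalid position in site key at line ", badpos[1L] + 1L)
  badstr <- which(!km[, 3L] %in% c("+", "-"))
  if (length(badstr))
    stop("invalid strand '", km[badstr[1L], 3L], "' at line ",
         badstr[1L] + 1L)
  cnt <- suppressWarnings(
    matrix(as.integer(mat[, -1L, drop = FALSE]), nrow = n))
  badint <- which(apply(is.na(cnt) , 1L, any) | apply(cnt < 0, 1L, any))
  if (length(badint))
    stop("counts must be nonnegative integers at line ", badint[1L] + 1L)
  tot <- cnt[, seq(1L, 2L * s, by = 2L), drop = FALSE]
  met <- cnt[, seq(2L, 2L * s, by = 2L), drop = FALSE]
  badmn <- which(apply(met > tot, 1L, any))
  if (length(badmn))
    stop("meth exceeds total at line ", badmn[1L] + 1L)
  dup <- which(duplicated(mat[, 1L]))
  if (length(dup))
    stop("duplicate site '", mat[dup[1L], 1L], "' at line ", dup[1L] + 1L)
  MethCounts(tot, met, chrom = km[, 1L], pos = pos, strand = km[, 3L],
             context = km[, 4L], sampleNames = samples)
}

#' Write a methylation counts table
#'
#' Writes the dialect read by [readMethCounts()]; the round trip
#' reproduces the object exactly.
#'
#' @param counts a [MethCounts-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMethCounts <- function(counts, path) {
  tot <- totalReads(counts)
  met <- methReads(counts)
  s <- ncol(tot)
  inter <- matrix(NA_integer_, nrow(tot), 2L * s)
  if (s) {
    inter[, seq(1L, 2L * s, by = 2L)] <- tot
    inter[, seq(2L, 2L * s, by = 2L)] <- met
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(tot), collapse = "\t"), con)
  if (nrow(tot))
    writeLines(paste(siteKeys(counts),
                     apply(inter, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  invisible(path)
}

#' Read a design matrix
#'
#' The design dialect: a header line of factor names (the first must be
#' the explicit intercept column, conventionally named `"base"`; it is
#' never added silently), then one line per sample: the sample name
#' followed by one 0/1 entry per factor. The matrix must have full column
#' rank; when a [MethCounts-class] object is supplied its sample names
#' must match the design rows exactly and in order.
#'
#' @param path file path.
#' @param counts optional `MethCounts` to validate samples against.
#' @return a samples x factors numeric matrix with dimnames.
#' @export
readDesign <- function(path, counts = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("design file needs a header and rows")
  factors <- scan(text = lines[1L], what = character(), quiet = TRUE)
  t <- length(factors)
  fields <- strsplit(trimws(lines[-1L]), "[ \t]+")
  bad <- which(lengths(fields) != t + 1L)
  if (length(bad))
    stop("wrong field count in design at line ", bad[1L] + 1L)
  mat <- matrix(unlist(fields, use.names = FALSE),
                nrow = length(fields), byrow = TRUE)
  samples <- mat[, 1L]
  ent <- mat[, -1L, drop = FALSE]
  if (!all(ent %in% c("0", "1"))) {
    badrow <- which(apply(!matrix(ent %in% c("0", "1"), nrow(ent)), 1L,
                          any))[1L]
    stop("non-binary design entry at line ", badrow + 1L)
  }
  X <- matrix(as.numeric(ent), nrow = nrow(ent),
              dimnames = list(samples, factors))
  if (qr(X)$rank < t)
    stop("design matrix is rank deficient")
  if (!is.null(counts) && !identical(rownames(X), colnames(counts)))
    stop("design samples do not match counts samples (same names, same order)")
  X
}

#' Write a design matrix
#'
#' Writes the dialect read by [readDesign()].
#'
#' @param design samples x factors matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(design), collapse = "\t"), con)
  writeLines(paste(rownames(design),
                   apply(format(design, trim = TRUE), 1L, paste,
                         collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write per-site results
#'
#' Tab-delimited, header-free, BED-sorted: chrom, start (0-based, pos-1),
#' end (start+1), `context:strand`, raw p, combined p, adjusted p, group-A
#' pooled level, group-B pooled level, then the pooled group counts
#' totalA, methA, totalB, methB (so region summaries can be computed from
#' this table alone). Untestable sites carry `NA` in the p-value fields.
#'
#' @param siteRes the `GRanges` from [dmTest()] / [adjustPvalues()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSiteResults()]
#' @export
writeSiteResults <- function(siteRes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(siteRes)) {
    o <- .orderSites(as.character(GenomicRanges::seqnames(siteRes)),
                     GenomicRanges::start(siteRes),
                     as.character(GenomicRanges::strand(siteRes)))
    x <- siteRes[o]
    lines <- paste(as.character(GenomicRanges::seqnames(x)),
                   GenomicRanges::start(x) - 1L,
                   GenomicRanges::start(x),
                   paste(x$context, as.character(GenomicRanges::strand(x)),
                         sep = ":"),
                   .fmtNum(x$pRaw), .fmtNum(x$pCombined), .fmtNum(x$pAdj),
                   .fmtNum(x$levelA), .fmtNum(x$levelB),
                   ifelse(is.na(x$totalA), "NA", x$totalA),
                   ifelse(is.na(x$methA), "NA", x$methA),
                   ifelse(is.na(x$totalB), "NA", x$totalB),
                   ifelse(is.na(x$methB), "NA", x$methB),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read per-site results
#'
#' Parses the table written by [writeSiteResults()] back into the
#' `GRanges` layout used by the pipeline.
#'
#' @param path file path.
#' @return a `GRanges` with the [dmTest()] metadata columns.
#' @export
readSiteResults <- function(path) {
  cols <- c("chrom", "start", "end", "key", "pRaw", "pCombined", "pAdj",
            "levelA", "levelB", "totalA", "methA", "totalB", "methB")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  tab <- read.table(path, sep = "\t", col.names = cols,
                    colClasses = c("character", "integer", "integer",
                                   "character", rep("numeric", 5L),
                                   rep("integer", 4L)),
                    na.strings = "NA")
  ks <- strsplit(tab$key, ":", fixed = TRUE)
  context <- vapply(ks, `[`, "", 1L)
  strand <- vapply(ks, `[`, "", 2L)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, width = 1L),
    strand = strand)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevelsInUse(gr))
  gr$context <- context
  gr$pRaw <- tab$pRaw
  gr$pCombined <- tab$pCombined
  gr$pAdj <- tab$pAdj
  gr$levelA <- tab$levelA
  gr$levelB <- tab$levelB
  gr$totalA <- tab$totalA
  gr$methA <- tab$methA
  gr$totalB <- tab$totalB
  gr$methB <- tab$methB
  o <- .orderSites(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr),
                   as.character(GenomicRanges::strand(gr)))
  gr[o]
}

#' Write DM regions as BED6+1
#'
#' Half-open 0-based BED with columns: chrom, start, end, name
#' `dmr:<nCpGs>:<nSig>`, score = region log-odds ratio, strand `"."`, and
#' an extra column holding the minimum methylation difference. Output is
#' BED-sorted regardless of input order.
#'
#' @param regions a summarised region `GRanges` (see [summarizeRegions()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions)) {
    o <- order(as.character(GenomicRanges::seqnames(regions)),
               GenomicRanges::start(regions))
    x <- regions[o]
    lines <- paste(as.character(GenomicRanges::seqnames(x)),
                   GenomicRanges::start(x) - 1L,
                   GenomicRanges::end(x),
                   sprintf("dmr:%d:%d", x$nCpGs, x$nSig),
                   .fmtNum(x$logOdds), ".",
                   .fmtNum(x$minMethDiff), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a DM-region BED file
#'
#' Parses the BED6+1 written by [writeRegionsBed()].
#'
#' @param path file path.
#' @return a region `GRanges` with `nCpGs`, `nSig`, `logOdds`,
#'   `minMethDiff`.
#' @export
readRegionsBed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(GenomicRanges::GRanges())
  tab <- read.table(path, sep = "\t",
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand", "minMethDiff"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character",
                                   "numeric"),
                    na.strings = "NA")
  parts <- strsplit(tab$name, ":", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
  gr$nSig <- as.integer(vapply(parts, `[`, "", 3L))
  gr$nCpGs <- as.integer(vapply(parts, `[`, "", 2L))
  gr$logOdds <- tab$score
  gr$minMethDiff <- tab$minMethDiff
  gr
}
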