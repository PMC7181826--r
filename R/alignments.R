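#' Read aligned DRIP-seq reads for one condition
#'
#' Consumes the output of the upstream alignment step: either a
#' coordinate-sorted, indexed BAM or a BED3 file of aligned read spans.
#' Unmapped, secondary and supplementary BAM records are always excluded,
#' matching default `samtools` counting; there is no MAPQ threshold unless
#' one is requested.  Duplicates are retained.  Strand is discarded
#' everywhere: DRIP-seq with the S9.6 antibody is an unstranded readout.
#'
#' `total_aligned` is always computed over the *whole* library with the
#' same record filter, regardless of `region`, because coverage is later
#' normalized to total library size.
#'
#' @param path BAM (sorted + indexed for region queries) or BED file.
#' @param condition `"minusOHT"` (undamaged) or `"plusOHT"` (damaged).
#' @param region Optional `c(chrom, start, end)` (0-based half-open) to
#'   restrict the returned reads.
#' @param min_mapq Minimum mapping quality for BAM records; `0` (default)
#'   applies no threshold.
#' @return An `aligned_reads` object: a list with elements `condition`,
#'   `reads` (an unstranded [GenomicRanges::GRanges] of aligned spans) and
#'   `total_aligned`.
#' @export
read_alignments <- function(path, condition = c("minusOHT", "plusOHT"),
                            region = NULL, min_mapq = 0L) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("alignment file does not exist: ", path)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (is_bam) {
    res <- read_alignments_bam(path, region, min_mapq)
  } else {
    res <- read_alignments_bed(path, region)
  }
  aligned_reads(condition, res$reads, res$total_aligned)
}

#' Construct an aligned-read set
#'
#' @param condition Condition label.
#' @param reads A `GRanges` of aligned spans (strand is reset to `*`).
#' @param total_aligned Total aligned reads in the library; must be at
#'   least the number of reads supplied (the near-anchor subset may be
#'   smaller than the library).
#' @return An `aligned_reads` object.
#' @export
aligned_reads <- function(condition = c("minusOHT", "plusOHT"), reads,
                          total_aligned = length(reads)) {
  condition <- match.arg(condition)
  stopifnot(methods::is(reads, "GRanges"))
  if (total_aligned < length(reads)) {
    stop("total_aligned (", total_aligned, ") is smaller than the number ",
         "of reads supplied (", length(reads), ")")
  }
  GenomicRanges::strand(reads) <- "*"
  structure(list(condition = condition, reads = reads,
                 total_aligned = as.integer(total_aligned)),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("aligned_reads:", x$condition, "|", length(x$reads),
      "reads in memory |", x$total_aligned, "aligned in library\n")
  invisible(x)
}

bam_flag_filter <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

read_alignments_bam <- function(path, region, min_mapq) {
  flag <- bam_flag_filter()
  mapq <- if (min_mapq > 0L) min_mapq else NA_integer_
  total <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(
      flag = flag, mapqFilter = mapq))$records
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq)
  } else {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
      stop("region query on an unindexed BAM: ", path,
           "; index it first (samtools index)")
    }
    which <- GenomicRanges::GRanges(
      region[[1L]],
      IRanges::IRanges(as.numeric(region[[2L]]) + 1,
                       as.numeric(region[[3L]])))
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq,
                                     which = which)
  }
  aln <- GenomicAlignments::readGAlignments(path, param = param)
  reads <- GenomicRanges::granges(aln)
  list(reads = reads, total_aligned = total)
}

read_alignments_bed <- function(path, region) {
  n_lines <- length(readLines(path))
  if (n_lines == 0L) {
    return(list(reads = GenomicRanges::GRanges(), total_aligned = 0L))
  }
  reads <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(reads) <- NULL
  total <- length(reads)
  if (!is.null(region)) {
    which <- GenomicRanges::GRanges(
      region[[1L]],
      IRanges::IRanges(as.numeric(region[[2L]]) + 1,
                       as.numeric(region[[3L]])))
    reads <- IRanges::subsetByOverlaps(reads, which, ignore.strand = TRUE)
  }
  list(reads = reads, total_aligned = total)
}

#' Write aligned reads as BED3
#'
#' @param x An `aligned_reads` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(x, path) {
  stopifnot(inherits(x, "aligned_reads"))
  out <- data.frame(as.character(GenomicRanges::seqnames(x$reads)),
                    GenomicRanges::start(x$reads) - 1L,
                    GenomicRanges::end(x$reads))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write aligned reads as unpaired SAM
#'
#' Emits minimal single-end records (fixed MAPQ, no sequence) so simulated
#' libraries can round-trip through BAM-based tooling.
#'
#' @param x An `aligned_reads` object.
#' @param path Output path (`.sam`).
#' @param mapq Mapping quality assigned to every record.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(x, path, mapq = 42L) {
  stopifnot(inherits(x, "aligned_reads"))
  gr <- x$reads
  lens <- GenomeInfoDb::seqlengths(gr)
  chroms <- names(lens)
  if (anyNA(lens)) {
    lens <- vapply(split(GenomicRanges::end(gr),
                         as.character(GenomicRanges::seqnames(gr))),
                   max, numeric(1))[chroms]
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", as.character(chroms),
                      as.integer(lens)))
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  w <- GenomicRanges::width(gr)
  body <- sprintf("read%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  seq_along(gr),
                  as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), as.integer(mapq), w)
  writeLines(c(header, body), path)
  invisible(path)
}
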