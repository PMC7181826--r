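#' Write a per-position signal track as bedGraph
#'
#' The value vector is interpreted as one value per genomic base starting
#' at `origin` (0-based).  Runs of equal value are merged into single
#' bedGraph intervals; zeros are written, not dropped, so the track
#' round-trips exactly through [read_track()].
#'
#' @param values Numeric vector, finite (or `NA` for explicitly missing
#'   positions, which are skipped on output).
#' @param chrom Chromosome name.
#' @param origin 0-based genomic position of `values[1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' p <- tempfile(fileext = ".bedGraph")
#' write_track(c(1, 1, 2), "chr1", 100, p)
#' readLines(p)  # chr1 100 102 1 / chr1 102 103 2
#' @export
write_track <- function(values, chrom, origin, path) {
  if (origin < 0) stop("origin must be >= 0")
  if (any(!is.finite(values) & !is.na(values))) {
    stop("track values must be finite or NA")
  }
  r <- rle(values)
  ends <- origin + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values)
  # %.17g preserves doubles bit-for-bit across the write/read round trip
  lines <- sprintf("%s\t%d\t%d\t%.17g", chrom, as.integer(starts[keep]),
                   as.integer(ends[keep]), r$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track back into a per-position vector
#'
#' Inverse of [write_track()] over the span it covers.
#'
#' @param path bedGraph file.
#' @param chrom Optional chromosome to restrict to (required when the file
#'   covers several).
#' @return A list with `chrom`, `origin` (0-based position of the first
#'   value) and `values` (one value per base; gaps between intervals are
#'   `NA`).
#' @export
read_track <- function(path, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(chrom)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  } else {
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (length(chroms) > 1L) {
      stop("track covers several chromosomes (",
           paste(chroms, collapse = ", "), "); pass `chrom`")
    }
    chrom <- chroms
  }
  if (length(gr) == 0L) {
    return(list(chrom = chrom, origin = 0L, values = numeric()))
  }
  origin <- min(GenomicRanges::start(gr)) - 1L
  span <- max(GenomicRanges::end(gr)) - origin
  values <- rep(NA_real_, span)
  for (i in seq_along(gr)) {
    idx <- (GenomicRanges::start(gr)[i] - origin):
           (GenomicRanges::end(gr)[i] - origin)
    values[idx] <- gr$score[i]
  }
  list(chrom = chrom, origin = as.integer(origin), values = values)
}
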