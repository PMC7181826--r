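#' Per-nucleotide read depth in a break-centered window
#'
#' Counts, at every base of the window `cut_pos - half_width ..
#' cut_pos + half_width` (break-relative positions `-half_width ..
#' +half_width`), the number of aligned read spans covering that base.
#' Reads only partially overlapping the window contribute at the positions
#' they cover.  Window positions falling off the chromosome start are
#' reported as zero depth.
#'
#' @param reads An [aligned_reads] object.
#' @param site One row of an `anchor_sites` table (or any list with
#'   `site_id`, `chrom`, `cut_pos`).
#' @param half_width Window half-width in nucleotides; the default 10000
#'   gives the standard 20-kb break-centered window at single-nucleotide
#'   resolution.
#' @param cov Optional precomputed coverage (`RleList` from
#'   [GenomicRanges::coverage()] over `reads$reads`); callers iterating
#'   many sites over one library pass it to avoid recomputing the pileup.
#' @return A `windowed_coverage` object: list with `site_id`, `chrom`,
#'   `cut_pos`, `half_width`, `condition` and integer `depth` of length
#'   `2 * half_width + 1`.
#' @export
window_depth <- function(reads, site, half_width = 10000L,
                         cov = NULL) {
  stopifnot(inherits(reads, "aligned_reads"))
  if (half_width < 1L) stop("half_width must be positive")
  chrom <- as.character(site$chrom)
  len <- 2L * as.integer(half_width) + 1L
  if (is.null(cov)) cov <- GenomicRanges::coverage(reads$reads)
  if (!chrom %in% names(cov)) {
    warning("chromosome ", chrom, " absent from the read set; ",
            "window depth for site ", site$site_id, " is all zero")
    depth <- integer(len)
  } else {
    rl <- cov[[chrom]]
    # 1-based genomic coordinates of the window; cut_pos is 0-based
    lo <- site$cut_pos + 1L - half_width
    hi <- site$cut_pos + 1L + half_width
    depth <- integer(len)
    from <- max(lo, 1L)
    to <- min(hi, length(rl))
    if (from <= to) {
      depth[(from - lo + 1L):(to - lo + 1L)] <-
        as.integer(S4Vectors::window(rl, start = from, end = to))
    }
  }
  structure(list(site_id = site$site_id, chrom = chrom,
                 cut_pos = as.integer(site$cut_pos),
                 half_width = as.integer(half_width),
                 condition = reads$condition, depth = depth),
            class = "windowed_coverage")
}

#' Library-size normalization of windowed depth
#'
#' Divides per-nucleotide depth (plus a pseudocount) by the total number
#' of aligned reads in the library.  A pseudocount of one read (default)
#' keeps downstream log2 ratios finite everywhere and exactly
#' antisymmetric under condition swap; `pseudocount_reads = 0` is allowed
#' for raw browser tracks, where no ratio is formed.
#'
#' @param cov A `windowed_coverage` object.
#' @param total_aligned Total aligned reads in the library; must be
#'   positive.
#' @param pseudocount_reads Pseudocount in read units added to every
#'   depth, default `1`.
#' @return A `normalized_coverage` object (as `cov` but with `normalized`
#'   instead of `depth`, plus `total_aligned` and `pseudocount`).
#' @export
normalize_coverage <- function(cov, total_aligned,
                               pseudocount_reads = 1) {
  stopifnot(inherits(cov, "windowed_coverage"))
  if (is.na(total_aligned) || total_aligned <= 0) {
    stop("total_aligned must be positive (library has no aligned reads?)")
  }
  if (pseudocount_reads < 0) stop("pseudocount_reads must be >= 0")
  structure(list(site_id = cov$site_id, chrom = cov$chrom,
                 cut_pos = cov$cut_pos, half_width = cov$half_width,
                 condition = cov$condition,
                 normalized = (cov$depth + pseudocount_reads) /
                   total_aligned,
                 total_aligned = as.integer(total_aligned),
                 pseudocount = pseudocount_reads),
            class = "normalized_coverage")
}

#' Per-nucleotide log2 fold change of damaged over undamaged coverage
#'
#' The pipeline's core transform: `log2(plus / minus)` of library-size
#' normalized coverage at each nucleotide of the break-centered window.
#' Both inputs must carry a positive pseudocount so the ratio is finite
#' everywhere.
#'
#' @param plus Normalized coverage of the damaged (+OHT) condition.
#' @param minus Normalized coverage of the undamaged (-OHT) condition.
#' @return A `fold_change_profile` object: list with `site_id`,
#'   `half_width` and `lfc` (length `2 * half_width + 1`, break-relative
#'   positions `-half_width .. +half_width`).
#' @export
log2_fold_change <- function(plus, minus) {
  stopifnot(inherits(plus, "normalized_coverage"),
            inherits(minus, "normalized_coverage"))
  if (!identical(plus$site_id, minus$site_id)) {
    stop("site mismatch: ", plus$site_id, " vs ", minus$site_id)
  }
  if (plus$half_width != minus$half_width) {
    stop("window half-width mismatch: ", plus$half_width, " vs ",
         minus$half_width)
  }
  if (plus$pseudocount <= 0 || minus$pseudocount <= 0) {
    stop("log2 fold change requires a positive pseudocount in both ",
         "conditions")
  }
  # log difference rather than log of the ratio: the same value, but
  # bit-for-bit antisymmetric under condition swap
  structure(list(site_id = plus$site_id,
                 half_width = plus$half_width,
                 lfc = log2(plus$normalized) - log2(minus$normalized)),
            class = "fold_change_profile")
}

#' Centered moving average with truncated edges
#'
#' Smooths a signal with a centered window of `window` values; at the
#' array ends the window shrinks to the available values, so the output
#' has the same length as the input and stays aligned to genomic
#' coordinates.  Used with `window = 200` for metagenes and `window = 500`
#' for browser tracks.
#'
#' @param x Numeric vector.
#' @param window Window size in positions (>= 1).  Even windows extend one
#'   position further left than right.
#' @return Numeric vector, `length(x)`.
#' @export
moving_average <- function(x, window) {
  if (window < 1L) stop("window must be >= 1")
  window <- as.integer(window)
  if (window == 1L || length(x) == 0L) return(as.numeric(x))
  n <- length(x)
  left <- (window - 1L) %/% 2L + (1L - window %% 2L)  # extra on the left
  right <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mean over consecutive non-overlapping bins
#'
#' @param x Numeric vector.
#' @param bin_size Bin width in positions (>= 1); the last bin may be
#'   shorter.
#' @return Numeric vector of `ceiling(length(x) / bin_size)` bin means.
#' @export
bin_mean <- function(x, bin_size) {
  if (bin_size < 1L) stop("bin_size must be >= 1")
  bin_size <- as.integer(bin_size)
  if (length(x) == 0L) return(numeric())
  idx <- (seq_along(x) - 1L) %/% bin_size
  as.numeric(tapply(x, idx, mean))
}

#' Break-relative positions of a window or profile
#'
#' @param half_width Window half-width in nucleotides.
#' @return Integer vector `-half_width .. +half_width`.
#' @export
relative_positions <- function(half_width) {
  seq.int(-half_width, half_width)
}
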