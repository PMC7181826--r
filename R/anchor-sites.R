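#' Read an anchor-site annotation table
#'
#' Anchor sites are AsiSI cut sites carrying the per-site metadata the
#' downstream comparisons group by: relative transcriptional activity
#' (elongating RNAPII occupancy from ChIP-seq), repair-pathway preference
#' (HR / NHEJ) and genic status.  Two on-disk layouts are accepted:
#'
#' * **BED6+3**: `chrom start end name score strand` plus three extra
#'   columns `activity`, `pathway`, `genic`.  The BED `start` (0-based) is
#'   taken as the cut position; `name` is the site id.  Strand and score
#'   are ignored (DRIP-seq here is unstranded).
#' * **TSV**: a headered tab-separated file with columns `site_id`,
#'   `chrom`, `cut_pos`, `activity`, `pathway`, `genic` (`cut_pos`
#'   0-based).
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default; BED if the file has no `site_id`
#'   header), `"bed"` or `"tsv"`.
#' @return A `data.frame` of class `anchor_sites` with columns `site_id`,
#'   `chrom`, `cut_pos`, `activity`, `pathway`, `genic`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t1008\tsiteA\t0\t+\t5.0\tHR\tintragenic",
#'              "chr1\t9000\t9008\tsiteB\t0\t-\t0.1\tNHEJ\tintergenic"), bed)
#' read_anchor_sites(bed)
#' @export
read_anchor_sites <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("anchor-site file does not exist: ", path)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || all(!nzchar(trimws(readLines(path))))) {
    warning("anchor-site file is empty: ", path)
    return(empty_anchor_sites())
  }
  if (format == "auto") {
    format <- if (grepl("site_id", first, fixed = TRUE)) "tsv" else "bed"
  }
  tab <- if (format == "bed") parse_sites_bed(path) else parse_sites_tsv(path)
  validate_anchor_sites(tab, path)
}

empty_anchor_sites <- function() {
  structure(
    data.frame(site_id = character(), chrom = character(),
               cut_pos = integer(), activity = numeric(),
               pathway = character(), genic = character(),
               stringsAsFactors = FALSE),
    class = c("anchor_sites", "data.frame"))
}

parse_sites_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 9L) {
    need <- c("activity", "pathway", "genic")
    stop("BED6+3 anchor-site file ", path, " has ", ncol(tab),
         " columns; columns 7-9 (",
         paste(need[seq_len(min(3L, 9L - ncol(tab)))], collapse = ", "),
         " ...) are required")
  }
  data.frame(site_id = tab[[4L]], chrom = tab[[1L]],
             cut_pos = suppressWarnings(as.integer(tab[[2L]])),
             activity_raw = tab[[7L]], pathway = tab[[8L]],
             genic = tab[[9L]], stringsAsFactors = FALSE)
}

parse_sites_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#")
  need <- c("site_id", "chrom", "cut_pos", "activity", "pathway", "genic")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("anchor-site TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(site_id = tab$site_id, chrom = tab$chrom,
             cut_pos = suppressWarnings(as.integer(tab$cut_pos)),
             activity_raw = tab$activity, pathway = tab$pathway,
             genic = tab$genic, stringsAsFactors = FALSE)
}

validate_anchor_sites <- function(tab, path) {
  activity <- suppressWarnings(as.numeric(tab$activity_raw))
  bad <- which(is.na(activity) | !is.finite(activity))
  if (length(bad) > 0L) {
    stop("non-numeric or non-finite activity value ",
         dQuote(tab$activity_raw[bad[1L]]), " at data line ", bad[1L],
         " of ", path)
  }
  if (any(activity < 0)) {
    stop("negative activity at data line ", which(activity < 0)[1L],
         " of ", path)
  }
  if (anyNA(tab$cut_pos) || any(tab$cut_pos < 0L)) {
    stop("malformed cut position at data line ",
         which(is.na(tab$cut_pos) | tab$cut_pos < 0L)[1L], " of ", path)
  }
  dup <- duplicated(tab$site_id)
  if (any(dup)) {
    stop("duplicated site_id in ", path, ": ",
         paste(unique(tab$site_id[dup]), collapse = ", "))
  }
  pathway <- normalize_enum(tab$pathway, c("HR", "NHEJ", "unclassified"),
                            "pathway", path)
  genic <- normalize_enum(tab$genic, c("intragenic", "intergenic"),
                          "genic", path)
  structure(
    data.frame(site_id = tab$site_id, chrom = tab$chrom,
               cut_pos = as.integer(tab$cut_pos), activity = activity,
               pathway = pathway, genic = genic, stringsAsFactors = FALSE),
    class = c("anchor_sites", "data.frame"))
}

normalize_enum <- function(x, levels, what, path) {
  idx <- match(toupper(x), toupper(levels))
  if (anyNA(idx)) {
    stop("invalid ", what, " value ", dQuote(x[which(is.na(idx))[1L]]),
         " in ", path, " (expected one of: ",
         paste(levels, collapse = ", "), ")")
  }
  levels[idx]
}

#' Write an anchor-site table as BED6+3
#'
#' Inverse of [read_anchor_sites()]; the cut position becomes the BED start
#' and the interval is given the 8-bp width of the AsiSI recognition
#' sequence.
#'
#' @param sites An `anchor_sites` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_sites <- function(sites, path) {
  stopifnot(inherits(sites, "anchor_sites"))
  out <- data.frame(sites$chrom, sites$cut_pos, sites$cut_pos + 8L,
                    sites$site_id, 0L, ".", sites$activity, sites$pathway,
                    sites$genic)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
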