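#' Metagene curves of break-centered fold change
#'
#' Each site's profile is smoothed with a centered moving average
#' (default 200 nt) and the smoothed curves are averaged positionwise
#' within each group (unweighted across sites).
#'
#' @param profiles List of `fold_change_profile` objects sharing one
#'   half-width.
#' @param labels Group label per profile (character or factor, recycled
#'   to a single group when of length 1).
#' @param smooth_window Moving-average window in nucleotides.
#' @return A `metagene_curves` data frame in long format: `group`,
#'   `rel_pos`, `mean_lfc`, `n_sites`.
#' @export
metagene <- function(profiles, labels = "all", smooth_window = 200L) {
  stopifnot(length(profiles) > 0L)
  hw <- vapply(profiles, `[[`, integer(1), "half_width")
  if (length(unique(hw)) != 1L) {
    stop("profiles have mixed half-widths: ",
         paste(unique(hw), collapse = ", "))
  }
  if (length(labels) == 1L) labels <- rep(labels, length(profiles))
  if (length(labels) != length(profiles)) {
    stop("need one group label per profile")
  }
  labels <- as.character(labels)
  rel <- relative_positions(hw[1L])
  smoothed <- lapply(profiles, function(p) {
    moving_average(p$lfc, smooth_window)
  })
  groups <- split(smoothed, labels)
  out <- lapply(names(groups), function(g) {
    m <- Reduce(`+`, groups[[g]]) / length(groups[[g]])
    data.frame(group = g, rel_pos = rel, mean_lfc = m,
               n_sites = length(groups[[g]]), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("metagene_curves", "data.frame"))
}

#' Activity-ordered heatmap matrix of binned fold change
#'
#' One row per site, ordered by descending transcriptional activity (ties
#' broken by site id) with no clustering; one column per position bin
#' across the break-centered window, each value the mean fold change of
#' its bin.
#'
#' @param profiles List of `fold_change_profile` objects, one per site.
#' @param sites Matching `anchor_sites` table.
#' @param bin_size Bin width in nucleotides, default 200.
#' @return A `heatmap_matrix` object: list with `matrix` (rows named by
#'   site id), `row_meta` (site id + activity in row order) and `bin_mid`
#'   (break-relative center of each column's bin).
#' @export
heatmap_matrix <- function(profiles, sites, bin_size = 200L) {
  ids <- vapply(profiles, `[[`, character(1), "site_id")
  missing <- setdiff(sites$site_id, ids)
  extra <- setdiff(ids, sites$site_id)
  if (length(missing) || length(extra)) {
    stop("site/profile mismatch; sites without profile: ",
         paste(missing, collapse = ", "), "; orphan profiles: ",
         paste(extra, collapse = ", "))
  }
  ord <- order(-sites$activity, sites$site_id)
  sites <- sites[ord, , drop = FALSE]
  profiles <- profiles[match(sites$site_id, ids)]
  rows <- lapply(profiles, function(p) bin_mean(p$lfc, bin_size))
  mat <- do.call(rbind, rows)
  rownames(mat) <- sites$site_id
  hw <- profiles[[1L]]$half_width
  rel <- relative_positions(hw)
  starts <- seq(1L, length(rel), by = bin_size)
  ends <- pmin(starts + bin_size - 1L, length(rel))
  structure(list(matrix = mat,
                 row_meta = data.frame(site_id = sites$site_id,
                                       activity = sites$activity,
                                       stringsAsFactors = FALSE),
                 bin_mid = (rel[starts] + rel[ends]) / 2),
            class = "heatmap_matrix")
}

#' Paired browser-style coverage tracks for one site
#'
#' For single-site genome-browser views the two conditions are shown as
#' separate normalized coverage tracks (no ratio is formed), each
#' smoothed with a 500-nt moving average and then binned into 200-nt
#' bins.  Typically built over a 200-kb window (`half_width = 1e5`).
#'
#' @param minus,plus `normalized_coverage` objects over the same window;
#'   a zero pseudocount is fine here.
#' @param smooth_window Moving-average window in nucleotides.
#' @param bin_size Bin width in nucleotides.
#' @return A `browser_tracks` object: list with `site_id`, `half_width`,
#'   `bin_mid` and numeric `minus_track`, `plus_track`.
#' @export
browser_tracks <- function(minus, plus, smooth_window = 500L,
                           bin_size = 200L) {
  stopifnot(inherits(minus, "normalized_coverage"),
            inherits(plus, "normalized_coverage"))
  if (!identical(minus$site_id, plus$site_id) ||
      minus$half_width != plus$half_width ||
      minus$cut_pos != plus$cut_pos) {
    stop("minus and plus tracks cover different regions")
  }
  pipe <- function(x) bin_mean(moving_average(x, smooth_window), bin_size)
  rel <- relative_positions(minus$half_width)
  starts <- seq(1L, length(rel), by = bin_size)
  ends <- pmin(starts + bin_size - 1L, length(rel))
  structure(list(site_id = minus$site_id,
                 half_width = minus$half_width,
                 bin_mid = (rel[starts] + rel[ends]) / 2,
                 minus_track = pipe(minus$normalized),
                 plus_track = pipe(plus$normalized)),
            class = "browser_tracks")
}

#' Build per-site fold-change profiles for a whole site table
#'
#' Convenience wrapper running [window_depth()], [normalize_coverage()]
#' and [log2_fold_change()] over every anchor site.
#'
#' @param minus_reads,plus_reads [aligned_reads] for the two conditions.
#' @param sites An `anchor_sites` table.
#' @param half_width Window half-width, default 10000 (20-kb window).
#' @param pseudocount Pseudocount in reads, default 1.
#' @return Named list of `fold_change_profile` objects (names = site id).
#' @export
fold_change_profiles <- function(minus_reads, plus_reads, sites,
                                 half_width = 10000L, pseudocount = 1) {
  cov_m <- GenomicRanges::coverage(minus_reads$reads)
  cov_p <- GenomicRanges::coverage(plus_reads$reads)
  profs <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    dm <- window_depth(minus_reads, site, half_width, cov = cov_m)
    dp <- window_depth(plus_reads, site, half_width, cov = cov_p)
    log2_fold_change(
      normalize_coverage(dp, plus_reads$total_aligned, pseudocount),
      normalize_coverage(dm, minus_reads$total_aligned, pseudocount))
  })
  names(profs) <- sites$site_id
  profs
}
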