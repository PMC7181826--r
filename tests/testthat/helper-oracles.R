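# Independent brute-force oracles.  These deliberately share no code with
# the package: per-base counting by loop, smoothing by sapply/mean,
# rank-sum p by full enumeration of group assignments.

bf_window_depth <- function(starts0, ends0, cut_pos, half_width) {
  # starts0/ends0: 0-based half-open read spans on one chromosome
  pos <- (cut_pos - half_width):(cut_pos + half_width)  # 0-based bases
  vapply(pos, function(p) sum(starts0 <= p & p < ends0), numeric(1))
}

bf_moving_average <- function(x, window) {
  n <- length(x)
  left <- (window - 1L) %/% 2L + (1L - window %% 2L)
  right <- (window - 1L) %/% 2L
  sapply(seq_len(n), function(i) {
    mean(x[max(1L, i - left):min(n, i + right)])
  })
}

bf_bin_mean <- function(x, bin_size) {
  groups <- split(x, ceiling(seq_along(x) / bin_size))
  unname(vapply(groups[order(as.integer(names(groups)))], mean,
                numeric(1)))
}

# Exact Mann-Whitney p by enumerating every assignment of the pooled
# observations to group x, with midranks for ties.
bf_rank_sum_exact <- function(x, y, alternative) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  eps <- 1e-9
  switch(alternative,
         greater = mean(u_all >= u_obs - eps),
         less = mean(u_all <= u_obs + eps),
         two.sided = min(1, 2 * min(mean(u_all >= u_obs - eps),
                                    mean(u_all <= u_obs + eps))))
}

bf_metagene <- function(lfc_list, labels, smooth_window) {
  smoothed <- lapply(lfc_list, bf_moving_average, window = smooth_window)
  lapply(split(seq_along(smoothed), labels), function(idx) {
    rowMeans(do.call(cbind, smoothed[idx]))
  })
}

# Minimal fold_change_profile constructor for tests operating on bare
# arrays.
fcp <- function(lfc, site_id = "s", half_width = (length(lfc) - 1L) %/% 2L) {
  stopifnot(length(lfc) == 2L * half_width + 1L)
  structure(list(site_id = site_id, half_width = as.integer(half_width),
                 lfc = as.numeric(lfc)),
            class = "fold_change_profile")
}

random_reads <- function(n, chrom_len, read_len = 50L,
                         chrom = "chrT") {
  starts <- sample.int(chrom_len - read_len, n, replace = TRUE)
  aligned_reads("minusOHT",
                GenomicRanges::GRanges(
                  chrom, IRanges::IRanges(start = starts, width = read_len)))
}

make_site <- function(site_id = "s1", chrom = "chrT", cut_pos = 1000L,
                      activity = 1, pathway = "HR",
                      genic = "intragenic") {
  structure(data.frame(site_id = site_id, chrom = chrom,
                       cut_pos = as.integer(cut_pos), activity = activity,
                       pathway = pathway, genic = genic,
                       stringsAsFactors = FALSE),
            class = c("anchor_sites", "data.frame"))
}

make_scores <- function(score, activity = seq_along(score),
                        pathway = rep(c("HR", "NHEJ"),
                                      length.out = length(score)),
                        genic = rep(c("intragenic", "intergenic"),
                                    length.out = length(score))) {
  sites <- data.frame(site_id = sprintf("s%02d", seq_along(score)),
                      activity = activity, stringsAsFactors = FALSE)
  structure(data.frame(site_id = sites$site_id, score = score,
                       activity = activity, pathway = pathway,
                       genic = genic,
                       activity_class = classify_activity(sites),
                       stringsAsFactors = FALSE),
            class = c("site_scores", "data.frame"))
}

sites_bed_lines <- function() {
  c("chrT\t1000\t1008\tsiteA\t0\t+\t5.0\tHR\tintragenic",
    "chrT\t9000\t9008\tsiteB\t0\t-\t0.1\tNHEJ\tintergenic")
}
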