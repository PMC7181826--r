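#' Render metagene curves
#'
#' Writes the exact data matrix (long TSV) next to a simple line plot so
#' the figure is regenerable and diffable.
#'
#' @param curves A `metagene_curves` data frame from [metagene()].
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.png`.
#' @return Character vector of the files written, invisibly.
#' @export
render_metagene <- function(curves, path_prefix) {
  if (nrow(curves) == 0L) stop("no metagene curves to render")
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  utils::write.table(curves, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$rel_pos, y = .data$mean_lfc,
                                    colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to break (nt)",
                  y = "mean log2(+OHT / -OHT)") +
    ggplot2::theme_minimal()
  save_png(p, png)
  invisible(c(tsv, png))
}

#' Render an activity-ordered heatmap
#'
#' @param hm A `heatmap_matrix` object.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` (matrix with
#'   row metadata) and `<prefix>.png`.
#' @return Files written, invisibly.
#' @export
render_heatmap <- function(hm, path_prefix) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  if (nrow(hm$matrix) == 0L) stop("empty heatmap matrix")
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  out <- cbind(hm$row_meta, as.data.frame(hm$matrix))
  colnames(out) <- c("site_id", "activity",
                     paste0("bin_", hm$bin_mid))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- data.frame(
    site = factor(rep(hm$row_meta$site_id, ncol(hm$matrix)),
                  levels = rev(hm$row_meta$site_id)),
    rel_pos = rep(hm$bin_mid, each = nrow(hm$matrix)),
    lfc = as.vector(hm$matrix))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$rel_pos, y = .data$site,
                                    fill = .data$lfc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "position relative to break (nt)", y = NULL,
                  fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  save_png(p, png)
  invisible(c(tsv, png))
}

#' Render induction-score boxplots for one grouping
#'
#' @param scores A `site_scores` table.
#' @param group_var `"activity_class"`, `"pathway"` or `"genic"`.
#' @param path_prefix Output prefix.
#' @return Files written, invisibly.
#' @export
render_boxplot <- function(scores, group_var, path_prefix) {
  if (nrow(scores) == 0L) stop("no scores to render")
  stopifnot(group_var %in% names(scores))
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  long <- data.frame(group = as.character(scores[[group_var]]),
                     score = scores$score, site_id = scores$site_id)
  utils::write.table(long, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group,
                                          y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = group_var, y = "induction score (mean log2 FC)") +
    ggplot2::theme_minimal()
  save_png(p, png)
  invisible(c(tsv, png))
}

#' Render the activity-score correlation scatter
#'
#' @param scores A `site_scores` table.
#' @param corr Result of [correlate_activity()].
#' @param path_prefix Output prefix.
#' @return Files written, invisibly.
#' @export
render_correlation <- function(scores, corr, path_prefix) {
  if (nrow(scores) == 0L) stop("no scores to render")
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  out <- scores[, c("site_id", "activity", "score")]
  out$fitted <- corr$intercept + corr$slope * out$activity
  utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- ggplot2::ggplot(out, ggplot2::aes(x = .data$activity,
                                         y = .data$score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = corr$intercept, slope = corr$slope,
                         colour = "red") +
    ggplot2::labs(x = "relative transcriptional activity",
                  y = "induction score (mean log2 FC)",
                  subtitle = sprintf("r = %.3f, p = %.2e, n = %d",
                                     corr$r, corr$p, corr$n)) +
    ggplot2::theme_minimal()
  save_png(p, png)
  invisible(c(tsv, png))
}

#' Render a paired browser-track panel
#'
#' @param tracks A `browser_tracks` object.
#' @param path_prefix Output prefix.
#' @return Files written, invisibly.
#' @export
render_browser <- function(tracks, path_prefix) {
  stopifnot(inherits(tracks, "browser_tracks"))
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  long <- data.frame(
    rel_pos = rep(tracks$bin_mid, 2L),
    condition = rep(c("-OHT", "+OHT"), each = length(tracks$bin_mid)),
    coverage = c(tracks$minus_track, tracks$plus_track))
  utils::write.table(long, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_pos,
                                          y = .data$coverage)) +
    ggplot2::geom_area() +
    ggplot2::facet_wrap(~condition, ncol = 1L) +
    ggplot2::labs(x = "position relative to break (nt)",
                  y = "normalized coverage",
                  title = tracks$site_id) +
    ggplot2::theme_minimal()
  save_png(p, png)
  invisible(c(tsv, png))
}

save_png <- function(plot, path, width = 7, height = 4.5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 120)
  on.exit(grDevices::dev.off())
  print(plot)
}
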