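#' Default pipeline configuration
#'
#' All knobs of the end-to-end analysis in one nested list, mirrored by
#' the YAML config file.  Unknown keys in a user config are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    paths = list(sites = NULL, reads_minus = NULL, reads_plus = NULL,
                 output_dir = "dripdsb_out"),
    parameters = list(
      half_width = 10000L, pseudocount = 1, score_half_width = 500L,
      metagene_smooth = 200L, heatmap_bin = 200L,
      browser_half_width = 100000L, browser_smooth = 500L,
      browser_bin = 200L, min_mapq = 0L,
      split_mode = "median_split", split_threshold = NULL,
      alternatives = list(activity = "greater", pathway = "two.sided",
                          genic = "two.sided"),
      group_var = "activity_class", n_browser_sites = 2L),
    simulate = list(enabled = FALSE),
    seed = 1L)
}

#' Read and validate a pipeline YAML config
#'
#' @param path YAML file; keys mirror [default_config()].  Keys under
#'   `simulate` other than `enabled` override [simulation_params()]
#'   arguments.
#' @return The fully populated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  allowed_extra <- if (prefix == "simulate.") {
    names(formals(simulation_params))
  } else {
    character()
  }
  for (key in names(user)) {
    if (!key %in% c(names(defaults), allowed_extra)) {
      stop("unknown config key: ", prefix, key)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(prefix, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the full break-centered DRIP-seq analysis
#'
#' Orchestrates every stage: (optionally) simulate a paired experiment,
#' read sites and alignments, build per-site fold-change profiles, write
#' per-site bedGraph tracks and a long-format profile TSV, score sites,
#' run the grouped comparisons and the activity correlation, and render
#' metagene, heatmap, boxplot, scatter and browser-track outputs.  Every
#' artifact is listed in a manifest with its md5 checksum, and the fully
#' populated config is echoed back as YAML for provenance.
#'
#' @param config A config list ([default_config()] shape) or the path to
#'   a YAML file.
#' @return Invisibly, the manifest data frame (`file`, `stage`, `md5`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pars <- config$parameters
  manifest <- list()
  note <- function(file, stage) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(file), stage = stage,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  if (isTRUE(config$simulate$enabled)) {
    message("stage simulate: generating paired experiment (seed ",
            config$seed, ")")
    sim_args <- config$simulate[setdiff(names(config$simulate),
                                        "enabled")]
    params <- do.call(simulation_params, sim_args)
    sim <- simulate_experiment(params, seed = config$seed)
    sites <- sim$sites
    minus <- sim$minus
    plus <- sim$plus
    write_anchor_sites(sites, file.path(out, "sites.bed"))
    note(file.path(out, "sites.bed"), "simulate")
    write_reads_bed(minus, file.path(out, "reads_minusOHT.bed"))
    write_reads_bed(plus, file.path(out, "reads_plusOHT.bed"))
    note(file.path(out, "reads_minusOHT.bed"), "simulate")
    note(file.path(out, "reads_plusOHT.bed"), "simulate")
    utils::write.table(sim$truth, file.path(out, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(out, "ground_truth.tsv"), "simulate")
  } else {
    for (p in c("sites", "reads_minus", "reads_plus")) {
      if (is.null(config$paths[[p]])) {
        stop("config paths$", p, " is required unless simulate is enabled")
      }
      if (!file.exists(config$paths[[p]])) {
        stop("input file for paths$", p, " does not exist: ",
             config$paths[[p]])
      }
    }
    message("stage io: reading sites and alignments")
    sites <- read_anchor_sites(config$paths$sites)
    minus <- read_alignments(config$paths$reads_minus, "minusOHT",
                             min_mapq = pars$min_mapq)
    plus <- read_alignments(config$paths$reads_plus, "plusOHT",
                            min_mapq = pars$min_mapq)
  }
  cfg_echo <- config
  cfg_echo$paths$output_dir <- out
  yaml::write_yaml(cfg_echo, file.path(out, "config_used.yaml"))
  note(file.path(out, "config_used.yaml"), "config")

  message("stage foldchange: ", nrow(sites), " sites, half-width ",
          pars$half_width)
  profiles <- fold_change_profiles(minus, plus, sites,
                                   half_width = pars$half_width,
                                   pseudocount = pars$pseudocount)
  long <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(site_id = p$site_id,
               rel_pos = relative_positions(p$half_width), lfc = p$lfc,
               stringsAsFactors = FALSE)
  }))
  lfc_tsv <- file.path(out, "foldchange_profiles.tsv")
  utils::write.table(long, lfc_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(lfc_tsv, "foldchange")
  track_dir <- file.path(out, "tracks")
  dir.create(track_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(sites))) {
    p <- profiles[[sites$site_id[i]]]
    origin <- max(0L, sites$cut_pos[i] - p$half_width)
    f <- file.path(track_dir, paste0(sites$site_id[i], "_lfc.bedGraph"))
    write_track(p$lfc, sites$chrom[i], origin, f)
    note(f, "foldchange")
  }

  message("stage score")
  scores <- score_sites(profiles, sites,
                        score_half_width = pars$score_half_width,
                        split_mode = pars$split_mode,
                        split_threshold = pars$split_threshold)
  score_tsv <- file.path(out, "site_scores.tsv")
  utils::write.table(scores, score_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(score_tsv, "score")

  message("stage compare/correlate")
  comparisons <- run_comparisons(scores,
                                 alternatives = pars$alternatives)
  cmp_tsv <- file.path(out, "comparisons.tsv")
  utils::write.table(comparisons, cmp_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(cmp_tsv, "compare")
  corr <- correlate_activity(scores)
  corr_tsv <- file.path(out, "correlation.tsv")
  utils::write.table(as.data.frame(corr), corr_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(corr_tsv, "correlate")
  for (f in render_boxplot(scores, pars$group_var,
                           file.path(out, "boxplot"))) {
    note(f, "compare")
  }
  for (f in render_correlation(scores, corr,
                               file.path(out, "correlation"))) {
    note(f, "correlate")
  }

  message("stage metagene/heatmap")
  labels <- scores[[pars$group_var]][match(names(profiles),
                                           scores$site_id)]
  for (f in metagene(profiles, labels,
                     smooth_window = pars$metagene_smooth) |>
         render_metagene(file.path(out, "metagene"))) {
    note(f, "metagene")
  }
  for (f in render_heatmap(heatmap_matrix(profiles, sites,
                                          bin_size = pars$heatmap_bin),
                           file.path(out, "heatmap"))) {
    note(f, "heatmap")
  }

  message("stage browser")
  n_show <- min(pars$n_browser_sites, nrow(sites))
  show <- sites[order(-sites$activity), ][
    unique(c(seq_len(ceiling(n_show / 2)),
             nrow(sites) - seq_len(floor(n_show / 2)) + 1L)), ,
    drop = FALSE]
  for (i in seq_len(nrow(show))) {
    site <- show[i, ]
    bm <- normalize_coverage(
      window_depth(minus, site, pars$browser_half_width),
      minus$total_aligned, pseudocount_reads = 0)
    bp <- normalize_coverage(
      window_depth(plus, site, pars$browser_half_width),
      plus$total_aligned, pseudocount_reads = 0)
    bt <- browser_tracks(bm, bp, smooth_window = pars$browser_smooth,
                         bin_size = pars$browser_bin)
    for (f in render_browser(bt, file.path(
      out, paste0("browser_", site$site_id)))) {
      note(f, "browser")
    }
  }

  manifest <- do.call(rbind, manifest)
  manifest_tsv <- file.path(out, "manifest.tsv")
  utils::write.table(manifest, manifest_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("pipeline complete: ", nrow(manifest), " artifacts in ", out)
  invisible(manifest)
}
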