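#' Parameters of the paired-condition DRIP-seq simulator
#'
#' The simulator encodes a minimal quantitative model of damage-induced
#' R-loop dynamics at endonuclease cut sites:
#'
#' * Undamaged (-OHT): uniform background plus activity-proportional
#'   canonical R-loop signal over each site's gene body (read-start rate
#'   `background_rate + genebody_rate * activity` per nucleotide).
#' * Damaged (+OHT): the canonical component is multiplied by
#'   `shutdown_factor` within `shutdown_half_width` of the break
#'   (transcriptional shutdown), and responder sites gain a sharp
#'   Gaussian peak of read starts at the cut whose amplitude scales with
#'   activity.  A `non_responder_fraction` of sites never gains a peak,
#'   mirroring the observed minority of high-activity sites without
#'   visible induction.  The damaged library is scaled by
#'   `library_ratio`, so the two conditions have different sizes and
#'   library normalization is actually exercised.
#'
#' Read starts are Poisson; reads are single-end, fixed length,
#' unstranded.
#'
#' @param n_sites Number of cut sites (default 99).
#' @param genome_length Single-contig genome length; the default 21 Mb
#'   accommodates 99 sites at the required spacing.
#' @param chrom Contig name.
#' @param activity_meanlog,activity_sdlog Log-normal activity
#'   distribution parameters (default meanlog 0, sdlog 1).
#' @param background_rate Expected read starts per nt per library
#'   (default 1e-3).
#' @param genebody_rate Per-unit-activity read-start rate over the gene
#'   body (default 5e-4).
#' @param genebody_half_width Gene-body half-width around the cut
#'   (default 5000 nt).
#' @param shutdown_factor Multiplier in `[0, 1]` applied to the canonical
#'   component near the break after damage (default 0.2).
#' @param shutdown_half_width Extent of the shutdown zone (default 1e5
#'   nt); sites are spaced at least twice this so zones never overlap.
#' @param peak_rate Per-unit-activity amplitude of the induced peak's
#'   read-start rate at the cut (default 2e-3).
#' @param peak_sd Gaussian width of the induced peak (default 400 nt).
#' @param non_responder_fraction Fraction of sites with the peak forced
#'   to zero (default 0.1).
#' @param read_length Read length (default 100 nt).
#' @param library_ratio Damaged / undamaged library-size ratio
#'   (default 1.2).
#' @return A validated `sim_params` list.
#' @export
simulation_params <- function(n_sites = 99L,
                              genome_length = 2.1e7,
                              chrom = "chrSim",
                              activity_meanlog = 0,
                              activity_sdlog = 1,
                              background_rate = 1e-3,
                              genebody_rate = 5e-4,
                              genebody_half_width = 5000L,
                              shutdown_factor = 0.2,
                              shutdown_half_width = 1e5,
                              peak_rate = 2e-3,
                              peak_sd = 400,
                              non_responder_fraction = 0.1,
                              read_length = 100L,
                              library_ratio = 1.2) {
  p <- list(n_sites = as.integer(n_sites),
            genome_length = as.numeric(genome_length), chrom = chrom,
            activity_meanlog = activity_meanlog,
            activity_sdlog = activity_sdlog,
            background_rate = background_rate,
            genebody_rate = genebody_rate,
            genebody_half_width = as.integer(genebody_half_width),
            shutdown_factor = shutdown_factor,
            shutdown_half_width = as.numeric(shutdown_half_width),
            peak_rate = peak_rate, peak_sd = peak_sd,
            non_responder_fraction = non_responder_fraction,
            read_length = as.integer(read_length),
            library_ratio = library_ratio)
  rates <- c("background_rate", "genebody_rate", "peak_rate",
             "library_ratio", "peak_sd")
  for (r in rates) if (p[[r]] < 0) stop(r, " must be >= 0")
  for (f in c("shutdown_factor", "non_responder_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (p$n_sites < 1L) stop("n_sites must be >= 1")
  if (p$read_length < 1L) stop("read_length must be >= 1")
  structure(p, class = "sim_params")
}

#' Null-configuration simulator parameters
#'
#' The no-effect configuration used for type-I calibration: damage
#' changes nothing (no induced peak, no shutdown, equal library sizes),
#' so the expected fold-change profile is identically zero at every site
#' and any rejection of the activity tests is a false positive.
#'
#' @param ... Overrides passed to [simulation_params()].
#' @return A `sim_params` list with `peak_rate = 0`,
#'   `shutdown_factor = 1`, `library_ratio = 1`.
#' @export
null_params <- function(...) {
  simulation_params(peak_rate = 0, shutdown_factor = 1,
                    library_ratio = 1, ...)
}

site_spacing <- function(params) {
  margin <- params$shutdown_half_width + 5 * params$peak_sd +
    params$read_length
  usable <- params$genome_length - 2 * margin
  list(margin = margin,
       spacing = if (params$n_sites > 1L) {
         floor(usable / (params$n_sites - 1L))
       } else {
         usable
       },
       usable = usable)
}

#' Simulate anchor sites with ground truth
#'
#' Places `n_sites` cut sites evenly across the contig (at least
#' `2 * shutdown_half_width` apart so shutdown zones never overlap),
#' draws log-normal activities, assigns repair pathway and genic status
#' by fair coin flips independent of activity, and marks each site as a
#' responder with probability `1 - non_responder_fraction`.
#'
#' @param params A `sim_params` list.
#' @return A list with `sites` (an `anchor_sites` table) and `truth` (a
#'   data frame with per-site `activity`, `responder` and
#'   `expected_lfc_cut`, the analytic expected fold change at the cut).
#' @export
simulate_sites <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sp <- site_spacing(params)
  min_spacing <- 2 * params$shutdown_half_width
  if (params$n_sites > 1L && sp$spacing < min_spacing) {
    max_n <- floor(sp$usable / min_spacing) + 1L
    stop("genome_length ", params$genome_length, " cannot hold ",
         params$n_sites, " sites at >= ", min_spacing,
         " nt spacing; maximum feasible n_sites is ", max_n)
  }
  cut_pos <- as.integer(round(sp$margin +
                                (seq_len(params$n_sites) - 1L) *
                                sp$spacing))
  activity <- stats::rlnorm(params$n_sites, params$activity_meanlog,
                            params$activity_sdlog)
  pathway <- sample(c("HR", "NHEJ"), params$n_sites, replace = TRUE)
  genic <- sample(c("intragenic", "intergenic"), params$n_sites,
                  replace = TRUE)
  responder <- stats::rbinom(params$n_sites, 1L,
                             1 - params$non_responder_fraction) == 1L
  sites <- structure(
    data.frame(site_id = sprintf("site%03d", seq_len(params$n_sites)),
               chrom = params$chrom, cut_pos = cut_pos,
               activity = activity, pathway = pathway, genic = genic,
               stringsAsFactors = FALSE),
    class = c("anchor_sites", "data.frame"))
  truth <- data.frame(site_id = sites$site_id, activity = activity,
                      responder = responder, stringsAsFactors = FALSE)
  truth$expected_lfc_cut <- vapply(seq_len(nrow(sites)), function(i) {
    ep <- expected_profile(sites[i, ], truth, params, half_width = 0L)
    ep$lfc[1L]
  }, numeric(1))
  list(sites = sites, truth = truth)
}

# Per-nt read-start rate profile around one site, by condition.
site_rate <- function(rel_pos, activity, responder, condition, params) {
  body <- abs(rel_pos) <= params$genebody_half_width
  canonical <- params$genebody_rate * activity * body
  if (condition == "minusOHT") {
    params$background_rate + canonical
  } else {
    shut <- ifelse(abs(rel_pos) <= params$shutdown_half_width,
                   params$shutdown_factor, 1)
    peak <- if (responder) {
      params$peak_rate * activity *
        exp(-rel_pos^2 / (2 * params$peak_sd^2))
    } else {
      0
    }
    params$library_ratio *
      (params$background_rate + shut * canonical + peak)
  }
}

#' Simulate an aligned-read library for one condition
#'
#' Draws Poisson read starts from the condition's rate profile
#' (background everywhere; canonical gene-body signal, shut down after
#' damage; Gaussian induced peak at responder cuts after damage) and
#' returns fixed-length unstranded read spans.  `total_aligned` is the
#' realized read count.
#'
#' @param sites An `anchor_sites` table from [simulate_sites()].
#' @param truth The matching ground-truth table.
#' @param condition `"minusOHT"` or `"plusOHT"`.
#' @param params A `sim_params` list.
#' @return An [aligned_reads] object.
#' @export
simulate_reads <- function(sites, truth,
                           condition = c("minusOHT", "plusOHT"),
                           params) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "sim_params"))
  scale <- if (condition == "plusOHT") params$library_ratio else 1
  G <- params$genome_length
  rl <- params$read_length
  # background component: homogeneous over the contig
  n_bg <- stats::rpois(1L, params$background_rate * G * scale)
  starts <- sample.int(max(1L, floor(G) - rl), n_bg, replace = TRUE) - 1L
  for (i in seq_len(nrow(sites))) {
    a <- truth$activity[i]
    cut <- sites$cut_pos[i]
    body_len <- 2L * params$genebody_half_width + 1L
    body_rate <- params$genebody_rate * a *
      (if (condition == "plusOHT") params$shutdown_factor else 1)
    n_body <- stats::rpois(1L, body_rate * body_len * scale)
    if (n_body > 0L) {
      starts <- c(starts,
                  cut - params$genebody_half_width +
                    sample.int(body_len, n_body, replace = TRUE) - 1L)
    }
    if (condition == "plusOHT" && truth$responder[i] &&
        params$peak_rate > 0) {
      # integral of the Gaussian rate: amplitude * sd * sqrt(2*pi)
      n_peak <- stats::rpois(1L, params$peak_rate * a * params$peak_sd *
                               sqrt(2 * pi) * scale)
      if (n_peak > 0L) {
        starts <- c(starts,
                    as.integer(round(stats::rnorm(n_peak, cut,
                                                  params$peak_sd))))
      }
    }
  }
  starts <- pmin(pmax(starts, 0L), floor(G) - rl)
  gr <- GenomicRanges::GRanges(
    rep(params$chrom, length(starts)),
    IRanges::IRanges(start = sort(starts) + 1L,
                     width = rep(rl, length(starts))),
    seqlengths = stats::setNames(floor(G), params$chrom))
  aligned_reads(condition, gr, length(gr))
}

#' Analytic expected fold-change profile for one simulated site
#'
#' Closed-form oracle for estimator checks: the expected per-nucleotide
#' depth is the read-start rate convolved with the read footprint, the
#' expected library size is the integral of the rate over the contig,
#' and the expected fold change is the log2 ratio of the
#' pseudocount-corrected expected normalized coverages.
#'
#' @param site One anchor-site row.
#' @param truth The full ground-truth table (library totals integrate the
#'   rate over every site); the row matching `site` supplies the local
#'   rate profile.
#' @param params A `sim_params` list.
#' @param half_width Profile half-width.
#' @param pseudocount Pseudocount in reads (default 1, as in the
#'   pipeline).
#' @return A `fold_change_profile` with the expected `lfc`.
#' @export
expected_profile <- function(site, truth, params, half_width = 10000L,
                             pseudocount = 1) {
  rl <- params$read_length
  row <- truth[truth$site_id == site$site_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("site ", site$site_id, " not in truth table")
  # rate evaluated rl-1 positions left of the window so the read-footprint
  # convolution is exact at the window edge
  rel <- seq.int(-half_width - rl + 1L, half_width)
  exp_lib <- function(cond) {
    scale <- if (cond == "plusOHT") params$library_ratio else 1
    shut <- if (cond == "plusOHT") params$shutdown_factor else 1
    body_len <- 2 * params$genebody_half_width + 1
    peak_mass <- if (cond == "plusOHT") {
      sum(params$peak_rate * truth$activity * truth$responder *
            params$peak_sd * sqrt(2 * pi))
    } else {
      0
    }
    scale * (params$background_rate * params$genome_length +
               shut * params$genebody_rate * sum(truth$activity) *
                 body_len + peak_mass)
  }
  exp_depth <- function(cond) {
    rate <- site_rate(rel, row$activity, row$responder, cond, params)
    # expected depth at p = sum of start rates over positions p-rl+1 .. p
    cs <- c(0, cumsum(rate))
    j <- rl:length(rate)
    cs[j + 1L] - cs[j - rl + 1L]
  }
  dm <- exp_depth("minusOHT")
  dp <- exp_depth("plusOHT")
  nm <- exp_lib("minusOHT")
  np <- exp_lib("plusOHT")
  lfc <- log2(((dp + pseudocount) / np) / ((dm + pseudocount) / nm))
  structure(list(site_id = site$site_id,
                 half_width = as.integer(half_width), lfc = lfc),
            class = "fold_change_profile")
}

#' Simulate a complete paired experiment
#'
#' One call producing everything the pipeline consumes: sites with
#' ground truth and one aligned-read library per condition.  All
#' randomness flows from `seed`, so identical `(params, seed)` give
#' byte-identical output.
#'
#' @param params A `sim_params` list.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A list `sites`, `truth`, `minus`, `plus`.
#' @export
simulate_experiment <- function(params = simulation_params(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ss <- simulate_sites(params)
  minus <- simulate_reads(ss$sites, ss$truth, "minusOHT", params)
  plus <- simulate_reads(ss$sites, ss$truth, "plusOHT", params)
  list(sites = ss$sites, truth = ss$truth, minus = minus, plus = plus)
}
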