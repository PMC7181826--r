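test_that("metagene averages smoothed profiles within groups", {
  p1 <- fcp(rep(1, 401))
  p3 <- fcp(rep(3, 401))
  mg <- metagene(list(p1, p3), labels = c("g", "g"), smooth_window = 50)
  expect_equal(unique(mg$group), "g")
  expect_equal(mg$mean_lfc, rep(2, 401))
  expect_equal(mg$rel_pos, -200:200)
  expect_equal(unique(mg$n_sites), 2L)

  # a singleton group is exactly its smoothed profile
  withr::local_seed(3)
  pr <- fcp(rnorm(401))
  mg1 <- metagene(list(pr), labels = "solo", smooth_window = 21)
  expect_equal(mg1$mean_lfc, moving_average(pr$lfc, 21))

  expect_error(metagene(list(p1, fcp(rep(1, 201))), c("a", "b")),
               "half-width")
  expect_error(metagene(list(p1, p3), labels = c("a", "b", "c")),
               "label")
})

test_that("metagene matches the independent smooth-then-average oracle", {
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    hw <- 150L
    profs <- lapply(seq_len(n), function(i) {
      fcp(rnorm(2 * hw + 1), site_id = paste0("s", i))
    })
    labels <- sample(c("a", "b"), n, replace = TRUE)
    w <- sample(c(1L, 7L, 40L), 1)
    mg <- metagene(profs, labels, smooth_window = w)
    oracle <- bf_metagene(lapply(profs, `[[`, "lfc"), labels, w)
    for (g in names(oracle)) {
      expect_equal(mg$mean_lfc[mg$group == g], oracle[[g]],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    # permutation invariance over input order
    perm <- sample(n)
    mg2 <- metagene(profs[perm], labels[perm], smooth_window = w)
    expect_equal(mg2, mg)
  }
})

test_that("heatmap rows are activity-ordered binned profiles", {
  sites <- structure(data.frame(
    site_id = c("a", "b", "c"), chrom = "chrT",
    cut_pos = c(100L, 200L, 300L), activity = c(5, 1, 3),
    pathway = "HR", genic = "intragenic", stringsAsFactors = FALSE),
    class = c("anchor_sites", "data.frame"))
  withr::local_seed(19)
  profs <- lapply(sites$site_id, function(id) {
    fcp(rnorm(401), site_id = id)
  })
  hm <- heatmap_matrix(profs, sites, bin_size = 100L)
  expect_equal(rownames(hm$matrix), c("a", "c", "b"))
  expect_true(all(diff(hm$row_meta$activity) <= 0))
  expect_equal(ncol(hm$matrix), ceiling(401 / 100))
  # each row equals bin_mean of its own profile
  for (i in seq_along(profs)) {
    expect_equal(hm$matrix[profs[[i]]$site_id, ],
                 bf_bin_mean(profs[[i]]$lfc, 100L),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # equal activities fall back to site_id order
  sites$activity <- c(2, 2, 2)
  hm2 <- heatmap_matrix(profs, sites, bin_size = 100L)
  expect_equal(rownames(hm2$matrix), c("a", "b", "c"))

  expect_error(heatmap_matrix(profs[1:2], sites, 100L), "mismatch")
})

test_that("browser tracks smooth then bin each condition separately", {
  withr::local_seed(29)
  site <- make_site(cut_pos = 5000L)
  mk <- function(n, total, pc = 0) {
    normalize_coverage(window_depth(random_reads(n, 10000L), site,
                                    2000L), total, pc)
  }
  minus <- mk(400, 1000)
  plus <- mk(700, 1500)
  bt <- browser_tracks(minus, plus, smooth_window = 101L,
                       bin_size = 50L)
  expect_equal(bt$minus_track,
               bf_bin_mean(bf_moving_average(minus$normalized, 101L),
                           50L),
               tolerance = 1e-12)
  expect_equal(bt$plus_track,
               bf_bin_mean(bf_moving_average(plus$normalized, 101L),
                           50L),
               tolerance = 1e-12)
  expect_length(bt$minus_track, ceiling(4001 / 50))
  expect_true(all(bt$minus_track >= 0))

  # identical inputs give identical tracks; zero coverage stays zero
  same <- browser_tracks(minus, minus)
  expect_equal(same$minus_track, same$plus_track)
  zero <- minus
  zero$normalized <- rep(0, length(minus$normalized))
  expect_equal(browser_tracks(zero, plus)$minus_track,
               rep(0, ceiling(4001 / 200)))

  other <- mk(100, 500)
  other$cut_pos <- 4000L
  expect_error(browser_tracks(other, plus), "different regions")
})

test_that("renders emit both a data matrix and an image", {
  withr::local_seed(37)
  dir <- withr::local_tempdir()
  profs <- lapply(1:4, function(i) fcp(rnorm(401), paste0("s", i)))
  mg <- metagene(profs, c("hi", "hi", "lo", "lo"), 21L)
  files <- render_metagene(mg, file.path(dir, "mg"))
  expect_true(all(file.exists(files)))
  tab <- utils::read.delim(files[1])
  expect_equal(sort(unique(tab$group)), c("hi", "lo"))

  sites <- structure(data.frame(
    site_id = paste0("s", 1:4), chrom = "chrT", cut_pos = 100L,
    activity = c(4, 3, 2, 1), pathway = "HR", genic = "intragenic",
    stringsAsFactors = FALSE), class = c("anchor_sites", "data.frame"))
  hm <- heatmap_matrix(profs, sites, 100L)
  hfiles <- render_heatmap(hm, file.path(dir, "hm"))
  expect_equal(nrow(utils::read.delim(hfiles[1])), 4L)

  sc <- make_scores(rnorm(6))
  expect_true(all(file.exists(
    render_boxplot(sc, "activity_class", file.path(dir, "box")))))
  corr <- correlate_activity(sc)
  expect_true(all(file.exists(
    render_correlation(sc, corr, file.path(dir, "corr")))))

  expect_error(render_metagene(mg[0, ], file.path(dir, "empty")),
               "no metagene")
})
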