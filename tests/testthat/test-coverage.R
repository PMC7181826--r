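test_that("window depth counts per-base read cover around the cut", {
  rs <- aligned_reads("minusOHT", GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = 96, end = 105)))  # 0-based [95,105)
  d <- window_depth(rs, make_site(cut_pos = 100L), half_width = 3L)
  expect_equal(d$depth, rep(1L, 7L))  # bases 97..103 all covered
  d2 <- window_depth(rs, make_site(cut_pos = 100L), half_width = 8L)
  expect_equal(d2$depth, c(0L, 0L, 0L, rep(1L, 10L), rep(0L, 4L)))

  none <- aligned_reads("minusOHT", GenomicRanges::GRanges())
  expect_warning(d0 <- window_depth(none, make_site(), 5L), "absent")
  expect_equal(d0$depth, rep(0L, 11L))
})

test_that("window depth matches the brute-force per-base counter", {
  withr::local_seed(101)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    len <- 50000L
    starts0 <- sample.int(len - 200L, n, replace = TRUE)
    widths <- sample(20:150, n, replace = TRUE)
    rs <- aligned_reads("minusOHT", GenomicRanges::GRanges(
      "chrT", IRanges::IRanges(start = starts0 + 1L, width = widths)))
    cut <- sample(500:(len - 500L), 1)
    hw <- sample(c(50L, 200L, 400L), 1)
    d <- window_depth(rs, make_site(cut_pos = cut), hw)
    expect_equal(d$depth,
                 as.integer(bf_window_depth(starts0, starts0 + widths,
                                            cut, hw)))
    # sum conservation: total depth = summed per-read overlap lengths
    ov <- pmin(starts0 + widths, cut + hw + 1) - pmax(starts0, cut - hw)
    expect_equal(sum(d$depth), sum(pmax(ov, 0)))
  }
})

test_that("normalization follows (depth + pseudocount) / total", {
  d <- window_depth(aligned_reads("minusOHT", GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(1, 2000))), make_site(cut_pos = 100L), 3L)
  n1 <- normalize_coverage(d, 1e6, pseudocount_reads = 0)
  expect_equal(n1$normalized, rep(1e-6, 7))
  n2 <- normalize_coverage(d, 100, pseudocount_reads = 1)
  expect_equal(n2$normalized, rep(0.02, 7))
  expect_error(normalize_coverage(d, 0), "positive")
  # linear scaling: doubling depth and pseudocount at fixed total doubles
  d2 <- d
  d2$depth <- d$depth * 2L
  n4 <- normalize_coverage(d2, 100, pseudocount_reads = 2)
  expect_equal(n4$normalized, 2 * n2$normalized)
})

test_that("log2 fold change is antisymmetric and zero for identity", {
  withr::local_seed(7)
  rs <- random_reads(300, 20000L)
  site <- make_site(cut_pos = 10000L)
  d <- window_depth(rs, site, 500L)
  a <- normalize_coverage(d, 1000)
  rs2 <- random_reads(500, 20000L)
  b <- normalize_coverage(window_depth(rs2, site, 500L), 1700)

  expect_equal(log2_fold_change(a, a)$lfc, rep(0, 1001))
  fab <- log2_fold_change(a, b)
  fba <- log2_fold_change(b, a)
  expect_equal(fab$lfc, -fba$lfc)
  expect_true(all(is.finite(fab$lfc)))

  # 4x normalized coverage everywhere -> lfc identically 2
  a4 <- a
  a4$normalized <- 4 * a$normalized
  expect_equal(log2_fold_change(a4, a)$lfc, rep(2, 1001))

  bad <- normalize_coverage(window_depth(rs, site, 400L), 1000)
  expect_error(log2_fold_change(a, bad), "half-width")
  raw <- normalize_coverage(d, 1000, pseudocount_reads = 0)
  expect_error(log2_fold_change(a, raw), "pseudocount")
})

test_that("moving average truncates at the edges and preserves length", {
  expect_equal(moving_average(c(0, 3, 0, 3, 0), 3), c(1.5, 1, 2, 1, 1.5))
  expect_equal(moving_average(rep(4.2, 17), 5), rep(4.2, 17))
  x <- rnorm(30)
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(x, 0), "window")
})

test_that("moving average matches brute force and zoo::rollapply", {
  withr::local_seed(11)
  for (rep in 1:30) {
    x <- rnorm(sample(5:300, 1))
    w <- sample(1:20, 1)
    got <- moving_average(x, w)
    expect_equal(got, bf_moving_average(x, w), tolerance = 1e-12)
    if (w %% 2L == 1L) {  # zoo centers odd windows identically
      expect_equal(got,
                   zoo::rollapply(x, w, mean, partial = TRUE),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # idempotent only for constants
  const <- rep(2, 40)
  expect_equal(moving_average(moving_average(const, 7), 7), const)
  x <- c(rep(0, 20), rep(1, 20))
  once <- moving_average(x, 7)
  expect_false(isTRUE(all.equal(moving_average(once, 7), once)))
})

test_that("bin means partition the array with a short final bin", {
  expect_equal(bin_mean(c(1, 1, 2, 2), 2), c(1, 2))
  expect_equal(bin_mean(1:5, 2), c(1.5, 3.5, 5))
  expect_error(bin_mean(1:5, 0), "bin_size")
  withr::local_seed(13)
  for (rep in 1:20) {
    x <- rnorm(sample(10:1000, 1))
    b <- sample(1:200, 1)
    expect_equal(bin_mean(x, b), bf_bin_mean(x, b), tolerance = 1e-12)
  }
})
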