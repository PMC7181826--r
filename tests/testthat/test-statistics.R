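test_that("induction score is the mean over the central 1-kb region", {
  expect_equal(induction_score(fcp(rep(1.7, 2001))), 1.7)
  lfc <- rep(-3, 2001)
  lfc[(1001 - 500):(1001 + 500)] <- 2
  expect_equal(induction_score(fcp(lfc)), 2)

  withr::local_seed(5)
  x <- rnorm(2001)
  expect_equal(induction_score(fcp(x)),
               mean(x[501:1501]), tolerance = 1e-14)
  expect_error(induction_score(fcp(rnorm(201)), 500), "exceeds")

  # linearity: score of a sum of profiles is the sum of scores
  y <- rnorm(2001)
  expect_equal(induction_score(fcp(x + y)),
               induction_score(fcp(x)) + induction_score(fcp(y)),
               tolerance = 1e-12)
})

test_that("activity classification supports median split and threshold", {
  s <- data.frame(activity = c(1, 2, 3, 4))
  expect_equal(as.character(classify_activity(s)),
               c("low", "low", "high", "high"))
  expect_warning(cl <- classify_activity(data.frame(activity = rep(2, 4))),
                 "equal")
  expect_true(all(cl == "low"))
  expect_equal(as.character(
    classify_activity(data.frame(activity = c(0, 0.5, 2)),
                      mode = "threshold", threshold = 0)),
    c("low", "high", "high"))
  expect_error(classify_activity(s, mode = "threshold"), "threshold")
  expect_error(classify_activity(data.frame(activity = 1)), "2 sites")
})

test_that("rank-sum test reproduces textbook exact cases", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_true(rs$exact)
  expect_equal(rs$p_raw, 0.05)
  expect_equal(rs$statistic, 0)

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), "two.sided")
  expect_equal(same$p_raw, 1)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("rank-sum p equals full permutation enumeration for n <= 12", {
  withr::local_seed(23)
  alts <- c("two.sided", "greater", "less")
  for (rep in 1:60) {
    nx <- sample(1:6, 1)
    ny <- sample(1:6, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, mean = sample(c(0, 1), 1))
    alt <- sample(alts, 1)
    got <- rank_sum_test(x, y, alt)
    expect_true(got$exact)
    expect_equal(got$p_raw, bf_rank_sum_exact(x, y, alt),
                 tolerance = 1e-12,
                 label = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 4, 4)
  got <- rank_sum_test(x, y, "two.sided")
  expect_false(got$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$p_raw, ref$p.value)
  big <- rank_sum_test(rnorm(40), rnorm(40), "greater")
  expect_false(big$exact)
})

test_that("Pearson test matches closed-form r and the t distribution", {
  x <- c(1, 2, 3, 5, 9)
  perfect <- pearson_test(x, 2 * x + 1)
  expect_equal(perfect$r, 1)

  ct <- pearson_test(c(1, 2, 3), c(1, 2, 2))
  expect_equal(ct$r, sqrt(3) / 2, tolerance = 1e-12)
  tt <- ct$r * sqrt((3 - 2) / (1 - ct$r^2))
  expect_equal(ct$p, 2 * stats::pt(-abs(tt), df = 1), tolerance = 1e-12)

  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_test(1:2, 2:3), "n >= 3")

  # affine invariance and sign flip
  withr::local_seed(2)
  a <- rnorm(20)
  b <- rnorm(20)
  r0 <- pearson_test(a, b)$r
  expect_equal(pearson_test(3 * a + 7, b)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(-a, b)$r, -r0, tolerance = 1e-12)
})

test_that("Pearson p values are uniform under the null", {
  withr::local_seed(31)
  p <- replicate(200, pearson_test(rnorm(1000), rnorm(1000))$p)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.08)
})

test_that("Bonferroni multiplies by family size, caps and is monotone", {
  expect_equal(bonferroni(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1.0))
  expect_equal(bonferroni(0.2), 0.2)
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p)) >= 0))
  expect_equal(bonferroni(p), stats::p.adjust(p, "bonferroni"))
})

test_that("grouped comparisons follow the three-panel design", {
  sc <- make_scores(score = c(10, 9, 8, 7, 6, 1.5, 1.4, 1.3, 1.2, 1.1),
                    activity = c(5, 6, 7, 8, 9, 1, 1.1, 1.2, 1.3, 1.4))
  res <- run_comparisons(sc)
  expect_equal(res$comparison, c("activity", "pathway", "genic"))
  act <- res[res$comparison == "activity", ]
  expect_equal(act$alternative, "greater")
  expect_lt(act$p_raw, 0.01)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))

  # identical distributions in HR and NHEJ -> two-sided p = 1
  sc2 <- make_scores(score = c(1, 1, 2, 2, 3, 3),
                     pathway = c("HR", "NHEJ", "HR", "NHEJ", "HR",
                                 "NHEJ"))
  res2 <- run_comparisons(sc2)
  expect_equal(res2$p_raw[res2$comparison == "pathway"], 1)

  # an empty group drops that comparison with a warning
  sc3 <- make_scores(score = 1:6, pathway = rep("HR", 6))
  expect_warning(res3 <- run_comparisons(sc3), "pathway")
  expect_false("pathway" %in% res3$comparison)
  expect_equal(res3$p_adjusted, pmin(1, res3$p_raw * 2))
})

test_that("activity correlation returns the fitted line for plotting", {
  sc <- make_scores(score = c(1, 2, 3, 4.5), activity = 1:4)
  corr <- correlate_activity(sc)
  fit <- stats::lm(sc$score ~ sc$activity)
  expect_equal(corr$slope, unname(stats::coef(fit)[2]))
  expect_equal(corr$n, 4L)
  expect_gt(corr$r, 0.99)
})
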