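test_that("%COV matches closed forms and is scale invariant", {
  expect_equal(percent_cov(c(10, 10, 10)), 0)
  expect_equal(percent_cov(c(8, 12)), 100 * 2 * sqrt(2) / 10) # 28.28%
  set.seed(5)
  x <- rlnorm(20)
  expect_equal(percent_cov(7.3 * x), percent_cov(x), tolerance = 1e-12)
  expect_warning(na_cov <- percent_cov(c(-1, 1)), "zero")
  expect_true(is.na(na_cov))
})

test_that("pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_r(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 2, 3); y <- c(1, 2, 2)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), brute)
  expect_warning(r0 <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r0))
})

test_that("CCC analytic suite: identity, reversal, shift", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(ccc(x, x), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7) # population moments
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)),
               naive_ccc(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-14)
})

test_that("CCC is symmetric, Lin-bounded, and penalizes location shifts", {
  set.seed(13)
  for (k in 1:30) {
    n <- sample(4:40, 1)
    x <- rnorm(n); y <- 0.6 * x + rnorm(n, sd = 0.5)
    expect_equal(ccc(x, y), ccc(y, x), tolerance = 1e-14)
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    expect_equal(ccc(x, y), naive_ccc(x, y), tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_lt(ccc(x, x + 2), 1)
  expect_equal(pearson_r(x, x + 2), 1)
  expect_warning(cna <- ccc(c(2, 2), c(2, 2)), "constant")
  expect_true(is.na(cna))
})

test_that("classification bins honour the documented thresholds and boundaries", {
  expect_identical(classify_robustness(c(4.9, 5, 30, 30.1, NA)),
                   c("high", "mid", "mid", "low", "unclassifiable"))
  expect_identical(classify_correlation(c(0.85, -0.9, 0.2, 0.8, 0.19, NA)),
                   c("high", "high", "mid", "mid", "low", "unclassifiable"))
  expect_identical(classify_repeatability(c(0.89, 0.90, 0.93, 0.95, 0.99,
                                            0.991, NA)),
                   c("poor", "moderate", "moderate", "substantial",
                     "substantial", "near_perfect", "unclassifiable"))
})

test_that("robustness report aggregates a sweep per feature", {
  tab <- expand.grid(condition = c("nex1", "nex7"), slice = 1:2,
                     feature = c("S.Mean", "T.Ent"), stringsAsFactors = FALSE)
  tab$value <- c(10, 10.2, 10.1, 10.3, 2, 2.6, 2.1, 2.5)
  rep1 <- suppressWarnings(
    robustness_report(tab, c(nex1 = 1, nex7 = 7), "noise"))
  expect_equal(nrow(rep1), 2)
  m1 <- mean(c(10, 10.1)); m2 <- mean(c(10.2, 10.3))
  expect_equal(rep1$pct_cov[rep1$feature == "S.Mean"],
               100 * sd(c(m1, m2)) / mean(c(m1, m2)))
  # single condition: flagged, not an error
  expect_warning(r1 <- robustness_report(tab[tab$condition == "nex1", ],
                                         c(nex1 = 1), "noise"),
                 "unclassifiable")
  expect_true(all(is.na(r1$pct_cov)))
  expect_true(all(r1$robustness_class == "unclassifiable"))
})

test_that("repeatability report pairs arms and counts classes consistently", {
  tab <- expand.grid(condition = "A", slice = 1:5,
                     feature = c("S.Mean", "T.Ent"), stringsAsFactors = FALSE)
  tab$value <- c(1:5, seq(2, 4, length.out = 5))
  same <- repeatability_report(tab, tab, weighting = "T1")
  expect_true(all(same$ccc == 1))
  expect_true(all(same$repeatability_class == "near_perfect"))
  shifted <- tab; shifted$value <- tab$value + 10
  rep2 <- repeatability_report(tab, shifted, weighting = "T2")
  expect_true(all(rep2$ccc < 0.9))
  s <- summarize_reports(repeatability = rbind(same, rep2))
  expect_equal(s$repeatability$T1$near_perfect, 2)
  expect_equal(s$repeatability$T2$poor, 2)
  bad <- tab[-1, ]
  expect_error(repeatability_report(tab, bad, "T1"), "same")
})
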