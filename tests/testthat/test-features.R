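test_that("first-order statistics match hand-computed closed forms", {
  f1 <- first_order_features(make_patch(c(1, 1, 1, 1), nr = 2))
  expect_equal(unname(f1[c("S.Mean", "S.Std", "S.Var", "S.Ran", "S.En", "S.RMS")]),
               c(1, 0, 0, 0, 4, 1))
  expect_equal(unname(f1[c("S.Un", "S.Ent")]), c(1, 0))

  f2 <- first_order_features(make_patch(c(1, 2, 3, 4), nr = 2))
  expect_equal(unname(f2["S.Mean"]), 2.5)
  expect_equal(unname(f2["S.Med"]), 2.5)
  expect_equal(unname(f2["S.Ran"]), 3)
  expect_equal(unname(f2["S.MAD"]), 1)
  expect_equal(unname(f2["S.En"]), 30)
  expect_equal(unname(f2["S.RMS"]), sqrt(7.5))
  expect_equal(unname(f2["S.Min"]), 1)
  expect_equal(unname(f2["S.Max"]), 4)
})

test_that("first-order statistics match the naive oracle on random vectors", {
  set.seed(21)
  for (k in 1:25) {
    x <- rnorm(sample(5:200, 1), mean = runif(1, -50, 50),
               sd = runif(1, 0.1, 30))
    got <- first_order_features(make_patch(x))
    expect_equal(got, naive_first_order(x), tolerance = 1e-12)
  }
})

test_that("first-order features are permutation-invariant", {
  set.seed(3)
  x <- rnorm(64)
  a <- first_order_features(make_patch(x, nr = 8))
  b <- first_order_features(make_patch(sample(x), nr = 8))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("GLCM of the 2x2 two-level image matches pair enumeration", {
  lev <- matrix(c(1L, 2L, 1L, 2L), 2, 2) # rows [1,1] and [2,2]
  q <- structure(list(levels = lev, mask = matrix(TRUE, 2, 2), n_levels = 2L),
                 class = "quantized_roi")
  P <- compute_glcm(q, directions = list(c(0L, 1L)))
  expect_equal(P$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("GLCM is symmetric, sums to one, and a constant ROI has energy 1", {
  set.seed(31)
  for (k in 1:25) {
    q <- random_quantized_roi()
    P <- try(compute_glcm(q), silent = TRUE)
    if (inherits(P, "try-error")) next # no valid pair, legitimately rejected
    expect_equal(sum(P$matrix), 1, tolerance = 1e-12)
    expect_equal(P$matrix, t(P$matrix), tolerance = 1e-12)
  }
  const <- structure(list(levels = matrix(3L, 4, 4), mask = matrix(TRUE, 4, 4),
                          n_levels = 16L), class = "quantized_roi")
  f <- suppressWarnings(glcm_features(compute_glcm(const)))
  expect_equal(unname(f["T.En"]), 1)
  expect_equal(unname(f["T.MP"]), 1)
  expect_equal(unname(f["T.Cor"]), 0) # documented degenerate fallback
})

test_that("GLCM features match closed forms on simple matrices", {
  ident <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f <- glcm_features(ident)
  expect_equal(unname(f["T.Con"]), 0)
  expect_equal(unname(f["T.Dis"]), 0)
  expect_equal(unname(f["T.En"]), 0.5)
  expect_equal(unname(f["T.MP"]), 0.5)
  expect_equal(unname(f["T.Ent"]), 1) # one bit

  G <- 4
  unif <- matrix(1 / G^2, G, G)
  fu <- glcm_features(unif)
  expect_equal(unname(fu["T.En"]), 1 / G^2)
  expect_equal(unname(fu["T.Ent"]), 2 * log2(G))
  expect_error(glcm_features(2 * unif), "normalized")
})

test_that("GLRLM counts runs correctly and conserves pixels per direction", {
  lev <- matrix(c(1L, 1L, 2L), 1, 3)
  q <- structure(list(levels = lev, mask = matrix(TRUE, 1, 3), n_levels = 2L),
                 class = "quantized_roi")
  R <- compute_glrlm(q, directions = list(c(0L, 1L)))
  expect_equal(R$matrix[1, 2], 1) # level 1, length 2
  expect_equal(R$matrix[2, 1], 1) # level 2, length 1
  expect_equal(sum(R$matrix), 2)

  constrow <- structure(list(levels = matrix(5L, 1, 7),
                             mask = matrix(TRUE, 1, 7), n_levels = 8L),
                        class = "quantized_roi")
  Rc <- compute_glrlm(constrow, directions = list(c(0L, 1L)))
  expect_equal(Rc$matrix[5, 7], 1)
  expect_equal(sum(Rc$matrix), 1)

  # conservation: sum over (level, length) of count * length = mask size
  set.seed(41)
  for (k in 1:25) {
    q <- random_quantized_roi()
    R <- compute_glrlm(q)
    lenw <- matrix(seq_len(ncol(R$matrix)), nrow(R$matrix), ncol(R$matrix),
                   byrow = TRUE)
    for (M in R$per_direction)
      expect_equal(sum(M * lenw[, seq_len(ncol(M)), drop = FALSE]), sum(q$mask))
  }
})

test_that("GLRLM features match closed forms for degenerate run patterns", {
  # all runs length one
  alt <- structure(list(levels = matrix(c(1L, 2L), 4, 4),
                        mask = matrix(TRUE, 4, 4), n_levels = 2L),
                   class = "quantized_roi")
  R1 <- compute_glrlm(alt, directions = list(c(1L, 0L)))
  f1 <- glrlm_features(R1)
  expect_equal(unname(f1[c("T.SRE", "T.LRE", "T.RP")]), c(1, 1, 1))

  # single run of length L at level g
  L <- 6L; g <- 3L
  single <- structure(list(levels = matrix(g, 1, L), mask = matrix(TRUE, 1, L),
                           n_levels = 4L), class = "quantized_roi")
  fs <- glrlm_features(compute_glrlm(single, directions = list(c(0L, 1L))))
  expect_equal(unname(fs["T.LRE"]), L^2)
  expect_equal(unname(fs["T.SRE"]), 1 / L^2)
  expect_equal(unname(fs["T.RP"]), 1 / L)
  expect_equal(unname(fs["T.HGLRU"]), g^2)

  # bounds: SRE <= 1 <= LRE on any input
  set.seed(51)
  for (k in 1:20) {
    f <- glrlm_features(compute_glrlm(random_quantized_roi()))
    expect_lte(f[["T.SRE"]], 1 + 1e-12)
    expect_gte(f[["T.LRE"]], 1 - 1e-12)
  }
})

test_that("the full extractor returns 46 finite named features", {
  set.seed(61)
  p <- make_patch(rnorm(400, 100, 12), nr = 20)
  fv <- extract_all_features(p)
  expect_length(fv, 46)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("second-order features are invariant to affine intensity transforms", {
  set.seed(71)
  vals <- rnorm(144, 50, 8)
  f1 <- extract_all_features(make_patch(vals, nr = 12))
  f2 <- extract_all_features(make_patch(0.25 * vals - 11, nr = 12))
  tex <- grep("^T\\.", feature_names(), value = TRUE)
  expect_equal(f1[tex], f2[tex], tolerance = 1e-12)
})
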