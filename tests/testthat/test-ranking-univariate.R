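test_that("correlation ranking: perfect predictor first, constants score zero", {
  X <- cbind(ind = c(1, 1, 0, 0, 0),
             noisy = c(0.9, 0.2, 0.4, 0.8, 0.1),
             flat = rep(3, 5))
  d <- dataset(X, c("p", "p", "n", "n", "n"))
  r <- rank_correlation(d)
  expect_equal(r$order[1], 1L)
  expect_equal(r$scores[1], 1)
  expect_equal(r$scores[r$order == 3], 0)
  # scores are non-increasing and the order is a permutation
  expect_true(all(diff(r$scores) <= 0))
  expect_setequal(r$order, 1:3)
})

test_that("weighted correlation equals the unweighted correlation on replicated instances", {
  d <- toy6()
  w <- c(2, 2, 1, 1, 1, 1)
  a <- rank_correlation(d, weights = w)
  b <- rank_correlation(replicate_dataset(d, w))
  expect_equal(a$scores, b$scores)
  expect_identical(a$order, b$order)
})

test_that("information gain and gain ratio match direct entropy computation on toys", {
  # two-valued feature perfectly aligned with the class: IG = 1 bit, and the
  # even split gives SplitInfo = 1, hence GR = 1
  d <- dataset(matrix(c(0, 0, 1, 1), ncol = 1), c("p", "p", "n", "n"))
  expect_equal(rank_info_gain(d)$scores, 1)
  expect_equal(rank_gain_ratio(d)$scores, 1)

  # feature independent of the class: no cut reduces entropy, IG = 0
  d0 <- dataset(matrix(c(0, 1, 0, 1), ncol = 1), c("p", "p", "n", "n"))
  expect_equal(rank_info_gain(d0)$scores, 0)
  expect_equal(rank_gain_ratio(d0)$scores, 0)

  # constant (single-bin) feature: SplitInfo = 0, GR = 0 by convention
  dc <- dataset(matrix(rep(2, 4), ncol = 1), c("p", "p", "n", "n"))
  expect_equal(rank_gain_ratio(dc)$scores, 0)
})

test_that("MDL discretization matches an exhaustive-cut oracle on small numeric data", {
  for (s in 1:8) {
    set.seed(800 + s)
    x <- round(rnorm(8), 2)
    y <- rbinom(8, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    expect_equal(mdl_cut_points(x, y), oracle_mdl_cuts(x, y),
                 tolerance = 1e-10, info = paste("seed", s))
    # and with non-uniform integer weights
    w <- sample(1:3, 8, replace = TRUE)
    expect_equal(mdl_cut_points(x, y, w), oracle_mdl_cuts(x, y, w),
                 tolerance = 1e-10, info = paste("weighted seed", s))
  }
})

test_that("IG/GR weighted runs equal replicated-instance runs", {
  d <- toy6()
  w <- c(3, 1, 2, 1, 1, 2)
  drep <- replicate_dataset(d, w)
  expect_equal(rank_info_gain(d, weights = w)$scores,
               rank_info_gain(drep)$scores)
  expect_equal(rank_gain_ratio(d, weights = w)$scores,
               rank_gain_ratio(drep)$scores)
})

test_that("gain ratio never exceeds information gain when SplitInfo >= 1", {
  d <- generate_dataset(synth_config(25, 25, 40, 10, effect_size = 1.5,
                                     seed = 99))
  # guarantee at least one evenly splitting feature (SplitInfo exactly 1)
  d$features[, 40] <- class_indicator_test(d)
  # recover per-feature values in original order
  ig <- rank_info_gain(d); gr <- rank_gain_ratio(d)
  ig_f <- ig$scores[match(seq_len(40), ig$order)]
  gr_f <- gr$scores[match(seq_len(40), gr$order)]
  si <- vapply(seq_len(40), function(j) {
    cuts <- mdl_cut_points(d$features[, j], is_positive(d))
    if (!length(cuts)) return(0)
    b <- findInterval(d$features[, j], cuts)
    p <- table(b) / length(b)
    -sum(p * log2(p))
  }, numeric(1))
  idx <- si >= 1
  expect_true(any(idx))
  expect_true(all(gr_f[idx] <= ig_f[idx] + 1e-12))
})

test_that("rankers are invariant to instance order and reject one-class data", {
  d <- toy6()
  perm <- c(4, 2, 6, 1, 3, 5)
  dp <- dataset(d$features[perm, ], d$labels[perm],
                positive_label = d$positive_label)
  for (f in list(rank_correlation, rank_info_gain, rank_gain_ratio)) {
    expect_equal(f(dp)$scores, f(d)$scores)
    expect_identical(f(dp)$order, f(d)$order)
  }
  dd <- dataset(d$features, rep(c("n", "p"), c(5, 1)))
  expect_error(rank_correlation(dd, weights = c(rep(1, 5), 0)), "degenerate")
})

test_that("cut_ranking arithmetic and validation", {
  r <- ranked_list(seq(7129, 1), "corr")
  expect_length(cut_ranking(r, 0.02), 143L)       # ceiling(0.02 * 7129)
  expect_identical(cut_ranking(r, 7129), r$order) # retain = n: identity cut
  r2 <- ranked_list(seq(1000, 1), "corr")
  expect_length(cut_ranking(r2, 0.0025), 3L)      # ceiling(2.5)
  expect_error(cut_ranking(r2, 0), "retain")
  expect_error(cut_ranking(r2, 1001), "retain")
  expect_error(cut_ranking(r2, 2.5), "whole number")
})
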