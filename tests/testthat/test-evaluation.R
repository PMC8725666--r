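test_that("confusion counts partition the evaluated instances", {
  truth <- rep(c("p", "n"), c(2, 3))
  cc <- confusion_counts(truth, truth, "p")
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 3, fn = 0))
  all_neg <- confusion_counts(truth, rep("n", 5), "p")
  expect_equal(all_neg$tp, 0)
  expect_equal(all_neg$fn, 2)
  expect_equal(with(all_neg, tp + fp + tn + fn), 5)
  expect_error(confusion_counts(truth, truth[-1], "p"), "equal length")
})

test_that("metrics match direct formula evaluation", {
  perfect <- compute_metrics(list(tp = 2, fp = 0, tn = 3, fn = 0))
  expect_equal(unname(perfect[c("mcc", "g_mean", "f_measure")]), c(1, 1, 1))

  m <- compute_metrics(list(tp = 20, fp = 10, tn = 65, fn = 5))
  expect_equal(m[["mcc"]], 0.630, tolerance = 1e-3)
  expect_equal(m[["g_mean"]], 0.833, tolerance = 1e-3)
  expect_equal(m[["f_measure"]], 0.727, tolerance = 1e-3)

  degen <- compute_metrics(list(tp = 0, fp = 0, tn = 8, fn = 2))
  expect_equal(unname(degen[c("sensitivity", "g_mean", "mcc", "f_measure")]),
               c(0, 0, 0, 0))
})

test_that("metrics agree with an independent one-line oracle on 1000 fuzzed tables", {
  set.seed(2024)
  for (i in 1:1000) {
    cts <- as.list(stats::rpois(4, lambda = sample(c(1, 5, 40), 1)))
    names(cts) <- c("tp", "fp", "tn", "fn")
    if (sum(unlist(cts)) == 0) cts$tn <- 1
    m <- compute_metrics(cts)
    tp <- cts$tp; fp <- cts$fp; tn <- cts$tn; fn <- cts$fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    expect_equal(m[["mcc"]], mcc)
    expect_equal(m[["g_mean"]], sqrt(sens * spec))
    expect_equal(m[["f_measure"]],
                 if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0)
    expect_equal(m[["sensitivity"]], sens)
    expect_equal(m[["specificity"]], spec)
    expect_equal(m[["precision"]], prec)
    # symmetry: MCC invariant under TP<->TN with FP<->FN; G-mean under
    # sensitivity<->specificity
    sw <- compute_metrics(list(tp = tn, fp = fn, tn = tp, fn = fp))
    expect_equal(sw[["mcc"]], m[["mcc"]])
    expect_equal(sw[["g_mean"]], m[["g_mean"]])
  }
})

test_that("the cross-validation plan is stratified, exhaustive and seeded", {
  d <- generate_dataset(synth_config(8, 92, 10, 2, effect_size = 1, seed = 1))
  plan <- make_cv_plan(d, folds = 5, repeats = 4, seed = 17)
  expect_length(plan$partitions, 20L)
  pos <- is_positive(d)
  for (p in plan$partitions) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), 1:100)
    expect_true(sum(pos[p$test]) %in% 1:2)       # 8 positives over 5 folds
    expect_true(length(p$test) %in% 19:21)
  }
  # within one repeat the test folds partition the instances
  for (r in 1:4) {
    tests <- unlist(lapply(plan$partitions[
      vapply(plan$partitions, function(p) p$repeat_id == r, logical(1))],
      `[[`, "test"))
    expect_setequal(tests, 1:100)
    expect_length(tests, 100L)
  }
  expect_identical(make_cv_plan(d, seed = 17)$partitions, plan$partitions)
  expect_false(identical(make_cv_plan(d, seed = 18)$partitions,
                         plan$partitions))
  tiny <- subset_dataset(d, c(1:3, 9:20))
  expect_error(make_cv_plan(tiny, folds = 5), "fewer folds")
})

test_that("Wilcoxon signed-rank: conventions and exact small-sample values", {
  expect_warning(res <- wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_equal(res$p_value, 1)
  # 6 pairs all favoring A, no ties: two-sided exact 2/2^6
  expect_equal(wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10),
                                    c(1, 2, 3, 4, 5, 6))$p_value, 0.03125)
})

test_that("Wilcoxon matches exhaustive sign-pattern enumeration at n = 8", {
  mags <- c(0.3, 0.7, 1.1, 1.9, 2.4, 3.3, 4.1, 5.2)
  for (bits in 0:255) {
    signs <- ifelse(bitwAnd(bits, 2^(0:7)) > 0, 1, -1)
    a <- signs * mags
    p <- wilcoxon_signed_rank(a, rep(0, 8))$p_value
    expect_equal(p, oracle_wilcoxon(a, rep(0, 8)), info = paste("bits", bits))
  }
  # with tied magnitudes (mid-ranks), still exact vs enumeration
  mags_t <- c(1, 1, 2, 2, 3, 3, 4, 5)
  for (bits in c(0, 5, 37, 129, 255)) {
    signs <- ifelse(bitwAnd(bits, 2^(0:7)) > 0, 1, -1)
    a <- signs * mags_t
    expect_equal(wilcoxon_signed_rank(a, rep(0, 8))$p_value,
                 oracle_wilcoxon(a, rep(0, 8)), info = paste("tied", bits))
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test where both are exact", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(a, b)$p_value, ref)
  }
  # large-n branch tracks the approximate reference closely
  set.seed(78)
  a <- rnorm(40, 0.3); b <- rnorm(40)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, ref, tolerance = 1e-10)
})

test_that("Holm-Bonferroni step-down rejects the documented prefix", {
  p <- c(0.0006, 0.0024, 0.0085, 0.0131, 0.0267, 0.30)
  rep6 <- holm_bonferroni(p, alpha = 0.05)
  expect_equal(rep6$n_rejected, 4L)
  expect_equal(rep6$thresholds,
               c(0.05 / 6, 0.01, 0.0125, 0.05 / 3, 0.025, 0.05))
  expect_identical(rep6$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))

  expect_equal(holm_bonferroni(rep(1, 5))$n_rejected, 0L)
  expect_identical(holm_bonferroni(0.04, alpha = 0.05)$rejected, TRUE)
  expect_identical(holm_bonferroni(0.06, alpha = 0.05)$rejected, FALSE)
})

test_that("Holm rejections sit between Bonferroni and uncorrected, matching p.adjust", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))^sample(1:3, 1)
    rep_h <- holm_bonferroni(p, alpha = 0.05)
    ref <- stats::p.adjust(p, method = "holm") <= 0.05
    expect_identical(rep_h$rejected, unname(ref))
    expect_true(all(rep_h$rejected <= (p < 0.05 + 1e-15)))       # subset
    expect_true(all((p < 0.05 / length(p)) <= rep_h$rejected))   # superset
  }
})
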