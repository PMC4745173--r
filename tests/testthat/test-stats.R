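test_that("bootstrap ASL is the inclusive left-tail fraction, reproducibly", {
  x <- rand_seq(128, 55)
  r1 <- bootstrap_asl(x, n = 200L, seed = 9)
  r2 <- bootstrap_asl(x, n = 200L, seed = 9)
  expect_identical(r1$null_slopes, r2$null_slopes)
  expect_equal(r1$asl, sum(r1$null_slopes <= r1$observed$s, na.rm = TRUE) / 200)
  expect_gte(r1$asl, 0)
  expect_lte(r1$asl, 1)
  # monotonicity in the observed slope against a fixed null sample
  asl_at <- function(obs) sum(r1$null_slopes <= obs) / r1$n_replicates
  expect_lte(asl_at(min(r1$null_slopes) - 1), asl_at(r1$observed$s))
  expect_equal(asl_at(max(r1$null_slopes)), 1)
})

test_that("permutation test preserves composition; constant input gives ASL 1", {
  pa <- permutation_test(strrep("A", 32), n = 50L, seed = 3)
  expect_true(all(pa$null_slopes == pa$observed$s))
  expect_equal(pa$asl, 1)
  x <- rand_seq(64, 31)
  r <- permutation_test(x, n = 100L, seed = 4)
  expect_identical(r$n_replicates, 100L)
  expect_equal(r$asl, sum(r$null_slopes <= r$observed$s, na.rm = TRUE) / 100)
})

test_that("resampling p-values are roughly uniform under the iid null", {
  # sequences drawn from the same multinomial null as the bootstrap resamples
  set.seed(2024)
  asl <- vapply(1:60, function(i) {
    bootstrap_asl(rand_seq(64, seed = 7000 + i), n = 199L)$asl
  }, numeric(1L))
  ks <- suppressWarnings(stats::ks.test(asl, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pooled two-sample t matches the textbook formula", {
  x <- c(1.1, 2.3, 3.1, 4.0)
  y <- c(2.0, 2.9, 4.1, 5.2, 6.3)
  ht <- two_sample_t(x, y)
  # hand-computed pooled variance oracle
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(ht$t, t_oracle, tolerance = 1e-12)
  expect_equal(ht$df, length(x) + length(y) - 2)
  expect_equal(ht$p, 2 * stats::pt(-abs(t_oracle), ht$df), tolerance = 1e-12)
  expect_equal(two_sample_t(x, x)$t, 0)
  expect_lt(two_sample_t(c(1, 2, 3), c(2, 3, 4))$t, 0)  # y larger -> negative t
  expect_error(two_sample_t(c(1, 1, 1), c(1, 1, 1)), "constant")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("confusion counts at a threshold partition both samples", {
  cc <- confusion_at(-1.5, exon_slopes = -1.0, intron_slopes = -2.0)
  expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  set.seed(12)
  ex <- rnorm(40); it <- rnorm(25)
  low <- min(c(ex, it)) - 1
  cc2 <- confusion_at(low, ex, it)
  expect_identical(cc2$fn + cc2$tn, 0L)
  for (th in c(-1, 0, 1)) {
    cc3 <- confusion_at(th, ex, it)
    expect_identical(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 65L)
    expect_identical(cc3$tp + cc3$fn, 40L)
  }
})

test_that("reference confusion table yields its classification metrics", {
  m <- metrics_from_confusion(list(tp = 987L, fp = 546L, fn = 987L, tn = 1750L))
  expect_equal(round(100 * m$sensitivity, 1), 50.0)
  expect_equal(round(100 * m$specificity, 1), 76.2)
  expect_equal(round(100 * m$accuracy, 1), 64.1)
  expect_equal(round(m$mcc, 2), 0.27)
  perfect <- metrics_from_confusion(list(tp = 10L, fp = 0L, fn = 0L, tn = 10L))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, mcc = 1))
  expect_error(metrics_from_confusion(list(tp = 0L, fp = 0L, fn = 0L, tn = 5L)),
               "marginal")
})

test_that("Youden threshold maximizes J, ties toward the smallest threshold", {
  sep <- youden_threshold(c(0, 0, 1, 1), c(-1, -1))
  expect_equal(sep$J, 1)
  expect_gt(sep$threshold, -1)
  expect_lt(sep$threshold, 0)
  same <- youden_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$J, 0, tolerance = 1e-12)
  # internal consistency: J recomputed from the confusion table at s*
  set.seed(20)
  for (i in 1:5) {
    ex <- rnorm(sample(5:50, 1), mean = 0.5)
    it <- rnorm(sample(5:50, 1))
    y <- youden_threshold(ex, it)
    m <- metrics_from_confusion(confusion_at(y$threshold, ex, it))
    expect_equal(y$J, m$sensitivity + m$specificity - 1, tolerance = 1e-12)
    # brute-force oracle: no threshold among all pooled values +/- eps beats J
    cand <- sort(c(ex, it))
    cand <- c(cand - 1e-9, cand + 1e-9)
    J_all <- vapply(cand, function(th) {
      mean(ex > th) + mean(it <= th) - 1
    }, numeric(1L))
    expect_gte(y$J + 1e-12, max(J_all))
  }
})

test_that("kernel density estimates span the data on a 100-point grid", {
  set.seed(5)
  x <- rnorm(200)
  k <- kde_1d(x)
  expect_identical(length(k$grid), 100L)
  expect_equal(range(k$grid), range(x))
  expect_true(all(k$density >= 0))
  # symmetric sample -> symmetric density on the symmetric grid
  xs <- c(x, -x)
  ks <- kde_1d(xs)
  expect_lt(max(abs(ks$density - rev(ks$density))), 1e-10)
  expect_error(kde_1d(rep(1, 10)), "degenerate")
  expect_error(kde_1d(2), "at least 2")
})
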