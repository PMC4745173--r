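test_that("detail-block layout follows the submatrix convention", {
  l4 <- level_layout(4L, 32L)
  expect_identical(l4$z1_rows, 2L)
  expect_identical(l4$z1_cols, 9:16)
  expect_identical(l4$z2_rows, 3:4)
  expect_identical(l4$z2_cols, 17:32)
  l16 <- level_layout(16L, 64L)
  expect_identical(l16$z1_rows, 5:7)
  expect_identical(l16$z2_rows, 9:14)
  expect_false(any(c(8L, 15L, 16L) %in% c(l16$z1_rows, l16$z2_rows)))
  expect_error(level_layout(4L, 30L), "divisible")
})

test_that("homopolymer slope equals -log(8) in the configured base", {
  # Haar linear-ramp analysis: e2 = 1/8 (three finest rows of -1/2), e1 = 1
  s <- global_slope(strrep("A", 32))
  expect_equal(s$e1, 1, tolerance = 1e-12)
  expect_equal(s$e2, 1 / 8, tolerance = 1e-12)
  expect_equal(s$s, -log(8), tolerance = 1e-12)
  expect_equal(global_slope(strrep("A", 32), log_base = 2)$s, -3, tolerance = 1e-12)
  # single-code homopolymers share the same ramp structure
  expect_equal(global_slope(strrep("T", 32), mode = "single")$s, -log(8),
               tolerance = 1e-12)
})

test_that("degenerate energies map to infinities or missing, never errors", {
  layout <- level_layout(4L, 16L)
  Z <- matrix(0, 4, 16)
  Z[2, layout$z1_cols] <- 1
  s <- spectral_slope(Z, layout)
  expect_identical(s$s, -Inf)
  expect_identical(s$flag, "neg_inf")
  Z2 <- matrix(0, 4, 16)
  Z2[3, layout$z2_cols[1]] <- 2
  s2 <- spectral_slope(Z2, layout)
  expect_identical(s2$s, Inf)
  expect_identical(s2$flag, "pos_inf")
  s3 <- spectral_slope(matrix(0, 4, 16), layout)
  expect_true(is.na(s3$s))
  expect_identical(s3$flag, "missing")
  # equal blocks entrywise: comparable energies, slope 0
  Z4 <- matrix(0, 4, 16)
  Z4[2, layout$z1_cols] <- 0.5
  Z4[3:4, layout$z2_cols] <- 0.5
  expect_equal(spectral_slope(Z4, layout)$s, 0, tolerance = 1e-14)
})

test_that("global slope truncates to the leading power-of-2 prefix", {
  expect_equal(global_slope(strrep("A", 100))$s, global_slope(strrep("A", 64))$s,
               tolerance = 1e-12)
  s <- global_slope(rand_seq(877, 1))
  expect_identical(attr(s, "used_length"), 512L)
  expect_error(global_slope("ACGTACG"), "too short")
  # non-ACGT residues: missing by default, error in strict mode
  withN <- paste0(rand_seq(30, 2), "N", rand_seq(33, 3))
  expect_identical(global_slope(withN)$flag, "missing")
  expect_error(global_slope(withN, strict = TRUE), "unmappable")
})

test_that("single-code slopes depend only on the equivalence class", {
  orders <- all_assignments()
  cls <- vapply(orders, classify_assignment, integer(1L))
  for (seed in c(5, 6)) {
    x <- rand_seq(128, seed)
    slopes <- vapply(orders, function(o) {
      global_slope(x, mode = "single", code = o)$s
    }, numeric(1L))
    # all 8 members of a class agree exactly; at most 3 distinct values
    for (k in 1:3) {
      expect_lt(diff(range(slopes[cls == k])), 1e-12)
    }
    expect_lte(length(unique(round(slopes, 9))), 3L)
    pcs <- per_class_slopes(x)
    expect_equal(pcs$s1, unname(slopes[["ACGT"]]), tolerance = 1e-12)
    expect_equal(pcs$s1, unname(slopes[["TGCA"]]), tolerance = 1e-12)
    expect_equal(pcs$mean, mean(c(pcs$s1, pcs$s2, pcs$s3)), tolerance = 1e-12)
  }
  pa <- per_class_slopes(strrep("A", 64))
  expect_equal(pa$s1, pa$s2, tolerance = 1e-12)
  expect_equal(pa$s2, pa$s3, tolerance = 1e-12)
})

test_that("invariant slope is independent of representatives and block order", {
  x <- rand_seq(256, 17)
  ref <- global_slope(x)$s
  orders <- all_assignments()
  cls <- vapply(orders, classify_assignment, integer(1L))
  set.seed(33)
  for (i in 1:6) {
    triple <- c(sample(orders[cls == 1L], 1L), sample(orders[cls == 2L], 1L),
                sample(orders[cls == 3L], 1L))
    triple <- sample(triple)  # random block order too
    expect_lt(abs(global_slope(x, reps = triple)$s - ref), 1e-9)
  }
})

test_that("evolutionary slope windows tile the sequence as specified", {
  x <- rand_seq(64, 21)
  ser <- evolutionary_slope(x, window = 32L, step = 8L)
  expect_identical(ser$window_start, c(1L, 9L, 17L, 25L, 33L))
  expect_identical(ser$window_end, ser$window_start + 31L)
  expect_identical(nrow(ser), 5L)
  expect_error(evolutionary_slope(x, window = 30L), "divisible")
  expect_error(evolutionary_slope(x, window = 32L, step = 6L), "divisible")
  expect_error(evolutionary_slope(rand_seq(16, 1), window = 32L), "shorter")
})

test_that("restarting cumulation per window equals slicing the global Y*", {
  x <- rand_seq(200, 8)
  ser <- evolutionary_slope(x, window = 32L, step = 8L)
  Ystar_full <- cumulate(encode_invariant(x))
  layout <- level_layout(16L, 32L)
  for (i in seq_len(nrow(ser))) {
    sliced <- Ystar_full[, ser$window_start[i]:ser$window_end[i], drop = FALSE]
    s_slice <- spectral_slope(scale_mixing_transform(sliced), layout)
    expect_lt(abs(s_slice$s - ser$slope[i]), 1e-8)
  }
})

test_that("homogeneous input gives a flat slope series; Ns give missing windows", {
  ser <- evolutionary_slope(strrep("A", 96), window = 32L, step = 8L)
  expect_lt(diff(range(ser$slope)), 1e-12)
  expect_equal(ser$slope[1], -log(8), tolerance = 1e-12)

  x <- paste0(rand_seq(40, 4), "N", rand_seq(55, 5))
  ser2 <- evolutionary_slope(x, window = 32L, step = 8L)
  hits <- ser2$window_start <= 41L & ser2$window_end >= 41L
  expect_true(all(is.na(ser2$slope[hits])))
  expect_true(all(ser2$flag[hits] == "missing"))
  expect_true(all(is.finite(ser2$slope[!hits])))
})

test_that("persistent sequences score more negative slopes than iid ones", {
  probs <- c(0.3, 0.2, 0.2, 0.3)
  n <- 32L + 8L * 249L  # 250 windows
  pers <- markov_dna(n, probs, persistence = 0.95, seed = 101)
  iid <- random_dna(n, probs, seed = 102)
  s_pers <- evolutionary_slope(pers)$slope
  s_iid <- evolutionary_slope(iid)$slope
  ht <- two_sample_t(s_pers[is.finite(s_pers)], s_iid[is.finite(s_iid)],
                     alternative = "less")
  expect_lt(ht$p, 0.01)
  expect_lt(mean(s_pers[is.finite(s_pers)]), mean(s_iid[is.finite(s_iid)]))
})
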