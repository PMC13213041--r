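test_that("dual regression inverts noiseless mixtures exactly", {
  g <- tiny_grid()
  basis <- tiny_basis(4, g, seed = 1)
  # orthogonalize maps so stage-1 recovery is the exact linear inverse
  Q <- qr.Q(qr(basis$maps))
  basis$maps <- Q
  t_len <- 30
  tc_true <- matrix(rnorm(t_len * 4), t_len, 4)
  X <- tc_true %*% t(Q)          # T x V noiseless data
  dr <- dual_regression(X, basis)
  expect_false(dr$degenerate)
  expect_lt(max(abs(dr$timecourses - tc_true)), 1e-10)
})

test_that("dual regression tolerates noise at SNR 10", {
  g <- tiny_grid()
  basis <- tiny_basis(4, g, seed = 2)
  t_len <- 100
  set.seed(33)
  tc_true <- matrix(rnorm(t_len * 4), t_len, 4)
  signal <- tc_true %*% t(basis$maps)
  noise_sd <- sd(signal) / sqrt(10)
  X <- signal + matrix(rnorm(length(signal), sd = noise_sd), nrow = t_len)
  dr <- dual_regression(X, basis)
  for (k in 1:4) {
    expect_gt(abs(cor(dr$timecourses[, k], tc_true[, k])), 0.95)
  }
})

test_that("dual regression flags degenerate input and bad designs", {
  g <- tiny_grid()
  basis <- tiny_basis(3, g, seed = 3)
  X <- matrix(0, 20, sum(g$mask))
  dr <- dual_regression(X, basis)
  expect_true(dr$degenerate)
  expect_true(all(dr$timecourses == 0))

  rank_def <- basis
  rank_def$maps[, 2] <- rank_def$maps[, 1]
  expect_error(dual_regression(X, rank_def), "condition number")
  expect_error(dual_regression(array(0, c(5, 5, 5, 3)), basis),
               "does not match")
})

test_that("FC computation has the Pearson correlation's exact properties", {
  tc <- cbind(a = rnorm(50), b = rnorm(50))
  tc <- cbind(tc, c = tc[, 1], d = -tc[, 1])
  fc <- fc_from_timeseries(tc)
  expect_equal(fc[1, 3], 1)
  expect_equal(fc[1, 4], -1)
  expect_true(all(diag(fc) == 1))
  expect_true(all(abs(fc) <= 1 + 1e-12))
  # invariance to affine rescaling of a component
  tc2 <- tc; tc2[, 2] <- 5 * tc2[, 2] - 7
  expect_equal(fc_from_timeseries(tc2), fc, tolerance = 1e-12)
  # zero-variance component is a typed error naming the component
  tc3 <- tc; tc3[, 2] <- 1
  expect_error(fc_from_timeseries(tc3), "IC2")
  expect_error(fc_from_timeseries(tc[1:2, ]), "3 timepoints")
})

test_that("feature table has the documented shape and edge order", {
  ch <- planted_cohort(k = 4, n = c(3, 3), t_len = 50, seed = 5)
  ft <- build_feature_table(ch)
  expect_equal(ncol(ft) - 2, 6)   # 4 * 3 / 2 edges
  em <- edge_map(ft)
  expect_equal(em$edge, c("IC1_IC2", "IC1_IC3", "IC1_IC4",
                          "IC2_IC3", "IC2_IC4", "IC3_IC4"))
  # 16 retained of 25 components -> 120 edges
  ch25 <- simulate_cohort(25, list(A = diag(25), B = diag(25)), c(2, 2),
                          n_timepoints = 40, seed = 6)
  keep16 <- setdiff(1:25, c(4, 15, 16, 18, 20, 21, 24))[1:16]
  ft25 <- build_feature_table(ch25, keep16)
  expect_equal(ncol(ft25) - 2, 120)
  expect_equal(nrow(edge_map(ft25)), 16 * 15 / 2)
})

test_that("feature table round-trips FC entries and ignores subject order", {
  ch <- planted_cohort(k = 4, n = c(3, 3), t_len = 50, seed = 7)
  ft <- build_feature_table(ch)
  em <- edge_map(ft)
  # round-trip: every FC entry is recoverable from the table
  for (s in c(1, 4)) {
    fc <- fc_from_timeseries(ch$timeseries[[s]])
    row <- ft[ft$subject_id == ch$subjects$subject_id[s], ]
    for (r in seq_len(nrow(em))) {
      expect_equal(row[[em$edge[r]]], fc[em$i[r], em$j[r]])
    }
  }
  # permuting subject input order permutes rows only
  perm <- c(4, 2, 6, 1, 3, 5)
  ft2 <- build_feature_table(ch$timeseries[perm],
                             labels = ch$subjects$label[perm])
  ft2 <- ft2[match(ft$subject_id, ft2$subject_id), ]
  expect_equal(as.data.frame(ft2), as.data.frame(ft), ignore_attr = TRUE)
})

test_that("subjects with failed FC are excluded with a warning, not imputed", {
  ch <- planted_cohort(k = 3, n = c(3, 3), t_len = 40, seed = 8)
  ch$timeseries[[2]][, 1] <- 0   # zero-variance component
  expect_warning(ft <- build_feature_table(ch), "excluded 1 subject")
  expect_equal(nrow(ft), 5)
  expect_false(ch$subjects$subject_id[2] %in% ft$subject_id)
})

test_that("noiseless pipeline is end-to-end exact through FC", {
  # dual-regression stage-1 output equals generating time courses up to
  # per-component scale, and FC is scale invariant, so FC of recovered
  # time courses equals FC of the truth
  g <- tiny_grid()
  basis <- tiny_basis(4, g, seed = 9)
  t_len <- 60
  set.seed(10)
  tc_true <- matrix(rnorm(t_len * 4), t_len, 4)
  X <- tc_true %*% t(basis$maps)
  dr <- dual_regression(X, basis)
  expect_equal(fc_from_timeseries(dr$timecourses),
               fc_from_timeseries(tc_true), tolerance = 1e-9)
})
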