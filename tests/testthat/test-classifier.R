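quiet_fit <- function(...) suppressWarnings(tune_and_fit_cv(...))

# a small feature-table tibble built directly from a matrix
as_features <- function(X, labels) {
  k <- (1 + sqrt(1 + 8 * ncol(X))) / 2
  em <- connsig:::upper_pairs(seq_len(k))
  colnames(X) <- em$edge
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%03d", seq_len(nrow(X))),
                   label = labels),
    tibble::as_tibble(as.data.frame(X)))
  attr(out, "edge_map") <- em
  out
}

test_that("a separable toy problem is classified perfectly in every fold", {
  set.seed(1)
  n <- 28
  X <- rbind(matrix(rnorm(n / 2 * 6, mean = -2, sd = 0.3), ncol = 6),
             matrix(rnorm(n / 2 * 6, mean = 2, sd = 0.3), ncol = 6))
  ft <- as_features(X, rep(c("A", "B"), each = n / 2))
  fit <- quiet_fit(ft, c("A", "B"),
                   enet_config(C_grid = 100, l1_ratio_grid = 0.5,
                               k_folds = 7, seed = 2))
  expect_true(all(fit$metrics$accuracy == 1))
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(n * 10), ncol = 10)
  # fixed hyperparameters: tuning on permuted labels would add the usual
  # optimistic max-over-grid selection bias, which is not the chance level
  accs <- vapply(1:40, function(r) {
    labels <- sample(rep(c("A", "B"), each = n / 2))
    ft <- as_features(X, labels)
    fit <- quiet_fit(ft, c("A", "B"),
                     enet_config(C_grid = 1, l1_ratio_grid = 0.5,
                                 k_folds = 4, seed = r))
    mean(fit$metrics$accuracy)
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("lasso at small C zeroes most uninformative features", {
  ch <- planted_cohort(k = 16, n = c(40, 40), t_len = 300, r_low = 0.1,
                       r_high = 0.7, seed = 4)
  ft <- build_feature_table(ch)
  fit <- quiet_fit(ft, c("groupA", "groupB"),
                   enet_config(C_grid = 0.05, l1_ratio_grid = 1,
                               k_folds = 5, seed = 5))
  w <- tidy(fit)$estimate
  em <- edge_map(ft)
  truth_zero <- !(em$i == 1 & em$j == 2)
  expect_gte(mean(w[truth_zero] == 0), 0.8)
})

test_that("selection is reproducible and class weighting behaves", {
  ch <- planted_cohort(k = 5, n = c(12, 12), t_len = 100, seed = 6)
  ft <- build_feature_table(ch)
  cfg <- enet_config(C_grid = c(0.1, 1, 10), l1_ratio_grid = c(0.5, 1),
                     k_folds = 4, seed = 7)
  f1 <- quiet_fit(ft, c("groupA", "groupB"), cfg)
  f2 <- quiet_fit(ft, c("groupA", "groupB"), cfg)
  expect_identical(f1$folds, f2$folds)
  expect_identical(f1$chosen, f2$chosen)
  expect_identical(f1$fold_weights, f2$fold_weights)

  # equal class sizes: balanced weights coincide with unweighted fits
  cfg_b <- enet_config(C_grid = c(0.1, 1, 10), l1_ratio_grid = c(0.5, 1),
                       k_folds = 4, class_weight = "balanced", seed = 7)
  f3 <- quiet_fit(ft, c("groupA", "groupB"), cfg_b)
  expect_equal(f3$fold_weights, f1$fold_weights, tolerance = 1e-8)
})

test_that("held-out metrics are internally consistent", {
  # balanced accuracy equals accuracy when class predictions are balanced
  prob <- c(0.9, 0.8, 0.2, 0.1)
  y <- c(1, 1, 0, 0)
  m <- connsig:::fold_metrics(prob, y)
  expect_equal(m$accuracy, m$balanced_accuracy)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$pr_auc, 1)
  # ROC-AUC is invariant to monotone transforms of the scores
  s <- c(0.1, 0.4, 0.35, 0.8, 0.7)
  y2 <- c(0, 0, 1, 1, 1)
  expect_equal(connsig:::roc_auc(s, y2), connsig:::roc_auc(exp(3 * s), y2))
  # hand-checked Mann-Whitney value
  expect_equal(connsig:::roc_auc(s, y2), 5 / 6)
})

test_that("fold counts adapt to small classes and bad contrasts error", {
  ch <- planted_cohort(k = 4, n = c(4, 12), t_len = 60, seed = 8)
  ft <- build_feature_table(ch)
  w <- testthat::capture_warnings(
    fit <- suppressMessages(
      tune_and_fit_cv(ft, c("groupA", "groupB"),
                      enet_config(C_grid = 1, l1_ratio_grid = 1,
                                  k_folds = 7, seed = 9))))
  expect_true(any(grepl("reducing folds", w)))
  expect_equal(nrow(fit$metrics), 4)
  expect_error(tune_and_fit_cv(ft, c("groupA", "nope")), "not both present")
  expect_error(tune_and_fit_cv(ft, "groupA"), "exactly two")
})

test_that("internal ROC-AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (r in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    ref <- suppressMessages(as.numeric(pROC::auc(y, s)))
    expect_equal(connsig:::roc_auc(s, y), ref, tolerance = 1e-12)
  }
})
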