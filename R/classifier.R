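#' Elastic-net classifier configuration
#'
#' Hyperparameter grids and cross-validation settings for the penalized
#' logistic classifier. `C` is the inverse regularization strength (larger =
#' weaker penalty) and `l1_ratio` the L1-to-L2 mixing weight; internally a
#' grid point maps onto the coordinate-descent parameterization as
#' `lambda = 1 / (n_train * C)`, `alpha = l1_ratio`.
#'
#' @param C_grid Positive inverse-regularization values. The default brackets
#'   two orders of magnitude either side of 1.
#' @param l1_ratio_grid Mixing values in `[0, 1]`.
#' @param k_folds Stratified cross-validation folds (default 7, sized so a
#'   held-out fold holds a few subjects at typical cohort sizes).
#' @param class_weight `"none"` or `"balanced"` (weights `n / (2 n_class)`).
#' @param standardize Z-score features inside the solver (recorded in
#'   provenance; customary for elastic net).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(C_grid = 10^seq(-2, 2, length.out = 25),
                        l1_ratio_grid = seq(0.05, 1, by = 0.05),
                        k_folds = 7, class_weight = c("none", "balanced"),
                        standardize = TRUE, seed = 1) {
  class_weight <- match.arg(class_weight)
  if (!length(C_grid) || any(C_grid <= 0)) {
    stop("`C_grid` must be positive", call. = FALSE)
  }
  if (!length(l1_ratio_grid) ||
      any(l1_ratio_grid < 0 | l1_ratio_grid > 1)) {
    stop("`l1_ratio_grid` must lie in [0, 1]", call. = FALSE)
  }
  if (k_folds < 2) stop("`k_folds` must be >= 2", call. = FALSE)
  structure(list(C_grid = sort(C_grid), l1_ratio_grid = sort(l1_ratio_grid),
                 k_folds = as.integer(k_folds), class_weight = class_weight,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "enet_config")
}

# stratified fold assignment; redraws (logged) if any fold ends single-class
stratified_folds <- function(y, k, seed, max_tries = 20) {
  for (try in seq_len(max_tries)) {
    folds <- with_seed(seed + try - 1L, {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(fd) {
      length(unique(y[folds != fd])) == 2 && sum(folds == fd) > 0
    }, logical(1)))
    if (ok) {
      if (try > 1) {
        message("fold assignment redrawn ", try - 1,
                " time(s) to avoid a single-class split")
      }
      return(folds)
    }
  }
  stop("could not build stratified folds without a single-class split",
       call. = FALSE)
}

roc_auc <- function(scores, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-wise PR-AUC)
pr_auc <- function(scores, y01) {
  n1 <- sum(y01 == 1)
  if (n1 == 0 || sum(y01 == 0) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y01[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / n1
}

fold_metrics <- function(prob, y01) {
  pred <- as.integer(prob >= 0.5)
  acc <- mean(pred == y01)
  by_class <- vapply(c(0, 1), function(cl) {
    if (!any(y01 == cl)) return(NA_real_)
    mean(pred[y01 == cl] == cl)
  }, numeric(1))
  tibble::tibble(accuracy = acc,
                 balanced_accuracy = mean(by_class, na.rm = TRUE),
                 roc_auc = roc_auc(prob, y01),
                 pr_auc = pr_auc(prob, y01))
}

#' Tune and fit the penalized connectivity classifier
#'
#' Grid-searches `(C, l1_ratio)` by stratified k-fold cross-validation on a
#' two-class contrast of the feature table, selecting the point with maximal
#' mean held-out accuracy (ties broken toward sparser models: larger
#' `l1_ratio`, then smaller `C`). Per-fold models refit at the chosen point
#' are retained for back-projection, and held-out metrics are summarized as
#' mean and SD across folds.
#'
#' @param features A [build_feature_table()] tibble.
#' @param contrast Two labels, as `c("groupA", "groupC")` or `"groupA:groupC"`.
#'   The second label is scored as the positive class.
#' @param config An [enet_config()].
#' @return An object of class `connsig_cv`: fold weights, chosen
#'   hyperparameters, per-fold and summarized metrics, fold assignment and
#'   edge map. Use [tidy()] for edge weights and [glance()] for the metric
#'   summary.
#' @export
tune_and_fit_cv <- function(features, contrast, config = enet_config()) {
  stopifnot(inherits(config, "enet_config"))
  if (is.character(contrast) && length(contrast) == 1L) {
    contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  }
  if (length(contrast) != 2L) {
    stop("`contrast` must select exactly two labels", call. = FALSE)
  }
  emap <- edge_map(features)
  sub <- features[features$label %in% contrast, , drop = FALSE]
  if (length(unique(sub$label)) != 2L) {
    stop("contrast labels not both present in the data", call. = FALSE)
  }
  X <- as.matrix(sub[, emap$edge, drop = FALSE])
  y01 <- as.integer(sub$label == contrast[2])
  n <- nrow(X)
  k <- config$k_folds
  min_class <- min(table(y01))
  if (min_class < k) {
    warning("reducing folds from ", k, " to ", min_class,
            " (smallest class size)", call. = FALSE)
    k <- min_class
  }
  folds <- stratified_folds(y01, k, config$seed)

  weights_for <- function(yy) {
    if (config$class_weight == "balanced") {
      tab <- table(yy)
      as.numeric(length(yy) / (2 * tab[as.character(yy)]))
    } else rep(1, length(yy))
  }

  # grid search: one coordinate-descent path per (alpha, fold)
  acc <- array(NA_real_, dim = c(length(config$C_grid),
                                 length(config$l1_ratio_grid), k))
  for (ai in seq_along(config$l1_ratio_grid)) {
    alpha <- config$l1_ratio_grid[ai]
    for (fd in seq_len(k)) {
      tr <- folds != fd
      lam <- rev(1 / (sum(tr) * config$C_grid))  # decreasing for the solver
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y01[tr],
                            family = "binomial", alpha = alpha,
                            lambda = lam, standardize = config$standardize,
                            weights = weights_for(y01[tr]),
                            thresh = 1e-9, maxit = 1e5)
      prob <- stats::predict(fit, X[!tr, , drop = FALSE], s = lam,
                             type = "response", exact = FALSE)
      acc[, ai, fd] <- rev(colMeans((prob >= 0.5) == y01[!tr]))
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)
  best <- max(mean_acc)
  cand <- which(mean_acc >= best - 1e-12, arr.ind = TRUE)
  # ties: larger l1_ratio, then smaller C
  cand <- cand[order(-cand[, 2], cand[, 1]), , drop = FALSE]
  ci <- cand[1, 1]; ai <- cand[1, 2]
  C_star <- config$C_grid[ci]
  alpha_star <- config$l1_ratio_grid[ai]

  # refit per fold at the chosen point; collect weights and held-out metrics
  W <- matrix(NA_real_, k, nrow(emap),
              dimnames = list(NULL, emap$edge))
  intercepts <- numeric(k)
  met <- vector("list", k)
  for (fd in seq_len(k)) {
    tr <- folds != fd
    lam <- rev(1 / (sum(tr) * config$C_grid))
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y01[tr],
                          family = "binomial", alpha = alpha_star,
                          lambda = lam, standardize = config$standardize,
                          weights = weights_for(y01[tr]),
                          thresh = 1e-9, maxit = 1e5)
    s_star <- 1 / (sum(tr) * C_star)
    cf <- as.matrix(stats::coef(fit, s = s_star, exact = FALSE))
    intercepts[fd] <- cf[1, 1]
    W[fd, ] <- cf[-1, 1]
    prob <- as.numeric(stats::predict(fit, X[!tr, , drop = FALSE],
                                      s = s_star, type = "response"))
    met[[fd]] <- fold_metrics(prob, y01[!tr])
  }
  metrics <- dplyr::bind_cols(tibble::tibble(fold = seq_len(k)),
                              dplyr::bind_rows(met))
  summary_tb <- metrics |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")

  structure(list(contrast = contrast, positive_label = contrast[2],
                 config = config, chosen = list(C = C_star,
                                                l1_ratio = alpha_star),
                 fold_weights = W, intercepts = intercepts,
                 metrics = metrics, metric_summary = summary_tb,
                 folds = folds, edge_map = emap,
                 mean_cv_accuracy = mean_acc,
                 subject_id = sub$subject_id),
            class = "connsig_cv")
}

#' @export
print.connsig_cv <- function(x, ...) {
  cat("<connsig_cv> contrast", paste(x$contrast, collapse = " vs "),
      "| chosen C =", signif(x$chosen$C, 3),
      ", l1_ratio =", x$chosen$l1_ratio, "\n")
  acc <- x$metric_summary[x$metric_summary$metric == "accuracy", ]
  cat(sprintf("  held-out accuracy %.2f [%.2f] over %d folds\n",
              acc$mean, acc$sd, nrow(x$metrics)))
  invisible(x)
}

#' @rdname tune_and_fit_cv
#' @param x A `connsig_cv` object.
#' @param ... Unused.
#' @method tidy connsig_cv
#' @export
tidy.connsig_cv <- function(x, ...) {
  tibble::tibble(edge = colnames(x$fold_weights),
                 estimate = colMeans(x$fold_weights),
                 sd = apply(x$fold_weights, 2, stats::sd))
}

#' @rdname tune_and_fit_cv
#' @method glance connsig_cv
#' @export
glance.connsig_cv <- function(x, ...) {
  wide <- x$metric_summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble::tibble(contrast = paste(x$contrast,
                                                   collapse = ":"),
                                  C = x$chosen$C,
                                  l1_ratio = x$chosen$l1_ratio,
                                  k_folds = nrow(x$metrics)),
                   wide)
}
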