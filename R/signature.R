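#' Back-project classifier weights into a voxel signature map
#'
#' Edge weights are averaged across cross-validation folds; each component's
#' weight is the sum of its averaged edge weights (`w_i = sum_j W(i, j)`);
#' the voxel signature is the weight-combined basis,
#' `map = sum_i w_i * IC_i`. Both steps are linear in the edge weights.
#'
#' @param fit A [tune_and_fit_cv()] result, or a numeric vector of averaged
#'   edge weights named by edge.
#' @param ic_basis The [make_ic_basis()] the features came from.
#' @param edge_map Required when `fit` is a bare weight vector.
#' @return A `signature_map`: list with `contrast`, `ic_weights` (named by
#'   component id), `values` (in-mask voxel vector), `grid`, `provenance`.
#' @export
backproject_signature <- function(fit, ic_basis, edge_map = NULL) {
  stopifnot(inherits(ic_basis, "ic_basis"))
  if (inherits(fit, "connsig_cv")) {
    wbar <- colMeans(fit$fold_weights)
    emap <- fit$edge_map
    contrast <- paste(fit$contrast, collapse = "-vs-")
    prov <- list(folds = nrow(fit$fold_weights), chosen = fit$chosen)
  } else {
    wbar <- fit
    emap <- edge_map
    if (is.null(emap)) stop("`edge_map` required for a bare weight vector",
                            call. = FALSE)
    wbar <- wbar[emap$edge]
    contrast <- "custom"
    prov <- list()
  }
  ids <- sort(unique(c(emap$i, emap$j)))
  if (!all(ids %in% ic_basis$included_ids) || max(ids) > ncol(ic_basis$maps)) {
    stop("edge map references a component absent from the basis",
         call. = FALSE)
  }
  ic_w <- stats::setNames(numeric(length(ids)), ids)
  for (r in seq_len(nrow(emap))) {
    ic_w[as.character(emap$i[r])] <- ic_w[as.character(emap$i[r])] + wbar[r]
    ic_w[as.character(emap$j[r])] <- ic_w[as.character(emap$j[r])] + wbar[r]
  }
  vals <- as.numeric(ic_basis$maps[, ids, drop = FALSE] %*% ic_w)
  structure(list(contrast = contrast, ic_weights = ic_w, values = vals,
                 grid = ic_basis$grid,
                 provenance = c(prov, list(edge_weights = wbar))),
            class = "signature_map")
}

#' @export
print.signature_map <- function(x, ...) {
  cat("<signature_map>", x$contrast, "|", length(x$values), "mask voxels |",
      length(x$ic_weights), "component weights\n")
  invisible(x)
}

# per-fold IC-weight matrix (folds x components) from fold edge weights
fold_ic_weights <- function(W, emap) {
  ids <- sort(unique(c(emap$i, emap$j)))
  out <- matrix(0, nrow(W), length(ids),
                dimnames = list(NULL, as.character(ids)))
  for (r in seq_len(nrow(emap))) {
    out[, as.character(emap$i[r])] <- out[, as.character(emap$i[r])] + W[, r]
    out[, as.character(emap$j[r])] <- out[, as.character(emap$j[r])] + W[, r]
  }
  out
}

#' Cross-fold stability of the classifier weight profile
#'
#' Pairwise Pearson correlations between folds at three levels: the edge
#' weight vectors, the component weight vectors obtained by summing each
#' component's edge weights, and the back-projected voxel maps. Each level is
#' reported as mean and SD over fold pairs. Fold pairs involving an all-zero
#' weight vector are reported as `NA`, never dropped silently.
#'
#' @param fit A [tune_and_fit_cv()] result with at least 2 folds.
#' @param ic_basis The basis used for back-projection.
#' @return List with `summary` (tibble: level, mean, sd, n_pairs,
#'   n_undefined) and `pairs` (tibble of per-pair correlations).
#' @export
stability_report <- function(fit, ic_basis) {
  stopifnot(inherits(fit, "connsig_cv"))
  W <- fit$fold_weights
  k <- nrow(W)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  icw <- fold_ic_weights(W, fit$edge_map)
  ids <- as.integer(colnames(icw))
  vox <- icw %*% t(ic_basis$maps[, ids, drop = FALSE])  # folds x voxels

  level_pairs <- function(M, level) {
    prs <- utils::combn(k, 2)
    tibble::tibble(
      level = level,
      fold_a = prs[1, ], fold_b = prs[2, ],
      r = vapply(seq_len(ncol(prs)), function(p) {
        a <- M[prs[1, p], ]; b <- M[prs[2, p], ]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
        stats::cor(a, b)
      }, numeric(1)))
  }
  pairs <- dplyr::bind_rows(level_pairs(W, "edge_weights"),
                            level_pairs(icw, "ic_weights"),
                            level_pairs(vox, "voxel_maps"))
  summary <- pairs |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(mean = mean(.data$r, na.rm = TRUE),
                     sd = stats::sd(.data$r, na.rm = TRUE),
                     n_pairs = dplyr::n(),
                     n_undefined = sum(is.na(.data$r)),
                     .groups = "drop") |>
    dplyr::arrange(factor(.data$level, levels = c("edge_weights",
                                                  "ic_weights",
                                                  "voxel_maps")))
  list(summary = summary, pairs = pairs)
}

#' Pearson correlation between two signature maps
#'
#' @param sig_a,sig_b `signature_map`s (or in-mask value vectors) on the same
#'   grid and mask.
#' @param grid Required when bare vectors are supplied.
#' @return A single correlation, or `NA` (with a warning) when either map is
#'   constant.
#' @export
compare_signatures <- function(sig_a, sig_b, grid = NULL) {
  if (inherits(sig_a, "signature_map") && inherits(sig_b, "signature_map")) {
    if (!same_grid(sig_a$grid, sig_b$grid)) {
      stop("signatures are on different grids", call. = FALSE)
    }
    a <- sig_a$values; b <- sig_b$values
  } else {
    a <- as.numeric(if (inherits(sig_a, "signature_map")) sig_a$values
                    else sig_a)
    b <- as.numeric(if (inherits(sig_b, "signature_map")) sig_b$values
                    else sig_b)
  }
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant map: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}
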