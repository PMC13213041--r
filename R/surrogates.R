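# k-nearest-neighbour table for all mask voxels: indices and inverse-distance
# weights up to k_max neighbours, computed in row chunks to bound memory.
knn_table <- function(grid, k_max, mask = NULL) {
  coords <- mask_coords(grid, mask)
  V <- nrow(coords)
  k_max <- min(k_max, V - 1L)
  idx <- matrix(0L, V, k_max)
  wts <- matrix(0, V, k_max)
  nrm <- rowSums(coords^2)
  step <- 2048L
  for (start in seq(1L, V, by = step)) {
    rows <- start:min(start + step - 1L, V)
    d2 <- outer(nrm[rows], nrm, "+") -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    for (r in seq_along(rows)) {
      ord <- order(d2[r, ])[2:(k_max + 1L)]  # drop self
      idx[rows[r], ] <- ord
      wts[rows[r], ] <- 1 / pmax(sqrt(pmax(d2[r, ord], 0)), 1e-8)
    }
  }
  list(idx = idx, w = wts, k_max = k_max)
}

# smooth a value vector with the first k neighbours of a knn table
knn_smooth <- function(values, knn, k) {
  k <- min(k, knn$k_max)
  M <- matrix(values[knn$idx[, 1:k]], ncol = k) * knn$w[, 1:k, drop = FALSE]
  rowSums(M) / rowSums(knn$w[, 1:k, drop = FALSE])
}

# weight-sum denominators per candidate k (value independent; computed once)
knn_weight_sums <- function(knn, ks) {
  out <- matrix(0, nrow(knn$w), length(ks))
  wacc <- 0
  start <- 1L
  for (t in seq_along(ks)) {
    wacc <- wacc + rowSums(knn$w[, start:ks[t], drop = FALSE])
    out[, t] <- wacc
    start <- ks[t] + 1L
  }
  out
}

# smoothings at every candidate k in one pass: cumulative sums over the
# neighbour axis, segmented at the sorted candidate sizes
knn_smooth_all <- function(values, knn, ks, wsum) {
  P <- matrix(values[knn$idx], nrow = nrow(knn$idx)) * knn$w
  out <- matrix(0, nrow(P), length(ks))
  acc <- 0
  start <- 1L
  for (t in seq_along(ks)) {
    acc <- acc + rowSums(P[, start:ks[t], drop = FALSE])
    out[, t] <- acc / wsum[, t]
    start <- ks[t] + 1L
  }
  out
}

# nonnegative least squares of gamma_src ~ alpha * gamma_sm + beta
fit_vgm_scale <- function(g_src, g_sm) {
  ok <- is.finite(g_src) & is.finite(g_sm)
  x <- g_sm[ok]; y <- g_src[ok]
  cf <- stats::coef(stats::lm.fit(cbind(x, 1), y))
  a <- cf[1]; b <- cf[2]
  if (a < 0) { a <- 0; b <- mean(y) }
  if (b < 0) { b <- 0; a <- sum(x * y) / sum(x^2) }
  sse <- sum((y - (a * x + b))^2)
  list(alpha = a, beta = b, sse = sse)
}

#' Variogram-matched surrogate maps
#'
#' Builds spatially honest null maps for a source brain map. Each surrogate
#' is produced by (1) randomly permuting the source values over the mask,
#' (2) smoothing the permuted map with a k-nearest-neighbour inverse-distance
#' kernel at each candidate neighbourhood size, (3) least-squares matching a
#' scale and nugget (`surrogate = sqrt(alpha) * smoothed + sqrt(beta) *
#' white noise`) of the surrogate variogram to the source variogram,
#' (4) rank-mapping each candidate's values onto the source map's empirical
#' value distribution, and (5) keeping the candidate scale whose realized
#' (remapped) surrogate has minimal variogram SSE against the source.
#' Every surrogate therefore has exactly the source value multiset but a
#' randomized, autocorrelation-matched spatial arrangement.
#'
#' @param map Source map (in-mask vector, `signature_map`/`gene_map`, or 3-D
#'   array).
#' @param grid The [vol_grid()].
#' @param n Number of surrogates (>= 100 recommended for inference).
#' @param seed Integer seed.
#' @param knn_grid Candidate neighbourhood sizes for the smoothing kernel.
#'   The default spans sub-voxel to multi-centimetre scales so smooth fields
#'   can be matched on millimetre-resolution grids.
#' @param n_bins,max_frac,subsample Variogram settings (see
#'   [empirical_variogram()]).
#' @param mask Optional logical array restricting the scope.
#' @return A `surrogate_ensemble`: list with `values` (n x V matrix),
#'   `k_chosen`, `sse` (per-surrogate variogram fit error), `source_values`,
#'   `grid`, `settings`.
#' @export
generate_surrogates <- function(map, grid, n = 1000, seed = 1,
                                knn_grid = c(3, 10, 30, 80, 150, 300, 600),
                                n_bins = 25, max_frac = 0.5,
                                subsample = 500, mask = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!length(knn_grid)) stop("`knn_grid` is empty", call. = FALSE)
  values <- if (is.array(map) && length(dim(map)) == 3L) {
    mask_values(map, grid, mask)
  } else extract_map_values(map, grid)
  V <- length(values)
  knn <- knn_table(grid, max(knn_grid), mask)
  knn_grid <- sort(unique(pmin(knn_grid, knn$k_max)))
  vs <- variogram_structure(grid, n_bins, max_frac, subsample,
                            seed = stage_seed(seed, "variogram"),
                            mask = mask)
  g_src <- variogram_eval(values, vs)
  src_sorted <- sort(values)

  wsum <- knn_weight_sums(knn, knn_grid)
  out <- with_seed(seed, {
    surr <- matrix(NA_real_, n, V)
    kch <- integer(n)
    sse <- numeric(n)
    for (s in seq_len(n)) {
      perm <- values[sample.int(V)]
      SM <- knn_smooth_all(perm, knn, knn_grid, wsum)
      noise <- stats::rnorm(V)   # shared across candidates for a fair choice
      best <- NULL
      for (t in seq_along(knn_grid)) {
        sm <- SM[, t]
        ssd <- stats::sd(sm)
        if (!is.finite(ssd) || ssd == 0) next
        smz <- (sm - mean(sm)) / ssd
        fit <- fit_vgm_scale(g_src, variogram_eval(smz, vs))
        cand <- sqrt(fit$alpha) * smz + sqrt(fit$beta) * noise
        # rank-remap onto the source value distribution, then score the
        # realized surrogate: remapping itself perturbs the variogram, so
        # the scale choice must be made on the final product
        real <- src_sorted[rank(cand, ties.method = "first")]
        g_real <- variogram_eval(real, vs)
        ok <- is.finite(g_real) & is.finite(g_src)
        sse_real <- sum((g_real[ok] - g_src[ok])^2)
        if (is.null(best) || sse_real < best$sse) {
          best <- list(sse = sse_real, real = real, k = knn_grid[t])
        }
      }
      if (is.null(best)) {
        stop("all candidate smoothing scales are degenerate (constant ",
             "smoothed map); source map may be constant", call. = FALSE)
      }
      surr[s, ] <- best$real
      kch[s] <- best$k
      sse[s] <- best$sse
    }
    list(values = surr, k_chosen = kch, sse = sse)
  })
  structure(list(values = out$values, k_chosen = out$k_chosen,
                 sse = out$sse, source_values = values, grid = grid,
                 settings = list(n = n, seed = seed, knn_grid = knn_grid,
                                 n_bins = n_bins, max_frac = max_frac,
                                 subsample = subsample)),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble>", nrow(x$values), "surrogates x",
      ncol(x$values), "voxels | kernel sizes used:",
      paste(sort(unique(x$k_chosen)), collapse = ", "), "\n")
  invisible(x)
}

#' Naive (unconstrained) permutation null maps
#'
#' Plain random permutations of the source values with no autocorrelation
#' matching; the control null that a spatially constrained test is compared
#' against.
#'
#' @inheritParams generate_surrogates
#' @return A `surrogate_ensemble` with `k_chosen = NA`.
#' @export
generate_naive_permutations <- function(map, grid, n = 1000, seed = 1,
                                        mask = NULL) {
  values <- if (is.array(map) && length(dim(map)) == 3L) {
    mask_values(map, grid, mask)
  } else extract_map_values(map, grid)
  V <- length(values)
  surr <- with_seed(seed, {
    t(vapply(seq_len(n), function(s) values[sample.int(V)], numeric(V)))
  })
  structure(list(values = surr, k_chosen = rep(NA_integer_, n),
                 sse = rep(NA_real_, n), source_values = values,
                 grid = grid,
                 settings = list(n = n, seed = seed, naive = TRUE)),
            class = "surrogate_ensemble")
}
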