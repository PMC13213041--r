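# Precomputed pair structure for repeated variogram evaluation on one grid:
# a seeded voxel subsample, its pairwise mm distances, and per-pair bin ids.
variogram_structure <- function(grid, n_bins = 25, max_frac = 0.5,
                                subsample = 500, seed = 1, mask = NULL) {
  coords <- mask_coords(grid, mask)
  V <- nrow(coords)
  if (max_frac <= 0 || max_frac > 1) stop("`max_frac` must be in (0, 1]",
                                          call. = FALSE)
  n_sub <- min(subsample, V)
  if (n_sub < 2) stop("need at least 2 subsampled voxels", call. = FALSE)
  sub_idx <- if (n_sub == V) seq_len(V) else
    with_seed(seed, sort(sample.int(V, n_sub)))
  xy <- coords[sub_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xy))
  iu <- which(upper.tri(dmat), arr.ind = TRUE)
  dvec <- dmat[upper.tri(dmat)]
  dmax <- stats::quantile(dvec, max_frac, names = FALSE)
  keep <- dvec <= dmax & dvec > 0
  dvec <- dvec[keep]
  iu <- iu[keep, , drop = FALSE]
  breaks <- seq(0, dmax, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(dvec, breaks, left.open = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  h <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(sub_idx = sub_idx, pair_i = iu[, 1], pair_j = iu[, 2], bin = bin,
       h = h, counts = counts, n_bins = n_bins,
       settings = list(n_bins = n_bins, max_frac = max_frac,
                       subsample = n_sub, seed = seed))
}

# semivariance per bin for one value vector, given a structure
variogram_eval <- function(values, vs) {
  v <- values[vs$sub_idx]
  sq <- 0.5 * (v[vs$pair_i] - v[vs$pair_j])^2
  sums <- rep(0, vs$n_bins)
  agg <- rowsum(sq, vs$bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  ifelse(vs$counts > 0, sums / pmax(vs$counts, 1), NA_real_)
}

#' Empirical variogram of a brain map
#'
#' Semivariance `gamma(h) = mean of (x_i - x_j)^2 / 2` over voxel pairs in
#' each distance bin, with pairs drawn from a seeded random subsample of mask
#' voxels for tractability. Empty bins are dropped with a warning.
#'
#' @param map In-mask value vector, `gene_map`/`signature_map`, or 3-D array.
#' @param grid The [vol_grid()] the map lives on.
#' @param n_bins Number of distance bins.
#' @param max_frac Pairs are kept up to this quantile of pairwise distances.
#' @param subsample Voxel subsample size.
#' @param seed Seed for the subsample.
#' @param mask Optional logical array restricting the scope.
#' @return A `variogram` tibble with columns `h` (bin centre, mm), `gamma`,
#'   `n_pairs`, plus a `settings` attribute.
#' @export
empirical_variogram <- function(map, grid, n_bins = 25, max_frac = 0.5,
                                subsample = 500, seed = 1, mask = NULL) {
  values <- if (is.array(map) && length(dim(map)) == 3L) {
    mask_values(map, grid, mask)
  } else extract_map_values(map, grid)
  vs <- variogram_structure(grid, n_bins, max_frac, subsample, seed, mask)
  if (length(values) < max(vs$sub_idx)) {
    stop("map shorter than the mask it is evaluated on", call. = FALSE)
  }
  g <- variogram_eval(values, vs)
  empty <- vs$counts == 0
  if (any(empty)) {
    warning(sum(empty), " empty distance bin(s) dropped", call. = FALSE)
  }
  out <- tibble::tibble(h = vs$h[!empty], gamma = g[!empty],
                        n_pairs = vs$counts[!empty])
  attr(out, "settings") <- vs$settings
  class(out) <- c("variogram", class(out))
  out
}
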