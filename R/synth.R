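#' Generate a spatial component basis
#'
#' Creates `n_components` smooth, approximately localized spatial maps on a
#' common grid, emulating the group-level independent-component maps that a
#' data-driven decomposition of resting-state fMRI would provide. Each map is
#' Gaussian-smoothed white noise multiplied by a Gaussian envelope centred at
#' a random in-mask location, then unit-normalized over the mask.
#'
#' @param n_components Number of component maps (K >= 2).
#' @param grid A [vol_grid()].
#' @param smoothness_mm Gaussian kernel FWHM in mm controlling spatial
#'   autocorrelation; must be > 0 (values below one voxel give essentially
#'   unsmoothed fields).
#' @param seed Integer seed; the basis is a pure function of its arguments.
#' @param envelope_fwhm_mm FWHM of the localizing envelope; `Inf` disables
#'   localization.
#' @return An object of class `ic_basis`: list with `grid`, `maps` (V x K
#'   matrix of in-mask values, V = mask voxels), `included_ids` (1..K), and
#'   `provenance`.
#' @examples
#' g <- sphere_grid(c(12, 12, 12))
#' basis <- make_ic_basis(4, g, smoothness_mm = 8, seed = 1)
#' dim(basis$maps)
#' @export
make_ic_basis <- function(n_components, grid, smoothness_mm = 8, seed = 1,
                          envelope_fwhm_mm = 40) {
  stopifnot(inherits(grid, "vol_grid"))
  if (n_components < 2) stop("`n_components` must be >= 2", call. = FALSE)
  if (smoothness_mm <= 0) stop("`smoothness_mm` must be > 0", call. = FALSE)
  if (!any(grid$mask)) stop("grid mask is empty", call. = FALSE)

  coords <- mask_coords(grid)
  V <- nrow(coords)
  sig <- fwhm_to_sigma_vox(smoothness_mm, grid)
  maps <- with_seed(seed, {
    centres <- coords[sample.int(V, n_components, replace = TRUE), ,
                      drop = FALSE]
    vapply(seq_len(n_components), function(k) {
      field <- smooth_volume(array(stats::rnorm(prod(grid$shape)),
                                   dim = grid$shape), sig)
      v <- field[grid$mask]
      if (is.finite(envelope_fwhm_mm)) {
        s2 <- (envelope_fwhm_mm / (2 * sqrt(2 * log(2))))^2
        d2 <- rowSums(sweep(coords, 2, centres[k, ])^2)
        v <- v * exp(-d2 / (2 * s2))
      }
      v / sqrt(sum(v^2))
    }, numeric(V))
  })
  structure(list(grid = grid, maps = maps,
                 included_ids = seq_len(n_components),
                 provenance = list(n_components = n_components,
                                   smoothness_mm = smoothness_mm,
                                   envelope_fwhm_mm = envelope_fwhm_mm,
                                   seed = seed)),
            class = "ic_basis")
}

#' @export
print.ic_basis <- function(x, ...) {
  cat("<ic_basis> K =", ncol(x$maps), "maps on",
      paste(x$grid$shape, collapse = "x"), "grid,",
      nrow(x$maps), "mask voxels\n")
  invisible(x)
}

#' Build a group covariance with planted connectivity edges
#'
#' Starts from an exchangeable base correlation matrix and overwrites the
#' requested component pairs, then projects to the nearest positive-definite
#' correlation matrix so the result is always a valid generator.
#'
#' @param k Number of components.
#' @param base_r Off-diagonal correlation of the base matrix.
#' @param edges Optional data frame / tibble with columns `i`, `j`, `r`
#'   giving component pairs to overwrite.
#' @return A k x k positive-definite correlation matrix.
#' @export
group_covariance <- function(k, base_r = 0.1, edges = NULL) {
  S <- matrix(base_r, k, k)
  diag(S) <- 1
  if (!is.null(edges)) {
    for (row in seq_len(nrow(edges))) {
      i <- edges$i[row]; j <- edges$j[row]
      S[i, j] <- S[j, i] <- edges$r[row]
    }
  }
  nearest_pd(S)
}

#' Simulate a labelled cohort of component time series
#'
#' Each subject's T x K time series is drawn from a zero-mean multivariate
#' normal with its group's covariance, plus independent white noise. Group
#' differences in functional connectivity are planted through the covariance
#' matrices (see [group_covariance()]).
#'
#' @param ic_basis An `ic_basis` (fixes K) or an integer K.
#' @param group_covariances Named list of K x K positive-definite covariance
#'   matrices, one per group.
#' @param n_per_group Named or unnamed integer vector, subjects per group
#'   (same order as `group_covariances`).
#' @param n_timepoints Time points T per subject (default 400, a 10-minute
#'   scan at a 1.5 s sampling interval); must be >= K + 2.
#' @param noise_sd Standard deviation of additive white noise.
#' @param seed Integer seed.
#' @return A `cohort` object: list with `subjects` (tibble: subject_id,
#'   label), `timeseries` (named list of T x K matrices), and `provenance`.
#' @export
simulate_cohort <- function(ic_basis, group_covariances, n_per_group,
                            n_timepoints = 400, noise_sd = 0.5, seed = 1) {
  k <- if (inherits(ic_basis, "ic_basis")) ncol(ic_basis$maps)
       else as.integer(ic_basis)
  if (n_timepoints < k + 2) {
    stop("`n_timepoints` must be >= K + 2", call. = FALSE)
  }
  groups <- names(group_covariances)
  if (is.null(groups)) {
    groups <- paste0("group", LETTERS[seq_along(group_covariances)])
    names(group_covariances) <- groups
  }
  if (length(n_per_group) != length(groups)) {
    stop("`n_per_group` must match `group_covariances`", call. = FALSE)
  }
  for (g in groups) {
    S <- group_covariances[[g]]
    if (!isTRUE(all.equal(S, t(S))) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("covariance for group '", g,
           "' is not symmetric positive definite", call. = FALSE)
    }
  }
  labels <- rep(groups, times = n_per_group)
  ids <- sprintf("sub-%03d", seq_along(labels))
  ts_list <- with_seed(seed, {
    lapply(seq_along(labels), function(s) {
      S <- group_covariances[[labels[s]]]
      x <- MASS::mvrnorm(n_timepoints, mu = rep(0, k), Sigma = S)
      x + matrix(stats::rnorm(n_timepoints * k, sd = noise_sd),
                 n_timepoints, k)
    })
  })
  names(ts_list) <- ids
  structure(list(
    subjects = tibble::tibble(subject_id = ids, label = labels),
    timeseries = ts_list,
    provenance = list(k = k, groups = groups, n_per_group = n_per_group,
                      n_timepoints = n_timepoints, noise_sd = noise_sd,
                      seed = seed,
                      group_covariances = group_covariances)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$label)
  cat("<cohort>", nrow(x$subjects), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") | T =",
      x$provenance$n_timepoints, ", K =", x$provenance$k, "\n")
  invisible(x)
}

#' Generate a spatially autocorrelated gene-expression map
#'
#' Produces a Gaussian-random-field-like volume with controllable
#' autocorrelation length (kernel FWHM in mm). When a `target_map` is given,
#' the output is the mixture `rho * standardized(target) +
#' sqrt(1 - rho^2) * independent field`, so its population correlation with
#' the target equals `planted_rho`.
#'
#' @param grid A [vol_grid()].
#' @param gene_symbol Label carried by the map.
#' @param correlation_length_mm Smoothing kernel FWHM in mm.
#' @param target_map Optional numeric vector of in-mask values (or a
#'   `gene_map` / `signature_map` on the same grid) the new map should
#'   correlate with.
#' @param planted_rho Planted correlation in `[-1, 1]`; ignored when
#'   `target_map` is `NULL`.
#' @param scope `"cortical"` or `"subcortical"`; recorded because the two
#'   scopes are scaled separately and must never be pooled.
#' @param seed Integer seed.
#' @return A `gene_map`: list with `gene_symbol`, `grid`, `values` (in-mask
#'   vector), `scope`, `truth`.
#' @export
make_gene_map <- function(grid, gene_symbol = "GENE",
                          correlation_length_mm = 10, target_map = NULL,
                          planted_rho = 0, scope = "cortical", seed = 1) {
  stopifnot(inherits(grid, "vol_grid"))
  if (abs(planted_rho) > 1) stop("|planted_rho| must be <= 1", call. = FALSE)
  scope <- match.arg(scope, c("cortical", "subcortical"))
  target <- NULL
  if (!is.null(target_map)) {
    target <- extract_map_values(target_map, grid)
    if (length(target) != sum(grid$mask)) {
      stop("`target_map` is not on the same grid/mask", call. = FALSE)
    }
  }
  sig <- fwhm_to_sigma_vox(correlation_length_mm, grid)
  vals <- with_seed(seed, {
    field <- smooth_volume(array(stats::rnorm(prod(grid$shape)),
                                 dim = grid$shape), sig)
    v <- scale(field[grid$mask])[, 1]
    if (!is.null(target)) {
      tz <- scale(target)[, 1]
      v <- planted_rho * tz + sqrt(1 - planted_rho^2) * v
    }
    v
  })
  structure(list(gene_symbol = gene_symbol, grid = grid, values = vals,
                 scope = scope,
                 truth = list(planted_rho = if (is.null(target)) NA_real_
                                            else planted_rho,
                              correlation_length_mm = correlation_length_mm,
                              seed = seed)),
            class = "gene_map")
}

# pull in-mask values out of the map-like objects the package passes around
extract_map_values <- function(x, grid) {
  if (is.numeric(x) && is.null(dim(x))) return(as.numeric(x))
  if (inherits(x, c("gene_map", "signature_map"))) {
    if (!same_grid(x$grid, grid)) {
      stop("maps are on different grids", call. = FALSE)
    }
    return(x$values)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(mask_values(x, grid))
  stop("cannot interpret map input", call. = FALSE)
}

#' Partition a mask into contiguous regions
#'
#' Voronoi-style parcellation: `n_regions` seed voxels are drawn from the
#' mask and every mask voxel is assigned to its nearest seed (mm distance),
#' emulating an anatomical atlas of labelled regions.
#'
#' @param grid A [vol_grid()].
#' @param n_regions Number of regions (1 <= n <= mask voxels).
#' @param seed Integer seed.
#' @return A `parcellation`: list with `grid`, `labels` (integer vector over
#'   mask voxels, 1..n_regions), `region_ids`.
#' @export
make_parcellation <- function(grid, n_regions, seed = 1) {
  stopifnot(inherits(grid, "vol_grid"))
  coords <- mask_coords(grid)
  V <- nrow(coords)
  if (n_regions < 1 || n_regions > V) {
    stop("`n_regions` must be between 1 and the number of mask voxels (",
         V, ")", call. = FALSE)
  }
  labels <- with_seed(seed, {
    ctr_idx <- sample.int(V, n_regions)
    ctrs <- coords[ctr_idx, , drop = FALSE]
    # nearest-centre assignment, chunked to bound memory
    lab <- integer(V)
    step <- 4096L
    for (start in seq(1L, V, by = step)) {
      rows <- start:min(start + step - 1L, V)
      d2 <- outer(rowSums(coords[rows, , drop = FALSE]^2),
                  rowSums(ctrs^2), "+") -
        2 * coords[rows, , drop = FALSE] %*% t(ctrs)
      lab[rows] <- max.col(-d2, ties.method = "first")
    }
    lab
  })
  structure(list(grid = grid, labels = labels,
                 region_ids = sort(unique(labels)),
                 provenance = list(n_regions = n_regions, seed = seed)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", length(x$region_ids), "regions over",
      length(x$labels), "mask voxels\n")
  invisible(x)
}
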