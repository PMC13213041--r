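#' Spearman correlation between two maps over a scope
#'
#' Rank correlation (average ranks for ties) across non-missing voxels in
#' the requested scope; monotone-invariant and robust to outliers, which is
#' why it is the similarity measure between signature gradients and
#' gene-expression gradients.
#'
#' @param signature,gene_map In-mask value vectors (or map objects on the
#'   same grid).
#' @param scope_idx Optional integer index vector selecting the scope's
#'   voxels; default all.
#' @param min_voxels Scopes below this size are flagged `skipped` rather
#'   than scored.
#' @param grid Optional grid for map objects.
#' @return Tibble row: `rho`, `n_voxels`, `skipped`.
#' @export
spatial_spearman <- function(signature, gene_map, scope_idx = NULL,
                             min_voxels = 10, grid = NULL) {
  a <- if (is.numeric(signature) && is.null(dim(signature))) signature
       else extract_map_values(signature, grid %||% signature$grid)
  b <- if (is.numeric(gene_map) && is.null(dim(gene_map))) gene_map
       else extract_map_values(gene_map, grid %||% gene_map$grid)
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  if (!is.null(scope_idx)) { a <- a[scope_idx]; b <- b[scope_idx] }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < min_voxels) {
    return(tibble::tibble(rho = NA_real_, n_voxels = length(a),
                          skipped = TRUE))
  }
  tibble::tibble(rho = stats::cor(a, b, method = "spearman"),
                 n_voxels = length(a), skipped = FALSE)
}

#' Permutation z-approximated p-value
#'
#' `z = (rho_obs - mean(null)) / sd(null)`; `p` is the two-sided normal tail
#' probability of `|z|`.
#'
#' @param rho_obs Observed correlation.
#' @param null_rhos Null correlations (>= 100 for stable inference).
#' @return Tibble row: `z`, `p`, `null_mean`, `null_sd`.
#' @export
permutation_pvalues <- function(rho_obs, null_rhos) {
  null_rhos <- null_rhos[is.finite(null_rhos)]
  if (length(null_rhos) < 2) {
    stop("need at least 2 finite null values", call. = FALSE)
  }
  m <- mean(null_rhos); s <- stats::sd(null_rhos)
  if (s == 0) {
    warning("null distribution has zero spread; p undefined", call. = FALSE)
    return(tibble::tibble(z = NA_real_, p = NA_real_, null_mean = m,
                          null_sd = 0))
  }
  z <- (rho_obs - m) / s
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)), null_mean = m,
                 null_sd = s)
}

#' Multiple-testing adjustment with significance flags
#'
#' Benjamini-Hochberg step-up (false discovery rate) or Bonferroni
#' (family-wise error) adjustment at level `alpha`.
#'
#' @param p Raw p-values in `(0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @param alpha Significance level for the flags.
#' @return Tibble: `p`, `p_adj`, `significant`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(p)) {
    return(tibble::tibble(p = numeric(), p_adj = numeric(),
                          significant = logical()))
  }
  adj <- stats::p.adjust(p, method = method)
  tibble::tibble(p = p, p_adj = adj, significant = adj <= alpha)
}

# fast matrix of Spearman correlations: rows of A (n_a x V) vs rows of B
rank_rows <- function(M) {
  t(apply(M, 1, rank, ties.method = "average"))
}

spearman_cross <- function(A, B) {
  Ra <- scale(t(rank_rows(A)))   # V x n_a standardized ranks
  Rb <- scale(t(rank_rows(B)))
  crossprod(Ra, Rb) / (nrow(Ra) - 1)
}

#' Score gene maps against a signature under a surrogate null
#'
#' For each gene map, computes the Spearman correlation with the signature,
#' a null distribution of the same statistic between the gene map and every
#' surrogate of the signature, the z-approximated permutation p-value, and
#' BH / Bonferroni adjusted p-values across the gene family at this scope.
#' With a `parcellation`, the same machinery is applied per region using the
#' surrogate ensemble restricted to that region's voxels.
#'
#' @param signature A `signature_map` (or in-mask vector with `grid`).
#' @param gene_maps List of `gene_map`s (or named list of in-mask vectors).
#' @param surrogates A [generate_surrogates()] ensemble of the signature.
#' @param parcellation Optional [make_parcellation()] switching to regional
#'   scope.
#' @param scope Scope label recorded for cortical-level results.
#' @param alpha Significance level for adjusted flags.
#' @param min_voxels Minimum scope size (see [spatial_spearman()]).
#' @param grid Grid when `signature` is a bare vector.
#' @return A `similarity_result` tibble: `gene`, `scope`, `rho`, `null_mean`,
#'   `null_sd`, `z`, `p`, `p_bh`, `p_bonf`, `n_voxels`. Adjustment families
#'   are per scope (all genes at the cortical scope; all genes within each
#'   region at regional scope).
#' @export
similarity_table <- function(signature, gene_maps, surrogates,
                             parcellation = NULL, scope = "cortical",
                             alpha = 0.05, min_voxels = 10, grid = NULL) {
  stopifnot(inherits(surrogates, "surrogate_ensemble"))
  sig <- if (is.numeric(signature) && is.null(dim(signature))) signature
         else extract_map_values(signature, grid %||% signature$grid)
  gene_names <- names(gene_maps) %||%
    vapply(gene_maps, function(g) g$gene_symbol %||% "GENE", "")
  if (is.null(names(gene_maps)) &&
      all(vapply(gene_maps, inherits, TRUE, "gene_map"))) {
    gene_names <- vapply(gene_maps, `[[`, "", "gene_symbol")
  }
  G <- do.call(rbind, lapply(gene_maps, function(g) {
    if (is.numeric(g) && is.null(dim(g))) g
    else extract_map_values(g, grid %||% g$grid)
  }))
  rownames(G) <- gene_names
  if (ncol(G) != length(sig)) {
    stop("gene maps and signature differ in mask size", call. = FALSE)
  }

  score_scope <- function(idx, scope_label) {
    if (length(idx) < min_voxels) {
      return(tibble::tibble(gene = gene_names, scope = scope_label,
                            rho = NA_real_, null_mean = NA_real_,
                            null_sd = NA_real_, z = NA_real_, p = NA_real_,
                            p_bh = NA_real_, p_bonf = NA_real_,
                            n_voxels = length(idx), skipped = TRUE))
    }
    obs <- spearman_cross(matrix(sig[idx], nrow = 1),
                          G[, idx, drop = FALSE])[1, ]
    null <- spearman_cross(surrogates$values[, idx, drop = FALSE],
                           G[, idx, drop = FALSE])  # n_surr x n_gene
    nm <- colMeans(null)
    ns <- apply(null, 2, stats::sd)
    z <- (obs - nm) / ns
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(gene = gene_names, scope = scope_label,
                   rho = unname(obs), null_mean = unname(nm),
                   null_sd = unname(ns), z = unname(z), p = unname(p),
                   p_bh = unname(stats::p.adjust(p, "BH")),
                   p_bonf = unname(stats::p.adjust(p, "bonferroni")),
                   n_voxels = length(idx), skipped = FALSE)
  }

  if (is.null(parcellation)) {
    out <- score_scope(seq_along(sig), scope)
  } else {
    out <- dplyr::bind_rows(lapply(parcellation$region_ids, function(rid) {
      score_scope(which(parcellation$labels == rid),
                  paste0("region:", rid))
    }))
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("similarity_result", class(out))
  out
}
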