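# canonical signature of an edge set, for de-duplicating variants
edge_signature <- function(edges) {
  paste(sort(paste(edges$parent, "->", edges$child)), collapse = "; ")
}

#' Enumerate and fit variants of a hypothesized cascade
#'
#' Explores the model space around a base path model: `single-edge-reversal`
#' reverses one directed edge at a time; `hierarchy-permutation` permutes the
#' assignment of variables to positions in the cascade graph; `both`
#' combines them. Variants that violate acyclicity are discarded (and
#' counted), duplicates by symmetry are removed, every admissible variant is
#' fitted to the data, and the ranking is by RMSEA ascending then CFI
#' descending. Fits are flagged against the strict cutoffs (CFI > 0.95,
#' TLI > 0.95, RMSEA < 0.05) and a more lenient secondary band (CFI > 0.90,
#' TLI > 0.90, RMSEA < 0.08).
#'
#' @param base A [path_model()].
#' @param data Observations or covariance matrix (see [fit_path_model()]).
#' @param mode `"single-edge-reversal"`, `"hierarchy-permutation"`, or
#'   `"both"`.
#' @param n Sample size when `data` is a covariance matrix.
#' @param max_permutations Cap on hierarchy permutations enumerated (the
#'   base variable count must keep `factorial(p)` tractable).
#' @return A `variant_ranking` tibble: `variant`, `mode`, `edges`, `chi2`,
#'   `df`, `cfi`, `tli`, `rmsea`, `fit_strict`, `fit_lenient`, `fit`
#'   (list column of `sem_fit`s); attribute `n_cyclic_discarded`.
#' @export
enumerate_model_variants <- function(base, data,
                                     mode = c("single-edge-reversal",
                                              "hierarchy-permutation",
                                              "both"),
                                     n = NULL, max_permutations = 5040) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "path_model"))
  variants <- list(list(label = "base", mode = "base", edges = base$edges))
  n_cyclic <- 0L

  add_variant <- function(lst, label, mode_label, edges) {
    m <- tryCatch(path_model(edges), error = function(e) NULL)
    if (is.null(m)) return(list(lst = lst, cyclic = TRUE))
    sig <- edge_signature(m$edges)
    seen <- vapply(lst, function(v) edge_signature(v$edges), "")
    if (sig %in% seen) return(list(lst = lst, cyclic = FALSE))
    list(lst = c(lst, list(list(label = label, mode = mode_label,
                                edges = m$edges))),
         cyclic = FALSE)
  }

  if (mode %in% c("single-edge-reversal", "both")) {
    for (r in seq_len(nrow(base$edges))) {
      ed <- base$edges
      tmp <- ed$parent[r]; ed$parent[r] <- ed$child[r]; ed$child[r] <- tmp
      res <- add_variant(variants,
                         paste0("reverse:", base$edges$parent[r], "->",
                                base$edges$child[r]),
                         "single-edge-reversal", ed)
      if (res$cyclic) n_cyclic <- n_cyclic + 1L else variants <- res$lst
    }
  }
  if (mode %in% c("hierarchy-permutation", "both")) {
    vars <- base$variables
    if (factorial(length(vars)) > max_permutations) {
      stop("hierarchy permutation over ", length(vars),
           " variables exceeds `max_permutations`", call. = FALSE)
    }
    perms <- pracma::perms(seq_along(vars))
    for (row in seq_len(nrow(perms))) {
      mapping <- stats::setNames(vars[perms[row, ]], vars)
      ed <- tibble::tibble(parent = unname(mapping[base$edges$parent]),
                           child = unname(mapping[base$edges$child]))
      res <- add_variant(variants, paste0("perm:", row),
                         "hierarchy-permutation", ed)
      if (res$cyclic) n_cyclic <- n_cyclic + 1L else variants <- res$lst
    }
  }

  rows <- lapply(variants, function(v) {
    fit <- tryCatch(fit_path_model(path_model(v$edges), data, n = n),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble::tibble(variant = v$label, mode = v$mode,
                   edges = edge_signature(v$edges),
                   chi2 = fit$chi2, df = fit$df, cfi = fit$cfi,
                   tli = fit$tli, rmsea = fit$rmsea,
                   fit_strict = isTRUE(fit$cfi > 0.95 & fit$tli > 0.95 &
                                         fit$rmsea < 0.05),
                   fit_lenient = isTRUE(fit$cfi > 0.90 & fit$tli > 0.90 &
                                          fit$rmsea < 0.08),
                   fit = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    warning("no admissible variant could be fitted", call. = FALSE)
    return(structure(out, n_cyclic_discarded = n_cyclic))
  }
  out <- out[order(out$rmsea, -out$cfi), ]
  attr(out, "n_cyclic_discarded") <- n_cyclic
  class(out) <- c("variant_ranking", class(out))
  out
}

#' Compare edge significance between per-contrast fits
#'
#' Given fits of the same path model to data from different contrasts,
#' reports each edge's estimate and p-value per contrast and flags edges
#' whose significance status (at `alpha`) shifts between any two contrasts.
#'
#' @param fits Named list of `sem_fit`s sharing one model.
#' @param alpha Significance level for the shift flags.
#' @return Tibble: `term`, then `estimate_<name>` / `p_<name>` per contrast,
#'   and `shifted`.
#' @export
group_contrast_report <- function(fits, alpha = 0.05) {
  if (is.null(names(fits)) || length(fits) < 2) {
    stop("`fits` must be a named list of at least two fits", call. = FALSE)
  }
  sigs <- vapply(fits, function(f) edge_signature(f$model$edges), "")
  if (length(unique(sigs)) != 1) {
    stop("fits do not share the same path model", call. = FALSE)
  }
  per <- lapply(names(fits), function(nm) {
    est <- fits[[nm]]$estimates
    est <- est[est$type == "coefficient", c("term", "estimate", "p")]
    names(est)[2:3] <- paste0(c("estimate_", "p_"), nm)
    est
  })
  out <- Reduce(function(a, b) dplyr::left_join(a, b, by = "term"), per)
  pcols <- paste0("p_", names(fits))
  sig_mat <- as.matrix(out[, pcols]) < alpha
  out$shifted <- apply(sig_mat, 1, function(r) {
    any(r, na.rm = TRUE) && !all(r, na.rm = TRUE)
  })
  out
}
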