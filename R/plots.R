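#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical variogram
#'
#' @param object A [empirical_variogram()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot variogram
#' @export
autoplot.variogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "distance h (mm)", y = "semivariance γ(h)",
                  title = "Empirical variogram") +
    ggplot2::theme_minimal()
}

#' Plot gene-map similarity results
#'
#' Volcano-style view: Spearman rho against -log10 permutation p, coloured
#' by BH significance at the recorded alpha.
#'
#' @param object A [similarity_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot similarity_result
#' @export
autoplot.similarity_result <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- object[!is.na(object$p), ]
  df$sig <- df$p_bh <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho,
                                   y = -log10(.data$p),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = paste0("BH ≤ ", alpha)) +
    ggplot2::labs(x = "Spearman ρ (signature vs gene map)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated classifier metrics
#'
#' Held-out metrics per fold with the across-fold mean.
#'
#' @param object A [tune_and_fit_cv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connsig_cv
#' @export
autoplot.connsig_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out value",
                  title = paste("Contrast:",
                                paste(object$contrast, collapse = " vs "))) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a map
#'
#' @param map A `signature_map`, `gene_map`, or in-mask vector with `grid`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param grid Required for bare vectors.
#' @return A ggplot raster of the slice (out-of-mask voxels blank).
#' @export
plot_map_slice <- function(map, slice = NULL, grid = NULL) {
  if (inherits(map, c("signature_map", "gene_map"))) {
    grid <- map$grid
    vol <- unmask(map$values, grid)
  } else {
    if (is.null(grid)) stop("`grid` required", call. = FALSE)
    vol <- if (is.array(map)) map else unmask(map, grid)
  }
  if (is.null(slice)) slice <- ceiling(grid$shape[3] / 2)
  sl <- vol[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("axial slice", slice), x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' Plot path-model coefficient estimates
#'
#' Coefficients with approximate 95% confidence intervals from the
#' information-based standard errors.
#'
#' @param object A [fit_path_model()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sem_fit
#' @export
autoplot.sem_fit <- function(object, ...) {
  df <- object$estimates[object$estimates$type == "coefficient", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$se,
      xmax = .data$estimate + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "path coefficient", y = NULL,
                  title = sprintf("CFI %.2f | TLI %.2f | RMSEA %.3f",
                                  object$cfi, object$tli, object$rmsea)) +
    ggplot2::theme_minimal()
}
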